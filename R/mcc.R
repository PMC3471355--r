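#' @title Monoid-comprehension intermediate representation
#' @description Object queries are translated into monoid comprehensions
#'   `accumulator{header | qualifiers}` before target-language emission. A
#'   qualifier is either a generator `v <- e` (over a class extent, a
#'   role path `v.role`, or — before normalization — a nested comprehension)
#'   or a filter comparing path expressions and literals. Two accumulator
#'   monoids are supported: bag union (the collection results of object
#'   queries) and boolean disjunction. A reference evaluator over an
#'   in-memory object store fixes the semantics and serves as the
#'   normalization oracle.
#' @name mcc
NULL

## ---- structures ------------------------------------------------------------

mcc_var <- function(v) list(kind = "var", var = v)
mcc_lit <- function(x) list(kind = "lit", value = as.character(x))
mcc_path <- function(var, member) list(kind = "path", var = var, member = member)
mcc_extent <- function(class, prefix = NA_character_)
  list(kind = "extent", class = class, prefix = prefix)

mcc_gen <- function(var, source) list(kind = "generator", var = var, source = source)
mcc_filter <- function(lhs, op, rhs) list(kind = "filter", lhs = lhs, op = op, rhs = rhs)

#' Construct a monoid comprehension
#' @param monoid `"bag"` (bag union) or `"or"` (boolean disjunction)
#' @param header header expression (a variable reference)
#' @param qualifiers list of generators and filters
#' @return object of class `mcc_comprehension`
#' @export
comprehension <- function(monoid, header, qualifiers) {
  stopifnot(monoid %in% c("bag", "or"))
  structure(list(monoid = monoid, header = header, qualifiers = qualifiers),
            class = "mcc_comprehension")
}

is_comprehension <- function(x) inherits(x, "mcc_comprehension")

#' Variables of a comprehension in first-binding order
#' @param c an `mcc_comprehension`
#' @return character vector
#' @export
mcc_variables <- function(c) {
  out <- character()
  for (q in c$qualifiers) if (q$kind == "generator" && !q$var %in% out)
    out <- c(out, q$var)
  out
}

#' Generator source labels of a comprehension, in order
#' @param c an `mcc_comprehension`
#' @return character vector: class names for extents, `var.member` for paths
#' @export
mcc_generator_sources <- function(c) {
  vapply(Filter(function(q) q$kind == "generator", c$qualifiers), function(q) {
    s <- q$source
    switch(s$kind,
      extent = s$class,
      path = paste0(s$var, ".", s$member),
      comprehension = ,
      "<nested>")
  }, character(1))
}

#' Check binding discipline of a comprehension
#'
#' Every variable used in a path or the header must be bound by an earlier
#' generator (generators binding an already-bound variable act as membership
#' constraints and are allowed).
#'
#' @param c an `mcc_comprehension`
#' @return TRUE, or an error describing the first violation
#' @export
mcc_well_formed <- function(c) {
  bound <- character()
  need <- function(v, where) {
    if (!v %in% bound) stop("variable ", v, " used before binding in ", where)
  }
  for (q in c$qualifiers) {
    if (q$kind == "generator") {
      s <- q$source
      if (s$kind == "path") need(s$var, "generator source")
      if (is_comprehension(s)) mcc_well_formed(s)
      bound <- unique(c(bound, q$var))
    } else {
      for (side in list(q$lhs, q$rhs))
        if (side$kind == "path") need(side$var, "filter")
    }
  }
  if (c$header$kind == "var") need(c$header$var, "header")
  TRUE
}

## ---- translation -----------------------------------------------------------

new_var_counter <- function() {
  env <- new.env(parent = emptyenv()); env$i <- 0L
  function() { v <- paste0("v", env$i); env$i <- env$i + 1L; v }
}

name_catalog <- function(ontology) {
  cls <- chr <- character(); atn <- ats <- character(); rln <- rls <- character()
  for (ax in ontology$axioms) {
    if (ax$kind != "annotation") next
    if (ax$property == "ClassName") { cls <- c(cls, ax$value); chr <- c(chr, ax$subject) }
    if (ax$property == "AttributeName") { atn <- c(atn, ax$value); ats <- c(ats, ax$subject) }
    if (ax$property == "RoleName") { rln <- c(rln, ax$value); rls <- c(rls, ax$subject) }
  }
  list(class_name = stats::setNames(cls, chr),
       attribute_name = stats::setNames(atn, ats),
       role_name = stats::setNames(rln, rls))
}

raw_translate_tree <- function(node, catalog, fresh) {
  # compositional translation of a hop tree: a class node yields a bag
  # comprehension over its extent; each role hop yields a pair of
  # generators, the second over the nested translation of the child
  v <- fresh()
  quals <- list(mcc_gen(v, mcc_extent(catalog$class_name[[node$term]],
                                      term_prefix(node$term))))
  for (at in node$attrs) {
    if (!is.null(at$literal))
      quals[[length(quals) + 1L]] <- mcc_filter(
        mcc_path(v, catalog$attribute_name[[at$term]]), at$op, mcc_lit(at$literal))
  }
  for (br in node$branches) {
    w <- fresh()
    quals[[length(quals) + 1L]] <- mcc_gen(w, mcc_path(v, br$role))
    quals[[length(quals) + 1L]] <- mcc_gen(w, raw_translate_tree(br$child, catalog, fresh))
  }
  comprehension("bag", mcc_var(v), quals)
}

#' Translate a rewritten query into the comprehension IR
#'
#' Compositional translation: a class yields a generator over its extent; a
#' role existential yields a generator over the parent's role path plus a
#' generator over the (nested) translation of the filler; an attribute/value
#' restriction yields a filter on the owning class's variable; for federated
#' queries the per-service translations are concatenated and each join
#' condition contributes an equality filter between the joined classes'
#' attribute names (placed right after the foreign root's extent generator,
#' so every variable is bound before use). Fresh variables are `v0, v1, ...`
#' in translation order; the raw output contains nested comprehensions that
#' [normalize()] unnests.
#'
#' @param rq a `rewritten_query` with values re-inserted
#' @param ontology the generated (merged, for federated queries) ontology
#'   supplying `ClassName`/`AttributeName`/`RoleName` annotations
#' @return an `mcc_comprehension`
#' @export
translate_mcc <- function(rq, ontology) {
  catalog <- name_catalog(ontology)
  fresh <- new_var_counter()
  order <- c(rq$local, setdiff(names(rq$trees), rq$local))
  comps <- list()
  for (p in order) {
    cm <- raw_translate_tree(rq$trees[[p]], catalog, fresh)
    comps[[p]] <- flatten_comprehension(cm)
  }
  quals <- comps[[order[1]]]$qualifiers
  header <- comps[[order[1]]]$header
  for (p in order[-1]) {
    fq <- comps[[p]]$qualifiers
    # join filters for joins attaching this service
    jfs <- list()
    for (j in rq$joins) {
      if (j$foreign_prefix != p && j$local_prefix != p) next
      jc <- j$jc
      local_var <- var_for_class(quals, catalog$class_name[[jc$local_class]])
      # foreign root generator is fq[[1]]
      foreign_var <- comps[[p]]$header$var
      jfs[[length(jfs) + 1L]] <- mcc_filter(
        mcc_path(local_var, catalog$attribute_name[[jc$local_attribute]]),
        jc$predicate,
        mcc_path(foreign_var, catalog$attribute_name[[jc$foreign_attribute]]))
    }
    quals <- c(quals, fq[1], jfs, fq[-1])
  }
  comprehension("bag", header, quals)
}

var_for_class <- function(quals, class_name) {
  for (q in quals)
    if (q$kind == "generator" && q$source$kind == "extent" &&
        identical(q$source$class, class_name)) return(q$var)
  # search nested comprehensions
  for (q in quals) {
    if (q$kind == "generator" && is_comprehension(q$source)) {
      v <- tryCatch(var_for_class(q$source$qualifiers, class_name),
                    error = function(e) NULL)
      if (!is.null(v)) return(v)
    }
  }
  stop("no generator over class ", class_name)
}

#' Translate a class expression (named roles only) into the IR
#'
#' Convenience wrapper for single expressions outside the pipeline: builds a
#' one-service rewritten form and applies [translate_mcc()]. Generic
#' `hasAssociation` conjuncts are untranslatable and raise an error.
#'
#' @param expr a query AST over UML terms with named roles only
#' @param ontology generated ontology for the name catalog
#' @return an `mcc_comprehension`
#' @export
translate_expr <- function(expr, ontology) {
  check_no_generic <- function(x) {
    if (x$kind == "assoc" && is.null(x$prop))
      stop("untranslatable node: generic hasAssociation remains")
    for (f in x[c("filler")]) if (inherits(f, "oq_query")) check_no_generic(f)
    if (!is.null(x$args)) lapply(x$args, check_no_generic)
    invisible()
  }
  check_no_generic(expr)
  tree <- query_node_to_tree(expr, ontology)
  rq <- new_rewritten_query(stats::setNames(list(tree), tree$prefix),
                            joins = list(), local = tree$prefix)
  translate_mcc(rq, ontology)
}

query_node_to_tree <- function(x, ontology) {
  d <- decompose_query_node(x)
  node <- new_hop_node(d$root, d$attrs)
  roles <- role_names(ontology)
  for (a in d$assocs) {
    prop <- a$prop
    if (is.null(prop)) stop("generic hasAssociation cannot become a hop")
    role <- if (prop %in% names(roles)) roles[[prop]] else term_local(prop)
    node$branches <- c(node$branches, list(list(
      role = role, property = prop,
      child = query_node_to_tree(a$filler, ontology))))
  }
  node
}

## ---- normalization ---------------------------------------------------------

subst_var <- function(x, from, to) {
  if (is_comprehension(x)) {
    x$qualifiers <- lapply(x$qualifiers, subst_var, from = from, to = to)
    x$header <- subst_var(x$header, from, to)
    return(x)
  }
  if (!is.list(x)) return(x)
  if (!is.null(x$kind)) {
    if (x$kind == "var" && x$var == from) x$var <- to
    if (x$kind == "path" && x$var == from) x$var <- to
    if (x$kind == "generator") {
      if (x$var == from) x$var <- to
      x$source <- subst_var(x$source, from, to)
    }
    if (x$kind == "filter") {
      x$lhs <- subst_var(x$lhs, from, to)
      x$rhs <- subst_var(x$rhs, from, to)
    }
  }
  x
}

flatten_comprehension <- function(c) {
  # unnest comprehensions used as generator sources: the nested header
  # variable is unified with the outer generator variable, both inside the
  # spliced qualifiers and in everything that follows at this level
  out <- list(); pending <- list()
  apply_pending <- function(x) {
    for (s in pending) x <- subst_var(x, s[1], s[2])
    x
  }
  for (q in c$qualifiers) {
    q <- apply_pending(q)
    if (q$kind == "generator" && is_comprehension(q$source)) {
      nested <- flatten_comprehension(q$source)
      if (nested$header$kind != "var")
        stop("cannot unnest comprehension with non-variable header")
      hv <- nested$header$var
      out <- c(out, lapply(nested$qualifiers, subst_var, from = hv, to = q$var))
      pending[[length(pending) + 1L]] <- c(hv, q$var)
    } else out <- c(out, list(q))
  }
  c$qualifiers <- out
  c$header <- apply_pending(c$header)
  c
}

#' Normalize a comprehension
#'
#' Unnests comprehensions appearing as generator sources (the nested header
#' variable is unified with the outer generator variable and the nested
#' qualifiers spliced in place), coalesces duplicate generators over an
#' identical (variable, source) pair, and renames variables sequentially
#' `v0, v1, ...` in binding order. Idempotent, and semantics-preserving
#' under the reference evaluator. Generators whose variable is never used
#' downstream are kept: under bag semantics they still scale multiplicities,
#' so dropping them would not be equivalence-preserving.
#'
#' @param c an `mcc_comprehension`
#' @return normalized `mcc_comprehension`
#' @export
normalize <- function(c) {
  # 1. unnest
  c <- flatten_comprehension(c)
  # 2. coalesce duplicate generators
  seen <- character(); keep <- list()
  for (q in c$qualifiers) {
    if (q$kind == "generator") {
      key <- paste0(q$var, "|", source_key(q$source))
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    keep <- c(keep, list(q))
  }
  c$qualifiers <- keep
  # 3. sequential renaming
  vars <- mcc_variables(c)
  fresh <- paste0("v", seq_along(vars) - 1L)
  tmp <- paste0(".tmp", seq_along(vars))
  for (i in seq_along(vars)) c <- subst_var_all(c, vars[i], tmp[i])
  for (i in seq_along(vars)) c <- subst_var_all(c, tmp[i], fresh[i])
  c
}

subst_var_all <- function(c, from, to) {
  c$qualifiers <- lapply(c$qualifiers, subst_var, from = from, to = to)
  c$header <- subst_var(c$header, from, to)
  c
}

source_key <- function(s) {
  switch(s$kind,
    extent = paste0("E:", s$class),
    path = paste0("P:", s$var, ".", s$member),
    paste0("C:", render_mcc(s)))
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a comprehension over an object store
#'
#' Standard comprehension semantics: generators iterate class extents
#' (polymorphic — an extent contains instances of the class and its
#' descendants) or role links; a generator re-binding an already-bound
#' variable acts as a membership constraint; filters prune environments;
#' the header is collected under the accumulator. The bag monoid returns a
#' list of objects (with multiplicity); the `or` monoid returns a logical.
#'
#' @param c an `mcc_comprehension` (raw or normalized)
#' @param store an [object_store()]
#' @return list (bag) or logical
#' @export
evaluate <- function(c, store) {
  envs <- list(list())
  value_of <- function(env, e) {
    switch(e$kind,
      var = env[[e$var]],
      lit = e$value,
      path = {
        obj <- env[[e$var]]
        if (is.null(obj)) stop("unbound variable: ", e$var)
        if (e$member %in% names(obj$links)) {
          lapply(obj$links[[e$member]], function(id) store$objects[[id]])
        } else if (e$member %in% names(obj$attrs)) {
          obj$attrs[[e$member]]
        } else stop("unresolvable member: ", e$member, " on ", obj$class)
      },
      stop("cannot evaluate expression kind: ", e$kind))
  }
  collection_of <- function(env, s) {
    if (is_comprehension(s)) return(evaluate_in(s, env))
    switch(s$kind,
      extent = store_extent(store, s$class),
      path = {
        v <- value_of(env, s)
        if (is.list(v)) v else list(v)
      },
      stop("bad generator source"))
  }
  evaluate_in <- function(comp, outer_env) {
    local_envs <- list(outer_env)
    for (q in comp$qualifiers) {
      nxt <- list()
      for (env in local_envs) {
        if (q$kind == "generator") {
          coll <- collection_of(env, q$source)
          if (!is.null(env[[q$var]])) {
            # re-binding generator: the environment survives once per
            # occurrence of the bound value (bag multiplicity)
            cur <- env[[q$var]]
            k <- sum(vapply(coll, function(x) same_value(x, cur), logical(1)))
            if (k > 0L) nxt <- c(nxt, rep(list(env), k))
          } else {
            for (x in coll) { e2 <- env; e2[[q$var]] <- x; nxt <- c(nxt, list(e2)) }
          }
        } else {
          l <- value_of(env, q$lhs); r <- value_of(env, q$rhs)
          if (compare_values(l, q$op, r)) nxt <- c(nxt, list(env))
        }
      }
      local_envs <- nxt
    }
    lapply(local_envs, function(env) value_of(env, comp$header))
  }
  res <- evaluate_in(c, list())
  if (c$monoid == "or") return(length(res) > 0L)
  res
}

same_value <- function(a, b) {
  if (is.list(a) && is.list(b) && !is.null(a$id) && !is.null(b$id))
    return(identical(a$id, b$id))
  identical(a, b)
}

compare_values <- function(l, op, r) {
  l <- as.character(l); r <- as.character(r)
  switch(op,
    EQUAL_TO = identical(l, r),
    NOT_EQUAL_TO = !identical(l, r),
    LIKE = grepl(glob2rx_like(r), l),
    LESS_THAN = l < r,
    LESS_THAN_EQUAL_TO = l <= r,
    GREATER_THAN = l > r,
    GREATER_THAN_EQUAL_TO = l >= r,
    IS_NULL = !nzchar(l),
    IS_NOT_NULL = nzchar(l),
    stop("unknown comparison: ", op))
}

glob2rx_like <- function(pattern) {
  # CQL LIKE uses % as wildcard
  paste0("^", gsub("%", ".*", gsub("([.\\\\+*?\\[^\\]$(){}=!<>|:#-])", "\\\\\\1",
                                   pattern)), "$")
}

## ---- rendering & reading ---------------------------------------------------

render_qualifier <- function(q) {
  if (q$kind == "generator") {
    src <- if (is_comprehension(q$source)) render_mcc(q$source)
           else if (q$source$kind == "extent") q$source$class
           else paste0(q$source$var, ".", q$source$member)
    paste0(q$var, " <- ", src)
  } else {
    side <- function(e) {
      if (e$kind == "lit") paste0("\"", e$value, "\"")
      else paste0(e$var, ".", e$member)
    }
    paste0(side(q$lhs), " ", comparison_symbol(q$op), " ", side(q$rhs))
  }
}

#' Render a comprehension as text
#'
#' Deterministic form `⊎{header | q1, ..., qn}` (or `or{...}`),
#' parseable back by [read_mcc()].
#'
#' @param c an `mcc_comprehension`
#' @return character scalar
#' @export
render_mcc <- function(c) {
  acc <- if (c$monoid == "bag") "\u228e" else "or"
  paste0(acc, "{", c$header$var, " | ",
         paste(vapply(c$qualifiers, render_qualifier, character(1)), collapse = ", "),
         "}")
}

#' Read a rendered comprehension back
#'
#' Inverse of [render_mcc()] for flat (normalization-level) comprehensions.
#'
#' @param text rendered comprehension
#' @return an `mcc_comprehension`
#' @export
read_mcc <- function(text) {
  text <- trimws(text)
  acc <- if (startsWith(text, "\u228e")) "bag"
         else if (startsWith(text, "or{")) "or"
         else stop("not a comprehension: ", text)
  body <- sub("^[^{]*\\{", "", text)
  body <- sub("\\}$", "", body)
  parts <- strsplit(body, "|", fixed = TRUE)[[1]]
  header <- trimws(parts[1])
  quals_text <- trimws(paste(parts[-1], collapse = "|"))
  quals <- list()
  if (nzchar(quals_text)) {
    for (qt in split_top_commas(quals_text)) {
      qt <- trimws(qt)
      if (grepl(" <- ", qt, fixed = TRUE)) {
        bits <- strsplit(qt, " <- ", fixed = TRUE)[[1]]
        src <- trimws(bits[2])
        source <- if (grepl("^[A-Za-z_][A-Za-z0-9_]*\\.", src) && grepl("^v[0-9]+\\.", src)) {
          pb <- strsplit(src, ".", fixed = TRUE)[[1]]
          mcc_path(pb[1], paste(pb[-1], collapse = "."))
        } else mcc_extent(src)
        quals[[length(quals) + 1L]] <- mcc_gen(trimws(bits[1]), source)
      } else {
        m <- regexec("^(\\S+)\\s+(=|!=|<=|>=|<|>|like)\\s+(.*)$", qt)[[1]]
        if (m[1] < 0) stop("cannot read qualifier: ", qt)
        g <- regmatches(qt, regexec("^(\\S+)\\s+(=|!=|<=|>=|<|>|like)\\s+(.*)$", qt))[[1]]
        side <- function(s) {
          s <- trimws(s)
          if (startsWith(s, "\"")) mcc_lit(gsub("^\"|\"$", "", s))
          else {
            pb <- strsplit(s, ".", fixed = TRUE)[[1]]
            mcc_path(pb[1], paste(pb[-1], collapse = "."))
          }
        }
        quals[[length(quals) + 1L]] <-
          mcc_filter(side(g[2]), symbol_comparison(g[3]), side(g[4]))
      }
    }
  }
  comprehension(acc, mcc_var(header), quals)
}

split_top_commas <- function(text) {
  out <- character(); depth <- 0L; start <- 1L; in_str <- FALSE
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "\"") in_str <- !in_str
    if (in_str) next
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, substr(text, start, i - 1L)); start <- i + 1L
    }
  }
  c(out, substr(text, start, nchar(text)))
}

#' @export
print.mcc_comprehension <- function(x, ...) {
  cat(render_mcc(x), "\n")
  invisible(x)
}
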