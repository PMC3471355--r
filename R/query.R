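#' @title Concept-based queries
#' @description A restricted Manchester-style surface syntax for
#'   concept-based queries, its AST, and the query-level operations of the
#'   reformulation pipeline: UML candidate extraction, data-value stripping
#'   and exact re-insertion, and concept-to-UML substitution. The grammar is
#'   \preformatted{
#'   expr     := conjunct ("and" conjunct)*
#'   conjunct := concept
#'             | "hasAssociation" "some" unit
#'             | <roleName> "some" unit
#'             | "hasAttribute" "some" unit
#'             | "hasValue" ("value" | "=" | "!=" | "<" | "<=" | ">" | ">=" |
#'                           "like") <string literal>
#'   unit     := "(" expr ("or" expr)* ")" | conjunct}
#'   Disjunction requires explicit parentheses. Value restrictions are only
#'   legal inside `hasAttribute` fillers.
#' @name queries
NULL

new_q <- function(kind, ...) structure(list(kind = kind, ...), class = "oq_query")

#' Query-AST constructors
#' @param name concept or UML term
#' @param ... sub-expressions
#' @param prop association property/role name, or `NULL` for the generic
#'   transitive `hasAssociation`
#' @param filler sub-expression
#' @param op comparison operator (CQL predicate name)
#' @param literal string literal
#' @name query_ast
NULL

#' @rdname query_ast
#' @export
q_concept <- function(name) new_q("concept", name = name)

#' @rdname query_ast
#' @export
q_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1]], "oq_query")) args <- args[[1]]
  if (length(args) == 1L) return(args[[1]])
  new_q("and", args = args)
}

#' @rdname query_ast
#' @export
q_or <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1]], "oq_query")) args <- args[[1]]
  new_q("or", args = args)
}

#' @rdname query_ast
#' @export
q_assoc <- function(prop, filler) new_q("assoc", prop = prop, filler = filler)

#' @rdname query_ast
#' @export
q_attr <- function(filler) new_q("attr", filler = filler)

#' @rdname query_ast
#' @export
q_value <- function(op, literal) {
  stopifnot(op %in% cql_predicates())
  new_q("value", op = op, literal = as.character(literal))
}

#' Structural equality of query expressions
#' @param a,b query expressions
#' @return logical
#' @export
q_equal <- function(a, b) identical(unclass_rec(a), unclass_rec(b))

#' Render a query expression in the surface syntax
#' @param x query expression
#' @return character scalar
#' @export
q_render <- function(x) {
  paren <- function(y) {
    if (y$kind %in% c("and", "or")) paste0("(", q_render(y), ")") else q_render(y)
  }
  switch(x$kind,
    concept = x$name,
    and = paste(vapply(x$args, paren, character(1)), collapse = " and "),
    or  = paste(vapply(x$args, paren, character(1)), collapse = " or "),
    assoc = paste0(if (is.null(x$prop)) "hasAssociation" else x$prop,
                   " some ", paren(x$filler)),
    attr = paste0("hasAttribute some ", paren(x$filler)),
    value = paste0("hasValue ",
                   if (x$op == "EQUAL_TO") "value" else comparison_symbol(x$op),
                   " \"", x$literal, "\""))
}

## ---- tokenizer & parser ----------------------------------------------------

tokenize_query <- function(text) {
  tokens <- list(); pos <- 1L; n <- nchar(text)
  push <- function(type, value, at) tokens[[length(tokens) + 1L]] <<-
    list(type = type, value = value, at = at)
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
    if (ch == "(") { push("lparen", "(", pos); pos <- pos + 1L; next }
    if (ch == ")") { push("rparen", ")", pos); pos <- pos + 1L; next }
    if (ch == "\"") {
      close <- regexpr("\"", substr(text, pos + 1L, n), fixed = TRUE)
      if (close < 0) stop("unterminated string literal at offset ", pos)
      push("string", substr(text, pos + 1L, pos + close - 1L), pos)
      pos <- pos + close + 1L
      next
    }
    two <- substr(text, pos, pos + 1L)
    if (two %in% c("!=", "<=", ">=")) { push("cmp", two, pos); pos <- pos + 2L; next }
    if (ch %in% c("=", "<", ">")) { push("cmp", ch, pos); pos <- pos + 1L; next }
    m <- regexpr("^[A-Za-z_][A-Za-z0-9_:.]*", substr(text, pos, n))
    if (m == 1L) {
      len <- attr(m, "match.length")
      word <- substr(text, pos, pos + len - 1L)
      type <- if (word %in% c("and", "or", "some", "value", "like")) word else "ident"
      push(type, word, pos)
      pos <- pos + len
      next
    }
    stop("unexpected character '", ch, "' at offset ", pos)
  }
  tokens
}

#' Parse a concept-based query
#'
#' @param text query text in the surface syntax
#' @return a query AST (`oq_query`); syntax errors report the offending
#'   offset
#' @export
parse_query <- function(text) {
  toks <- tokenize_query(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- peek(); i <<- i + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t)) stop("unexpected end of query, expected ", type)
    if (t$type != type)
      stop("expected ", type, " but found '", t$value, "' at offset ", t$at)
    advance()
  }
  parse_unit <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of query")
    if (t$type == "lparen") {
      advance()
      e <- parse_expr()
      branches <- list(e)
      while (!is.null(peek()) && peek()$type == "or") {
        advance()
        branches[[length(branches) + 1L]] <- parse_expr()
      }
      expect("rparen")
      if (length(branches) > 1L) return(q_or(branches))
      return(e)
    }
    parse_conjunct()
  }
  parse_conjunct <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of query")
    if (t$type != "ident")
      stop("expected a concept or property at offset ", t$at, " (found '", t$value, "')")
    advance()
    word <- t$value
    nxt <- peek()
    if (word == "hasValue") {
      op <- "EQUAL_TO"
      if (!is.null(nxt) && nxt$type %in% c("value", "cmp", "like")) {
        advance()
        if (nxt$type != "value")
          op <- symbol_comparison(if (nxt$type == "like") "like" else nxt$value)
      }
      lit <- expect("string")
      return(q_value(op, lit$value))
    }
    if (!is.null(nxt) && nxt$type == "some") {
      advance()
      filler <- parse_unit()
      if (word == "hasAssociation") return(q_assoc(NULL, filler))
      if (word == "hasAttribute") return(q_attr(filler))
      return(q_assoc(word, filler))
    }
    q_concept(word)
  }
  parse_expr <- function() {
    parts <- list(parse_conjunct_or_unit())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parse_conjunct_or_unit()
    }
    q_and(parts)
  }
  parse_conjunct_or_unit <- function() {
    if (!is.null(peek()) && peek()$type == "lparen") parse_unit() else parse_conjunct()
  }
  out <- parse_expr()
  t <- peek()
  if (!is.null(t))
    stop("unexpected token '", t$value, "' at offset ", t$at)
  validate_query(out)
  out
}

#' Validate placement rules of a query AST
#'
#' Value restrictions may only appear inside `hasAttribute` fillers, and each
#' attribute filler must contain a concept.
#'
#' @param query query AST
#' @return the query, invisibly
#' @export
validate_query <- function(query) {
  walk <- function(x, in_attr) {
    switch(x$kind,
      value = if (!in_attr) stop("value restriction outside an attribute filler"),
      concept = invisible(),
      and = , or = lapply(x$args, walk, in_attr = in_attr),
      assoc = walk(x$filler, FALSE),
      attr = {
        f <- x$filler
        members <- if (f$kind == "and") f$args else list(f)
        if (!any(vapply(members, function(m) m$kind == "concept", logical(1))))
          stop("attribute filler must contain a concept")
        lapply(members, walk, in_attr = TRUE)
      })
    invisible()
  }
  walk(query, FALSE)
  invisible(query)
}

## ---- UML extraction --------------------------------------------------------

query_concepts <- function(query) {
  # concept occurrences with their role (class vs attribute) and, for
  # attribute concepts, the enclosing class concept
  out <- list()
  walk <- function(x, enclosing, in_attr) {
    switch(x$kind,
      concept = out[[length(out) + 1L]] <<-
        list(name = x$name, kind = if (in_attr) "attribute" else "class",
             enclosing = enclosing),
      and = , or = {
        encl <- enclosing
        if (!in_attr) {
          for (m in x$args) if (m$kind == "concept") { encl <- m$name; break }
        }
        for (m in x$args) walk(m, encl, in_attr)
      },
      assoc = walk(x$filler, NA_character_, FALSE),
      attr = walk(x$filler, enclosing, TRUE),
      value = invisible())
    invisible()
  }
  walk(query, NA_character_, FALSE)
  seen <- character(); uniq <- list()
  for (o in out) {
    if (!o$name %in% seen) { seen <- c(seen, o$name); uniq[[length(uniq) + 1L]] <- o }
  }
  uniq
}

#' Extract UML candidate substitutions for a query
#'
#' Maps every concept in the query to the UML classes (or attributes, for
#' concepts inside `hasAttribute` fillers) annotated below it in each target
#' ontology, forms the Cartesian product of the per-concept candidate sets
#' in deterministic order, and filters to substitutions where each attribute
#' candidate is attached to (declared on, or inherited by) its enclosing
#' class candidate — which also forces both to live in the same model.
#'
#' @param query parsed query AST
#' @param ontologies list of `generated_ontology` (one per target model)
#' @return list of `candidate_substitution` (named concept-to-term mappings)
#' @export
extract_uml <- function(query, ontologies) {
  if (inherits(ontologies, "generated_ontology")) ontologies <- list(ontologies)
  hierarchies <- lapply(ontologies, classify)
  occs <- query_concepts(query)
  candidates <- list()
  for (o in occs) {
    cand <- character()
    for (k in seq_along(ontologies)) {
      ct <- term("n", o$name)
      if (ct %in% hierarchies[[k]]$terms)
        cand <- c(cand, uml_elements_for(ct, hierarchies[[k]], o$kind))
    }
    cand <- sort(unique(cand))
    if (!length(cand))
      stop("no UML ", o$kind, " candidate for concept: ", o$name)
    candidates[[o$name]] <- cand
  }
  # owner lookup across all ontologies
  owner_of <- function(attr_term) {
    for (ont in ontologies) {
      ow <- attribute_owner(ont, attr_term)
      if (!is.null(ow)) return(ow)
    }
    NULL
  }
  hier_all <- classify(merge_ontologies(ontologies))
  # Cartesian product, first concept most significant
  grid <- expand.grid(rev(candidates), stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(candidates)), drop = FALSE]
  names(grid) <- names(candidates)
  out <- list()
  for (r in seq_len(nrow(grid))) {
    mapping <- vapply(names(candidates), function(nm) grid[r, nm], character(1))
    ok <- TRUE
    for (o in occs) {
      if (o$kind == "attribute") {
        if (is.na(o$enclosing)) { ok <- FALSE; break }
        cls <- mapping[[o$enclosing]]
        ow <- owner_of(mapping[[o$name]])
        if (is.null(ow) || !is_subsumed(hier_all, cls, ow)) { ok <- FALSE; break }
      }
    }
    if (ok) out[[length(out) + 1L]] <-
      structure(list(mapping = mapping,
                     prefixes = stats::setNames(term_prefix(mapping), names(mapping))),
                class = "candidate_substitution")
  }
  out
}

#' @export
print.candidate_substitution <- function(x, ...) {
  cat(paste0(names(x$mapping), " -> ", x$mapping, collapse = "; "), "\n")
  invisible(x)
}

#' Apply a candidate substitution to a query
#'
#' Replaces each concept leaf with its chosen UML term.
#'
#' @param query query AST
#' @param substitution a `candidate_substitution`
#' @return query AST over UML terms
#' @export
substitute_query <- function(query, substitution) {
  walk <- function(x) {
    switch(x$kind,
      concept = {
        if (!x$name %in% names(substitution$mapping))
          stop("substitution does not cover concept: ", x$name)
        q_concept(substitution$mapping[[x$name]])
      },
      and = new_q("and", args = lapply(x$args, walk)),
      or = new_q("or", args = lapply(x$args, walk)),
      assoc = q_assoc(x$prop, walk(x$filler)),
      attr = q_attr(walk(x$filler)),
      value = x)
  }
  walk(query)
}

## ---- value stripping & re-insertion ----------------------------------------

#' Strip data-value restrictions from a query
#'
#' Removes every `hasValue` restriction, recording enough positional
#' information that [reinsert_values()] restores the original expression
#' exactly. Attribute fillers that collapse to a single member lose their
#' conjunction wrapper; re-insertion rebuilds it.
#'
#' @param query query AST
#' @return list with `expr` (the stripped AST) and `bindings` (a
#'   `value_bindings` list; one entry per attribute filler that held values)
#' @export
strip_values <- function(query) {
  bindings <- list()
  walk <- function(x, path) {
    switch(x$kind,
      concept = , value = x,
      and = new_q("and", args = lapply(seq_along(x$args), function(i)
        walk(x$args[[i]], c(path, i)))),
      or = new_q("or", args = lapply(seq_along(x$args), function(i)
        walk(x$args[[i]], c(path, i)))),
      assoc = q_assoc(x$prop, walk(x$filler, c(path, 0L))),
      attr = {
        f <- x$filler
        members <- if (f$kind == "and") f$args else list(f)
        isval <- vapply(members, function(m) m$kind == "value", logical(1))
        if (any(isval)) {
          bindings[[length(bindings) + 1L]] <<- structure(list(
            path = path,
            n_members = length(members),
            values = lapply(which(isval), function(i)
              list(index = i, op = members[[i]]$op, literal = members[[i]]$literal)),
            attribute = {
              kc <- which(vapply(members, function(m)
                m$kind == "concept", logical(1)))
              if (length(kc)) members[[kc[1]]]$name else NA_character_
            }
          ), class = "value_binding")
          kept <- members[!isval]
          q_attr(if (length(kept) == 1L) kept[[1]] else new_q("and", args = kept))
        } else x
      })
  }
  expr <- walk(query, integer())
  structure(list(expr = expr, bindings = structure(bindings, class = "value_bindings")),
            class = "stripped_query")
}

node_at <- function(query, path) {
  x <- query
  for (p in path) x <- if (p == 0L) x$filler else x$args[[p]]
  x
}

replace_at <- function(query, path, value) {
  if (!length(path)) return(value)
  p <- path[1]
  if (p == 0L) query$filler <- replace_at(query$filler, path[-1], value)
  else query$args[[p]] <- replace_at(query$args[[p]], path[-1], value)
  query
}

#' Re-insert stripped data values
#'
#' Exact inverse of [strip_values()]: every recorded restriction is restored
#' at its original position. A binding whose attribute node no longer exists
#' (eliminated by a downstream choice) raises an error.
#'
#' @param expr stripped query AST
#' @param bindings `value_bindings` from [strip_values()]
#' @return the original query AST
#' @export
reinsert_values <- function(expr, bindings) {
  for (b in bindings) {
    attr_node <- tryCatch(node_at(expr, b$path), error = function(e) NULL)
    if (is.null(attr_node) || attr_node$kind != "attr")
      stop("orphaned value binding: its attribute restriction was eliminated")
    f <- attr_node$filler
    kept <- if (f$kind == "and") f$args else list(f)
    members <- vector("list", b$n_members)
    for (v in b$values) members[[v$index]] <- q_value(v$op, v$literal)
    j <- 1L
    for (i in seq_len(b$n_members)) {
      if (is.null(members[[i]])) { members[[i]] <- kept[[j]]; j <- j + 1L }
    }
    new_filler <- if (length(members) == 1L) members[[1]] else new_q("and", args = members)
    expr <- replace_at(expr, c(b$path), q_attr(new_filler))
  }
  expr
}
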