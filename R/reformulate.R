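#' @title Query reformulation pipeline
#' @description The staged rewriting of a concept-based query into CQL or
#'   DCQL: parsing, per-model ontology generation, UML candidate extraction,
#'   data-value stripping, semantic validation, path finding (single-service
#'   or federated with join discovery), value re-insertion, translation to
#'   the monoid-comprehension IR, normalization, and target-language
#'   emission. User interaction points (extraction choice, join choice, path
#'   choice) are resolved through an explicit [choice_policy()] so that the
#'   whole pipeline is a deterministic function of its inputs.
#' @name reformulation
NULL

#' Choice policy for the pipeline's user-interaction points
#'
#' @param strategy `"first"` (always take the first candidate),
#'   `"indexed"` (take the indices supplied per choice point), or
#'   `"interactive"` (prompt on the console; not used by tests)
#' @param extraction index into the UML-extraction candidates
#' @param join index (or vector of indices) into the discovered join
#'   conditions
#' @param path index into the candidate path rewritings
#' @return object of class `choice_policy`
#' @export
choice_policy <- function(strategy = c("first", "indexed", "interactive"),
                          extraction = 1L, join = 1L, path = 1L) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy,
                 indices = list(extraction = extraction, join = join, path = path)),
            class = "choice_policy")
}

resolve_choice <- function(policy, what, candidates, multiple = FALSE) {
  n <- length(candidates)
  if (!n) stop("no candidates available at choice point '", what, "'")
  idx <- switch(policy$strategy,
    first = 1L,
    indexed = policy$indices[[what]],
    interactive = {
      cat("Choose ", what, " (1-", n, "):\n", sep = "")
      for (i in seq_len(n)) cat("  [", i, "] ", format(candidates[[i]])[1], "\n", sep = "")
      as.integer(readline("> "))
    })
  idx <- as.integer(idx)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n))
    stop("choice index out of range at '", what, "': ", paste(idx, collapse = ","),
         " (", n, " candidates)")
  if (multiple) idx else idx[1]
}

## ---- query AST -> class expression -----------------------------------------

#' Convert a (substituted) query AST to a class expression
#' @param query query AST over UML terms
#' @return an `oq_ce`
#' @export
query_to_ce <- function(query) {
  u <- uml_terms()
  walk <- function(x) {
    switch(x$kind,
      concept = ce_named(x$name),
      and = new_ce("and", args = lapply(x$args, walk)),
      or = new_ce("or", args = lapply(x$args, walk)),
      assoc = ce_some(if (is.null(x$prop)) u$has_association else x$prop, walk(x$filler)),
      attr = ce_some(u$has_attribute, walk(x$filler)),
      value = ce_value(u$has_value, x$literal, x$op))
  }
  walk(query)
}

## ---- hop trees -------------------------------------------------------------

# A hop tree is the internal form of a rewritten query: a class node with
# attribute restrictions and role-labelled branches to child nodes.
new_hop_node <- function(term, attrs = list(), branches = list()) {
  list(term = term, prefix = term_prefix(term), attrs = attrs, branches = branches)
}

hop_tree_to_ce <- function(node) {
  u <- uml_terms()
  parts <- list(ce_named(node$term))
  for (at in node$attrs) {
    inner <- if (is.null(at$literal)) ce_named(at$term)
             else ce_and(ce_named(at$term), ce_value(u$has_value, at$literal, at$op))
    parts[[length(parts) + 1L]] <- ce_some(u$has_attribute, inner)
  }
  for (br in node$branches)
    parts[[length(parts) + 1L]] <- ce_some(br$property, hop_tree_to_ce(br$child))
  if (length(parts) == 1L) parts[[1]] else new_ce("and", args = parts)
}

#' Class sequence of a hop tree (preorder)
#' @param node hop-tree node
#' @return character vector of class terms
#' @export
hop_tree_classes <- function(node) {
  c(node$term, unlist(lapply(node$branches, function(br) hop_tree_classes(br$child))))
}

# decompose a conjunction-form query node into root term, attrs, assoc items
decompose_query_node <- function(x) {
  flat <- function(e) {
    if (e$kind != "and") return(list(e))
    do.call(c, lapply(e$args, flat))
  }
  parts <- flat(x)
  root <- NULL; attrs <- list(); assocs <- list()
  for (p in parts) {
    if (p$kind == "concept" && is.null(root)) root <- p$name
    else if (p$kind == "attr") {
      f <- p$filler
      members <- if (f$kind == "and") f$args else list(f)
      aterm <- NULL; op <- NULL; lit <- NULL
      for (m in members) {
        if (m$kind == "concept" && is.null(aterm)) aterm <- m$name
        if (m$kind == "value") { op <- m$op; lit <- m$literal }
      }
      attrs[[length(attrs) + 1L]] <- list(term = aterm, op = op, literal = lit)
    }
    else if (p$kind == "assoc") assocs[[length(assocs) + 1L]] <- p
    else if (p$kind == "concept") {
      # extra class conjunct on the same node; keep as zero-hop constraint
      assocs[[length(assocs) + 1L]] <- q_assoc(NULL, p)
    }
    else stop("unsupported construct in path rewriting: ", p$kind)
  }
  if (is.null(root)) stop("expression has no named root class")
  list(root = root, attrs = attrs, assocs = assocs)
}

# all hop-tree rewritings of a query node over an association graph
rewrite_combinations <- function(x, graph, max_paths) {
  d <- decompose_query_node(x)
  branch_options <- list()
  for (a in d$assocs) {
    fd <- decompose_query_node(a$filler)
    paths <- find_paths(graph, d$root, fd$root, max_paths)
    if (!length(paths))
      stop("no association path from ", d$root, " to ", fd$root)
    child_combos <- rewrite_combinations(a$filler, graph, max_paths)
    opts <- list()
    for (p in paths) for (child in child_combos)
      opts[[length(opts) + 1L]] <- list(path = p, child = child)
    branch_options[[length(branch_options) + 1L]] <- opts
  }
  combos <- list(list())
  for (opts in branch_options) {
    nxt <- list()
    for (base in combos) for (o in opts)
      nxt[[length(nxt) + 1L]] <- c(base, list(o))
    combos <- nxt
  }
  lapply(combos, function(chosen) {
    node <- new_hop_node(d$root, d$attrs)
    for (o in chosen) {
      if (!length(o$path$edges)) {
        # zero-hop: merge child into this node
        node$attrs <- c(node$attrs, o$child$attrs)
        node$branches <- c(node$branches, o$child$branches)
      } else {
        node$branches <- c(node$branches,
                           list(chain_to_branch(o$path$edges, o$child)))
      }
    }
    merge_hop_branches(node)
  })
}

merge_hop_branches <- function(node) {
  # conjuncts whose paths run through the same association hop to the same
  # class share that segment: one chain of intermediate classes, with the
  # divergent tails as separate branches below the shared node
  if (!length(node$branches)) return(node)
  merged <- list()
  for (br in node$branches) {
    hit <- 0L
    for (i in seq_along(merged)) {
      if (identical(merged[[i]]$property, br$property) &&
          identical(merged[[i]]$child$term, br$child$term)) { hit <- i; break }
    }
    if (hit) {
      m <- merged[[hit]]
      m$child$attrs <- unique(c(m$child$attrs, br$child$attrs))
      m$child$branches <- c(m$child$branches, br$child$branches)
      merged[[hit]] <- m
    } else merged[[length(merged) + 1L]] <- br
  }
  node$branches <- lapply(merged, function(br) {
    br$child <- merge_hop_branches(br$child)
    br
  })
  node
}

chain_to_branch <- function(edges, terminal) {
  # edges e1..ek; terminal tree replaces the node for ek's target
  if (length(edges) == 1L) {
    e <- edges[[1]]
    term_node <- terminal
    term_node$term <- e$target    # keep the hop's own class term
    term_node$prefix <- term_prefix(e$target)
    return(list(role = e$role, property = e$property, child = term_node))
  }
  e <- edges[[1]]
  list(role = e$role, property = e$property,
       child = new_hop_node(e$target,
                            branches = list(chain_to_branch(edges[-1], terminal))))
}

#' Single-service path rewriting
#'
#' Replaces every generic `hasAssociation` conjunct with a nested chain of
#' role-named existentials along a simple association path, producing one
#' candidate rewriting per combination of chosen paths, ordered
#' deterministically (per-conjunct paths shortest first).
#'
#' @param expr substituted (and usually stripped) query AST over one model's
#'   UML terms
#' @param ontology the model's `generated_ontology`
#' @param max_paths cap on paths considered per conjunct
#' @return list of `rewritten_query` objects, each with a single service
#'   entry
#' @export
find_query_paths <- function(expr, ontology, max_paths = Inf) {
  graph <- association_graph(ontology)
  trees <- rewrite_combinations(expr, graph, max_paths)
  lapply(trees, function(tr) {
    new_rewritten_query(trees = stats::setNames(list(tr), tr$prefix),
                        joins = list(), local = tr$prefix)
  })
}

new_rewritten_query <- function(trees, joins, local) {
  structure(list(trees = trees,
                 exprs = lapply(trees, hop_tree_to_ce),
                 joins = joins, local = local),
            class = "rewritten_query")
}

#' @export
print.rewritten_query <- function(x, ...) {
  for (p in names(x$trees)) {
    cat("[", p, "] ", ce_render(x$exprs[[p]]), "\n", sep = "")
  }
  for (j in x$joins) print(j$jc)
  invisible(x)
}

## ---- federated path finding ------------------------------------------------

split_tree_by_service <- function(tree, jcs) {
  # splits a combined hop tree (over a join-merged graph) into per-service
  # trees; returns list(trees = prefix -> tree, joins = list of crossings)
  service_trees <- list()
  joins <- list()
  ensure_root <- function(prefix, term) {
    if (is.null(service_trees[[prefix]])) {
      service_trees[[prefix]] <<- new_hop_node(term)
    } else if (service_trees[[prefix]]$term != term) {
      stop("federated split needs a single entry class per service; got ",
           service_trees[[prefix]]$term, " and ", term)
    }
    invisible()
  }
  # walk with an address into the service tree: vector of branch indices
  attach_branch <- function(prefix, addr, branch) {
    tr <- service_trees[[prefix]]
    tr <- attach_at(tr, addr, branch)
    service_trees[[prefix]] <<- tr
    c(addr, length(node_at_addr(tr, addr)$branches))
  }
  attach_at <- function(node, addr, branch) {
    if (!length(addr)) { node$branches <- c(node$branches, list(branch)); return(node) }
    node$branches[[addr[1]]]$child <-
      attach_at(node$branches[[addr[1]]]$child, addr[-1], branch)
    node
  }
  node_at_addr <- function(node, addr) {
    for (a in addr) node <- node$branches[[a]]$child
    node
  }
  add_attrs <- function(prefix, addr, attrs) {
    if (!length(attrs)) return(invisible())
    tr <- service_trees[[prefix]]
    mod <- function(node, addr) {
      if (!length(addr)) { node$attrs <- c(node$attrs, attrs); return(node) }
      node$branches[[addr[1]]]$child <- mod(node$branches[[addr[1]]]$child, addr[-1])
      node
    }
    service_trees[[prefix]] <<- mod(tr, addr)
    invisible()
  }
  match_jc <- function(local_term, foreign_term) {
    for (jc in jcs) {
      if ((jc$local_class == local_term && jc$foreign_class == foreign_term) ||
          (jc$local_class == foreign_term && jc$foreign_class == local_term))
        return(jc)
    }
    stop("path crosses services at (", local_term, ", ", foreign_term,
         ") but no matching join condition was selected")
  }
  walk <- function(node, prefix, addr) {
    add_attrs(prefix, addr, node$attrs)
    for (br in node$branches) {
      edge_prefix <- term_prefix(br$property)
      if (edge_prefix == prefix) {
        child_addr <- attach_branch(prefix, addr,
                                    list(role = br$role, property = br$property,
                                         child = new_hop_node(br$child$term)))
        walk(br$child, prefix, child_addr)
      } else {
        # join crossing: this node is equivalent to a class of edge_prefix
        local_term <- current_term(prefix, addr)
        foreign_term <- edge_source_term(br)
        jc <- match_jc(local_term, foreign_term)
        joins[[length(joins) + 1L]] <<-
          list(jc = jc, local_prefix = prefix, local_term = local_term,
               foreign_prefix = edge_prefix, foreign_term = foreign_term)
        ensure_root(edge_prefix, foreign_term)
        child_addr <- attach_branch(edge_prefix, integer(),
                                    list(role = br$role, property = br$property,
                                         child = new_hop_node(br$child$term)))
        walk(br$child, edge_prefix, child_addr)
      }
    }
    invisible()
  }
  current_term <- function(prefix, addr) node_at_addr(service_trees[[prefix]], addr)$term
  edge_source_term <- function(br) {
    # the class on the foreign side of the join is the declared source of the
    # crossing association property: <prefix>:<Source>_<role>_<Target>
    sp <- split_term(br$property)
    src <- sub(paste0("_", br$role, "_.*$"), "", sp$local)
    term(sp$prefix, src)
  }
  root_prefix <- tree$prefix
  ensure_root(root_prefix, tree$term)
  walk(tree, root_prefix, integer())
  # de-duplicate joins (both branches may cross at the same pair)
  seen <- character(); uniq <- list()
  for (j in joins) {
    k <- paste(j$jc$local_class, j$jc$foreign_class)
    if (!k %in% seen) { seen <- c(seen, k); uniq[[length(uniq) + 1L]] <- j }
  }
  list(trees = service_trees, joins = uniq, local = root_prefix)
}

#' Federated path rewriting
#'
#' Finds paths in the join-merged association graph (where the classes of
#' each applied join condition form one traversal node) and splits each
#' combined rewriting at the join crossings into per-service expressions,
#' returning the service-specific hop trees together with the join
#' conditions that connect them. With a single service and no joins this
#' degenerates to [find_query_paths()].
#'
#' @param expr substituted query AST over UML terms of several models
#' @param merged merged `generated_ontology` with join equivalences applied
#' @param jcs list of the applied `join_condition`s
#' @param max_paths cap on paths per conjunct
#' @return list of `rewritten_query` candidates
#' @export
federated_find_paths <- function(expr, merged, jcs, max_paths = Inf) {
  graph <- association_graph(merged)
  trees <- rewrite_combinations(expr, graph, max_paths)
  lapply(trees, function(tr) {
    sp <- split_tree_by_service(tr, jcs)
    new_rewritten_query(trees = sp$trees,
                        joins = sp$joins, local = sp$local)
  })
}

#' Number of service-specific expressions of a rewritten query
#' @param rq a `rewritten_query`
#' @return integer count
#' @export
n_service_paths <- function(rq) length(rq$trees)

## ---- value re-insertion into rewritten queries ------------------------------

#' Re-insert stripped values into a rewritten query
#'
#' Each binding is matched to the attribute restriction it originated from
#' (the attribute term recorded at strip time, tracked through substitution
#' and path finding) and its comparison/literal restored on that restriction.
#' A binding whose attribute no longer occurs in any service expression, or
#' that would attach twice, is an error: values are conserved one-for-one.
#'
#' @param rq a `rewritten_query` built from the stripped query
#' @param bindings `value_bindings` recorded from the substituted query
#' @return the `rewritten_query` with restrictions restored
#' @export
reinsert_values_rewritten <- function(rq, bindings) {
  for (b in bindings) {
    if (length(b$values) != 1L)
      stop("unsupported: multiple value restrictions in one attribute filler")
    v <- b$values[[1]]
    placed <- FALSE
    for (p in names(rq$trees)) {
      res <- place_binding(rq$trees[[p]], b$attribute, v)
      if (res$placed) {
        if (placed) stop("value binding for ", b$attribute, " attached twice")
        rq$trees[[p]] <- res$node
        placed <- TRUE
      }
    }
    if (!placed)
      stop("orphaned value binding: attribute ", b$attribute,
           " was eliminated from the rewriting")
  }
  rq$exprs <- lapply(rq$trees, hop_tree_to_ce)
  rq
}

place_binding <- function(node, attr_term, v) {
  for (i in seq_along(node$attrs)) {
    a <- node$attrs[[i]]
    if (identical(a$term, attr_term) && is.null(a$literal)) {
      node$attrs[[i]]$op <- v$op
      node$attrs[[i]]$literal <- v$literal
      return(list(node = node, placed = TRUE))
    }
  }
  for (i in seq_along(node$branches)) {
    res <- place_binding(node$branches[[i]]$child, attr_term, v)
    if (res$placed) {
      node$branches[[i]]$child <- res$node
      return(list(node = node, placed = TRUE))
    }
  }
  list(node = node, placed = FALSE)
}

## ---- the full pipeline -----------------------------------------------------

#' Reformulate a concept-based query end to end
#'
#' Runs the full staged pipeline and retains every intermediate artifact.
#' Stage order: parse, ontology generation (module extraction, disjointness
#' stripping, UML-to-OWL), UML extraction (choice point), data-value
#' stripping, join discovery and application (federated case; choice point),
#' semantic validation, path finding (choice point), value re-insertion,
#' translation to the comprehension IR, normalization, and CQL/DCQL
#' emission. An unsatisfiable query halts at validation: the returned bundle
#' carries the diagnosis and no later artifacts. Other stage failures raise
#' errors labelled with their stage.
#'
#' @param text concept-based query text (or an already parsed AST)
#' @param models list of [information_model()]s (one = CQL, several = DCQL
#'   when the query spans services)
#' @param domain_ontology a [domain_ontology()]
#' @param policy a [choice_policy()]
#' @param max_paths cap on paths per conjunct
#' @return object of class `reformulation_result`: a list of stage artifacts
#'   (`query`, `ontologies`, `candidates`, `substitution`, `stripped`,
#'   `join_candidates`, `joins`, `validation`, `rewritings`, `rewritten`,
#'   `comprehension`, `normalized`, `target`, `xml`, plus `status`)
#' @export
reformulate_query <- function(text, models, domain_ontology,
                              policy = choice_policy("first"),
                              max_paths = 25L) {
  if (inherits(models, "information_model")) models <- list(models)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  out <- list(status = "complete")

  out$query <- stage("parsing",
    if (inherits(text, "oq_query")) text else parse_query(text))

  out$ontologies <- stage("ontology generation", lapply(models, function(m) {
    module <- strip_disjointness(extract_module(domain_ontology, model_concepts(m)))
    generate_ontology(m, module)
  }))
  names(out$ontologies) <- vapply(models, `[[`, character(1), "prefix")

  out$candidates <- stage("UML extraction", extract_uml(out$query, out$ontologies))
  sel <- stage("UML extraction",
               resolve_choice(policy, "extraction", out$candidates))
  out$substitution <- out$candidates[[sel]]
  substituted <- stage("UML extraction",
                       substitute_query(out$query, out$substitution))

  stripped <- stage("data values extraction", strip_values(substituted))
  out$stripped <- stripped

  used_prefixes <- unique(unname(out$substitution$prefixes))
  federated <- length(used_prefixes) > 1L

  if (federated) {
    merged <- stage("ontology merging",
                    merge_ontologies(out$ontologies[vapply(models, `[[`, character(1), "prefix")]))
    out$join_candidates <- stage("join discovery", discover_join_conditions(merged))
    ji <- stage("join discovery",
                resolve_choice(policy, "join", out$join_candidates, multiple = TRUE))
    out$joins <- out$join_candidates[ji]
    for (jc in out$joins) merged <- stage("join application", apply_join(merged, jc))
    active <- merged
  } else {
    out$join_candidates <- list(); out$joins <- list()
    active <- out$ontologies[[used_prefixes]]
  }

  out$validation <- stage("validation",
    is_satisfiable(query_to_ce(stripped$expr), active))
  if (!out$validation$satisfiable) {
    out$status <- "halted"
    out$failed_stage <- "validation"
    return(structure(out, class = "reformulation_result"))
  }

  out$rewritings <- stage("path finding",
    if (federated) federated_find_paths(stripped$expr, active, out$joins, max_paths)
    else find_query_paths(stripped$expr, active, max_paths))
  pi_ <- stage("path finding", resolve_choice(policy, "path", out$rewritings))
  rewritten <- out$rewritings[[pi_]]

  out$rewritten <- stage("data values addition",
    reinsert_values_rewritten(rewritten, stripped$bindings))

  out$comprehension <- stage("MCC translation",
    translate_mcc(out$rewritten, active))
  out$normalized <- stage("MCC normalization", normalize(out$comprehension))

  if (length(out$rewritten$trees) > 1L) {
    services <- vapply(models, function(m)
      m$service_url %||% paste0("http://", m$prefix, ".invalid/"), character(1))
    names(services) <- vapply(models, `[[`, character(1), "prefix")
    out$target <- stage("DCQL translation", from_mcc_dcql(out$normalized, services))
  } else {
    out$target <- stage("CQL translation", from_mcc_cql(out$normalized))
  }
  out$xml <- stage("XML emission", emit_xml(out$target))
  structure(out, class = "reformulation_result")
}

#' @export
print.reformulation_result <- function(x, ...) {
  cat("Reformulation", x$status, "\n")
  if (x$status == "halted") {
    cat("  halted at:", x$failed_stage, "-", x$validation$diagnosis, "\n")
  } else {
    cat("  target:", class(x$target)[1], "\n")
  }
  invisible(x)
}

#' Serialize a pipeline bundle as JSON for audit
#'
#' Renders each retained stage artifact textually (query syntax, candidate
#' substitutions, join conditions, rewritten expressions, the comprehension,
#' and the emitted XML) keyed by stage name.
#'
#' @param result a `reformulation_result`
#' @param path optional file to write to
#' @return JSON text (invisibly if `path` given)
#' @export
bundle_json <- function(result, path = NULL) {
  render_sub <- function(s) paste0(names(s$mapping), " -> ", s$mapping, collapse = "; ")
  doc <- list(
    status = result$status,
    query = if (!is.null(result$query)) q_render(result$query),
    candidates = lapply(result$candidates, render_sub),
    substitution = if (!is.null(result$substitution)) render_sub(result$substitution),
    stripped = if (!is.null(result$stripped)) q_render(result$stripped$expr),
    join_candidates = lapply(result$join_candidates, function(jc)
      paste0("(", jc$local_class, ", ", jc$foreign_class, ") on ",
             jc$local_attribute, " = ", jc$foreign_attribute)),
    validation = result$validation,
    rewritten = if (!is.null(result$rewritten))
      lapply(result$rewritten$exprs, ce_render),
    comprehension = if (!is.null(result$normalized)) render_mcc(result$normalized),
    xml = result$xml
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
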