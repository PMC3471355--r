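#' @title Lightweight reasoning services
#' @description Structural EL-style reasoning over generated ontologies:
#'   classification as reachability closure over named-class subsumptions,
#'   retrieval of UML elements for a concept, satisfiability of query
#'   expressions against the association graph, construction of that graph
#'   (one edge per existential restriction over a sub-property of
#'   `u:hasAssociation`, inherited edges included), deterministic simple-path
#'   enumeration, ontology merging, semantic join-condition discovery, and
#'   path metrics. On these ontologies the justification for two classes
#'   being connected through the transitive upper property is exactly an
#'   edge chain, so path search is direct graph traversal.
#' @name semantics
NULL

## ---- classification --------------------------------------------------------

named_super_terms <- function(expr) {
  # named superclasses entailed from the top-level structure of a superclass
  # expression: intersection members recursively, existentials contribute none
  if (expr$kind == "named") return(expr$term)
  if (expr$kind == "and") return(unlist(lapply(expr$args, named_super_terms)))
  character()
}

#' Classify a generated ontology
#'
#' Computes the reflexive-transitive closure of the asserted subsumptions
#' between named terms (intersection superclasses contribute each named
#' member; equivalences contribute both directions). Cyclic subsumptions are
#' reported as equivalence classes rather than errors.
#'
#' @param ontology a `generated_ontology`
#' @return an object of class `subsumption_hierarchy` with `$supers`, a named
#'   list mapping each term to its (reflexive) superclasses
#' @export
classify <- function(ontology) {
  edges <- list()
  terms <- character()
  add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  for (ax in ontology$axioms) {
    if (ax$kind == "sub_class" && ax$sub$kind == "named") {
      terms <- c(terms, ax$sub$term)
      for (s in named_super_terms(ax$super)) { add_edge(ax$sub$term, s); terms <- c(terms, s) }
    } else if (ax$kind == "equivalent") {
      add_edge(ax$a, ax$b); add_edge(ax$b, ax$a)
      terms <- c(terms, ax$a, ax$b)
    }
  }
  terms <- sort(unique(terms))
  adj <- split(
    vapply(edges, `[`, character(1), 2),
    factor(vapply(edges, `[`, character(1), 1), levels = terms)
  )
  supers <- lapply(terms, function(t) {
    seen <- t; queue <- t
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      nxt <- setdiff(unique(adj[[x]]), seen)
      seen <- c(seen, nxt); queue <- c(queue, nxt)
    }
    sort(seen)
  })
  names(supers) <- terms
  structure(list(terms = terms, supers = supers), class = "subsumption_hierarchy")
}

#' Is `a` subsumed by `b`?
#' @param hierarchy a `subsumption_hierarchy`
#' @param a,b terms
#' @return logical
#' @export
is_subsumed <- function(hierarchy, a, b) {
  if (!a %in% hierarchy$terms) return(a == b)
  b %in% hierarchy$supers[[a]]
}

#' All (reflexive) subclasses of a term
#' @param hierarchy a `subsumption_hierarchy`
#' @param b term
#' @return character vector
#' @export
subclasses_of <- function(hierarchy, b) {
  hierarchy$terms[vapply(hierarchy$terms, function(a) b %in% hierarchy$supers[[a]],
                         logical(1))]
}

#' @export
print.subsumption_hierarchy <- function(x, ...) {
  cat("Subsumption hierarchy over", length(x$terms), "terms\n")
  invisible(x)
}

#' UML elements annotated below a concept
#'
#' Returns the subclasses of `concept` that are also below `u:UMLClass`
#' (kind `"class"`) or `u:UMLAttribute` (kind `"attribute"`) — i.e. the model
#' elements whose annotations place them under the concept.
#'
#' @param concept concept term, e.g. `"n:Chromosome"`
#' @param hierarchy a classified `subsumption_hierarchy`
#' @param kind `"class"` or `"attribute"`
#' @return sorted character vector of UML terms
#' @export
uml_elements_for <- function(concept, hierarchy, kind = c("class", "attribute")) {
  kind <- match.arg(kind)
  if (!concept %in% hierarchy$terms) stop("unknown concept: ", concept)
  anchor <- if (kind == "class") uml_terms()$class else uml_terms()$attribute
  sort(intersect(subclasses_of(hierarchy, concept), subclasses_of(hierarchy, anchor)))
}

## ---- association graph -----------------------------------------------------

association_properties <- function(ontology) {
  u <- uml_terms()
  props <- character()
  for (ax in ontology$axioms)
    if (ax$kind == "sub_property" && ax$super == u$has_association)
      props <- c(props, ax$sub)
  unique(props)
}

role_names <- function(ontology) {
  out <- character(); subj <- character()
  for (ax in ontology$axioms)
    if (ax$kind == "annotation" && ax$property == "RoleName") {
      out <- c(out, ax$value); subj <- c(subj, ax$subject)
    }
  stats::setNames(out, subj)
}

equivalence_reps <- function(ontology) {
  # union-find over Equivalent Class axioms; representative = lexicographic min
  pairs <- Filter(function(a) a$kind == "equivalent", ontology$axioms)
  members <- unique(unlist(lapply(pairs, function(a) c(a$a, a$b))))
  rep <- stats::setNames(members, members)
  find <- function(x) { while (rep[[x]] != x) x <- rep[[x]]; x }
  for (p in pairs) {
    ra <- find(p$a); rb <- find(p$b)
    if (ra != rb) {
      lo <- min(ra, rb); hi <- max(ra, rb)
      rep[[hi]] <- lo
    }
  }
  vapply(members, find, character(1))
}

graph_rep <- function(graph, x) {
  if (x %in% names(graph$rep)) graph$rep[[x]] else x
}

#' Build the association graph of a (possibly merged) ontology
#'
#' One edge per existential restriction over a declared sub-property of
#' `u:hasAssociation`, including the explicit inherited-association axioms.
#' Classes joined by Equivalent Class axioms are collapsed to a single
#' traversal node, while edges retain the class terms (and hence the model
#' prefix) of their owning model.
#'
#' @param ontology a `generated_ontology`
#' @return object of class `association_graph` with `$nodes` (traversal
#'   nodes), `$edges` (data frame: source, target, property, role,
#'   src_node, dst_node) and `$rep` (term-to-node mapping for joined classes)
#' @export
association_graph <- function(ontology) {
  props <- association_properties(ontology)
  roles <- role_names(ontology)
  rep <- equivalence_reps(ontology)
  src <- dst <- prp <- character()
  for (ax in ontology$axioms) {
    if (ax$kind == "sub_class" && ax$sub$kind == "named" &&
        ax$super$kind == "some" && ax$super$prop %in% props &&
        ax$super$filler$kind == "named") {
      src <- c(src, ax$sub$term); dst <- c(dst, ax$super$filler$term)
      prp <- c(prp, ax$super$prop)
    }
  }
  hierarchy <- classify(ontology)
  classes <- subclasses_of(hierarchy, uml_terms()$class)
  classes <- setdiff(classes, uml_terms()$class)
  role <- unname(ifelse(prp %in% names(roles), roles[prp], term_local(prp)))
  to_node <- function(x) vapply(x, function(t) if (t %in% names(rep)) rep[[t]] else t,
                                character(1), USE.NAMES = FALSE)
  edges <- data.frame(source = src, target = dst, property = prp, role = role,
                      src_node = to_node(src), dst_node = to_node(dst),
                      stringsAsFactors = FALSE)
  # de-duplicate identical edges (declared + inherited can coincide after joins)
  edges <- unique(edges)
  nodes <- sort(unique(c(to_node(classes), edges$src_node, edges$dst_node)))
  structure(list(nodes = nodes, edges = edges, rep = rep),
            class = "association_graph")
}

#' @export
print.association_graph <- function(x, ...) {
  cat("Association graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

new_path <- function(start, edges) {
  nodes <- c(start, if (length(edges)) vapply(edges, `[[`, character(1), "target"))
  structure(list(start = start, edges = edges, classes = nodes), class = "oq_path")
}

#' Class sequence of a path
#' @param path an `oq_path`
#' @return character vector of class terms, start first
#' @export
path_classes <- function(path) path$classes

#' @export
print.oq_path <- function(x, ...) {
  if (!length(x$edges)) { cat(x$start, "(zero-hop)\n"); return(invisible(x)) }
  cat(paste(vapply(x$edges, function(e) paste0("-[", e$role, "]-> ", e$target),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

path_sort_key <- function(p) {
  paste(vapply(p$edges, `[[`, character(1), "property"), collapse = "|")
}

#' Enumerate simple association paths
#'
#' Depth-first enumeration of all simple (no node revisited) edge-labelled
#' paths between two classes, returned shortest-first with lexicographic
#' property-label tie-break; the result is complete whenever `max_paths` is
#' at least the total path count. `start == end` (up to join equivalence)
#' yields a single zero-hop path.
#'
#' @param graph an `association_graph`
#' @param start,end class terms present in the graph
#' @param max_paths maximum number of paths to return
#' @return list of `oq_path`
#' @export
find_paths <- function(graph, start, end, max_paths = Inf) {
  s <- graph_rep(graph, start); t <- graph_rep(graph, end)
  if (!s %in% graph$nodes) stop("start class not in graph: ", start)
  if (!t %in% graph$nodes) stop("end class not in graph: ", end)
  if (s == t) return(list(new_path(start, list())))
  out <- list()
  e <- graph$edges
  walk <- function(node, visited, acc) {
    idx <- which(e$src_node == node)
    for (i in idx[order(e$property[idx])]) {
      nxt <- e$dst_node[i]
      if (nxt %in% visited) next
      edge <- list(source = e$source[i], target = e$target[i],
                   property = e$property[i], role = e$role[i])
      if (nxt == t) {
        out[[length(out) + 1L]] <<- new_path(start, c(acc, list(edge)))
      } else {
        walk(nxt, c(visited, nxt), c(acc, list(edge)))
      }
    }
  }
  walk(s, s, list())
  if (!length(out)) return(list())
  len <- vapply(out, function(p) length(p$edges), integer(1))
  key <- vapply(out, path_sort_key, character(1))
  out <- out[order(len, key)]
  if (is.finite(max_paths)) out <- out[seq_len(min(length(out), max_paths))]
  out
}

reachable <- function(graph, start, end) {
  s <- graph_rep(graph, start); t <- graph_rep(graph, end)
  if (!s %in% graph$nodes || !t %in% graph$nodes) return(FALSE)
  if (s == t) return(TRUE)
  seen <- s; queue <- s
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    nxt <- setdiff(graph$edges$dst_node[graph$edges$src_node == x], seen)
    if (t %in% nxt) return(TRUE)
    seen <- c(seen, nxt); queue <- c(queue, nxt)
  }
  FALSE
}

## ---- satisfiability --------------------------------------------------------

attribute_owner <- function(ontology, attr_term) {
  u <- uml_terms()
  for (ax in ontology$axioms)
    if (ax$kind == "sub_class" && ax$sub$kind == "named" &&
        ax$super$kind == "some" && ax$super$prop == u$has_attribute &&
        ax$super$filler$kind == "named" && ax$super$filler$term == attr_term)
      return(ax$sub$term)
  NULL
}

#' Satisfiability of a (stripped, substituted) query expression
#'
#' An expression is unsatisfiable exactly when it demands an association hop
#' absent from the reachability relation of the association graph, or an
#' attribute not attached to (or inherited by) the class it constrains. The
#' diagnosis names the failing conjunct. Unknown terms raise an error — they
#' are a different failure mode than unsatisfiability.
#'
#' @param expr a class expression (`oq_ce`) over UML terms
#' @param ontology a `generated_ontology` (single or merged, joins applied)
#' @return list with `satisfiable` (logical) and `diagnosis` (character)
#' @export
is_satisfiable <- function(expr, ontology) {
  graph <- association_graph(ontology)
  hierarchy <- classify(ontology)
  u <- uml_terms()
  known_class <- function(t) t %in% hierarchy$terms &&
    is_subsumed(hierarchy, t, u$class)
  fail <- NULL
  flat_and <- function(e) {
    if (e$kind != "and") return(list(e))
    do.call(c, lapply(e$args, flat_and))
  }
  check <- function(expr) {
    parts <- flat_and(expr)
    root <- NULL
    for (p in parts) if (p$kind == "named") { root <- p$term; break }
    if (is.null(root)) stop("expression has no named root class")
    if (!known_class(root)) stop("unknown term: ", root)
    for (p in parts) {
      if (!is.null(fail)) return(invisible())
      if (p$kind == "some" && p$prop != u$has_attribute) {
        sub <- p$filler
        subparts <- flat_and(sub)
        tgt <- NULL
        for (q in subparts) if (q$kind == "named") { tgt <- q$term; break }
        if (is.null(tgt)) stop("association filler has no named class")
        if (!known_class(tgt)) stop("unknown term: ", tgt)
        if (!reachable(graph, root, tgt)) {
          fail <<- paste0("no association path from ", root, " to ", tgt)
          return(invisible())
        }
        check(sub)
      } else if (p$kind == "some" && p$prop == u$has_attribute) {
        f <- p$filler
        aterm <- if (f$kind == "named") f$term
                 else if (f$kind == "and") f$args[[1]]$term
                 else stop("malformed attribute restriction")
        if (!aterm %in% hierarchy$terms) stop("unknown term: ", aterm)
        owner <- attribute_owner(ontology, aterm)
        if (is.null(owner) || !is_subsumed(hierarchy, root, owner))
          fail <<- paste0("attribute ", aterm, " is not attached to class ", root)
      }
    }
    invisible()
  }
  check(expr)
  list(satisfiable = is.null(fail),
       diagnosis = if (is.null(fail)) character() else fail)
}

## ---- merging & joins -------------------------------------------------------

#' Merge generated ontologies
#'
#' The merged ontology simply contains all the axioms of the inputs, in
#' input order; model prefixes keep terms from colliding and must be
#' pairwise distinct.
#'
#' @param ontologies list of `generated_ontology`
#' @return a `generated_ontology`
#' @export
merge_ontologies <- function(ontologies) {
  if (inherits(ontologies, "generated_ontology")) ontologies <- list(ontologies)
  prefixes <- unlist(lapply(ontologies, `[[`, "prefixes"))
  if (anyDuplicated(prefixes)) stop("prefix collision: ", prefixes[duplicated(prefixes)][1])
  axioms <- do.call(c, lapply(ontologies, `[[`, "axioms"))
  # a single transitivity declaration survives the merge
  is_trans <- vapply(axioms, function(a) a$kind == "transitive", logical(1))
  if (sum(is_trans) > 1L) axioms <- axioms[-which(is_trans)[-1L]]
  new_generated_ontology(
    iri = paste0("http://ontoquery.example.org/ontology/merged-",
                 paste(prefixes, collapse = "-")),
    prefixes = prefixes,
    imports = unique(unlist(lapply(ontologies, `[[`, "imports"))),
    axioms = axioms
  )
}

concept_annotation_sets <- function(ontology, subjects) {
  n_terms_in <- function(expr) {
    if (expr$kind == "named")
      return(if (term_prefix(expr$term) == "n") expr$term else character())
    if (expr$kind %in% c("and", "or"))
      return(unlist(lapply(expr$args, n_terms_in)))
    if (expr$kind == "some") return(n_terms_in(expr$filler))
    character()
  }
  out <- stats::setNames(vector("list", length(subjects)), subjects)
  for (ax in ontology$axioms) {
    if (ax$kind == "sub_class" && ax$sub$kind == "named" &&
        ax$sub$term %in% subjects) {
      ks <- n_terms_in(ax$super)
      if (length(ks)) out[[ax$sub$term]] <- sort(unique(c(out[[ax$sub$term]], ks)))
    }
  }
  out
}

new_join_condition <- function(local_class, foreign_class, local_attribute,
                               foreign_attribute, local_service, foreign_service,
                               predicate = "EQUAL_TO") {
  structure(list(local_class = local_class, foreign_class = foreign_class,
                 local_attribute = local_attribute,
                 foreign_attribute = foreign_attribute,
                 predicate = predicate,
                 local_service = local_service, foreign_service = foreign_service),
            class = "join_condition")
}

#' @export
print.join_condition <- function(x, ...) {
  cat("Join: (", x$local_class, ", ", x$foreign_class, ") on ",
      x$local_attribute, " ", x$predicate, " ", x$foreign_attribute, "\n", sep = "")
  invisible(x)
}

class_attributes <- function(ontology, class_term) {
  u <- uml_terms()
  out <- character()
  for (ax in ontology$axioms)
    if (ax$kind == "sub_class" && ax$sub$kind == "named" &&
        ax$sub$term == class_term && ax$super$kind == "some" &&
        ax$super$prop == u$has_attribute && ax$super$filler$kind == "named")
      out <- c(out, ax$super$filler$term)
  out
}

#' Discover semantic join conditions in a merged ontology
#'
#' Two classes from different models are semantically equivalent when they
#' are annotated with identical concept sets; the candidate joins are the
#' attribute pairs of such class pairs whose own concept sets are also
#' identical. One join condition is returned per (class pair, attribute
#' pair), with the default predicate `EQUAL_TO`, ordered deterministically.
#' Swapping the model order yields the same unordered pairs.
#'
#' @param merged a merged `generated_ontology` spanning at least two prefixes
#' @return list of `join_condition`
#' @export
discover_join_conditions <- function(merged) {
  if (length(merged$prefixes) < 2L)
    stop("join discovery needs a merged ontology spanning >= 2 models")
  hierarchy <- classify(merged)
  u <- uml_terms()
  classes <- setdiff(subclasses_of(hierarchy, u$class), u$class)
  attrs   <- setdiff(subclasses_of(hierarchy, u$attribute), u$attribute)
  csets <- concept_annotation_sets(merged, classes)
  asets <- concept_annotation_sets(merged, attrs)
  out <- list()
  pfx <- merged$prefixes
  for (i in seq_along(pfx)) for (j in seq_along(pfx)) {
    if (i >= j) next
    ci <- sort(classes[term_prefix(classes) == pfx[i]])
    cj <- sort(classes[term_prefix(classes) == pfx[j]])
    for (a in ci) for (b in cj) {
      if (!length(csets[[a]]) || !identical(csets[[a]], csets[[b]])) next
      aa <- sort(class_attributes(merged, a))
      bb <- sort(class_attributes(merged, b))
      for (x in aa) for (y in bb) {
        if (length(asets[[x]]) && identical(asets[[x]], asets[[y]]))
          out[[length(out) + 1L]] <- new_join_condition(a, b, x, y, pfx[i], pfx[j])
      }
    }
  }
  key <- vapply(out, function(jc)
    paste(jc$local_class, jc$foreign_class, jc$local_attribute, jc$foreign_attribute),
    character(1))
  out[order(key)]
}

#' Apply a join condition to a merged ontology
#'
#' Adds an Equivalent Class axiom between the join's two classes (idempotent)
#' so that association paths can traverse from one model into the other
#' through the joined node pair.
#'
#' @param merged a merged `generated_ontology`
#' @param jc a `join_condition` discovered from `merged`
#' @return the merged ontology with the equivalence added
#' @export
apply_join <- function(merged, jc) {
  stopifnot(inherits(jc, "join_condition"))
  hierarchy <- classify(merged)
  if (!jc$local_class %in% hierarchy$terms || !jc$foreign_class %in% hierarchy$terms)
    stop("join condition does not apply to this ontology")
  already <- any(vapply(merged$axioms, function(a)
    a$kind == "equivalent" &&
      setequal(c(a$a, a$b), c(jc$local_class, jc$foreign_class)), logical(1)))
  if (!already)
    merged$axioms <- c(merged$axioms, list(ax_equiv(jc$local_class, jc$foreign_class)))
  merged
}

## ---- path metrics ----------------------------------------------------------

#' Path metrics of an association graph
#'
#' Enumerates every simple edge-labelled path (at least one hop) between
#' every ordered pair of distinct nodes. `longest_path` is the maximum node
#' count over all such paths; `avg_nodes_per_path` the mean node count over
#' all paths; `avg_paths_per_journey` the mean path count over journeys
#' (ordered pairs with at least one path — pairs with none are excluded from
#' the denominator). An edgeless graph scores zero on all three.
#'
#' @param graph an `association_graph`
#' @return object of class `path_metrics` with the three summary values and
#'   a `$journeys` data frame (from, to, n_paths, total_nodes)
#' @export
path_metrics <- function(graph) {
  nodes <- graph$nodes
  e <- graph$edges
  journeys <- list()
  all_counts <- integer(); all_nodes <- integer()
  for (s in nodes) {
    # DFS from s collecting every simple path
    paths_to <- new.env(parent = emptyenv())
    walk <- function(node, visited, nhops) {
      idx <- which(e$src_node == node)
      for (i in idx) {
        nxt <- e$dst_node[i]
        if (nxt %in% visited) next
        key <- nxt
        cur <- if (!is.null(paths_to[[key]])) paths_to[[key]] else c(0L, 0L)
        paths_to[[key]] <- c(cur[1] + 1L, cur[2] + nhops + 2L)  # count, total nodes
        walk(nxt, c(visited, nxt), nhops + 1L)
      }
    }
    walk(s, s, 0L)
    for (t in ls(paths_to)) {
      cnt <- paths_to[[t]]
      journeys[[length(journeys) + 1L]] <-
        data.frame(from = s, to = t, n_paths = cnt[1], total_nodes = cnt[2],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(journeys)) {
    return(structure(list(longest_path = 0, avg_nodes_per_path = 0,
                          avg_paths_per_journey = 0,
                          journeys = data.frame(from = character(), to = character(),
                                                n_paths = integer(),
                                                total_nodes = integer())),
                     class = "path_metrics"))
  }
  j <- do.call(rbind, journeys)
  # longest path needs max node count, recompute via per-pair enumeration depth
  longest <- max_path_nodes(graph)
  structure(list(
    longest_path = longest,
    avg_nodes_per_path = sum(j$total_nodes) / sum(j$n_paths),
    avg_paths_per_journey = mean(j$n_paths),
    journeys = j
  ), class = "path_metrics")
}

max_path_nodes <- function(graph) {
  e <- graph$edges
  best <- 0L
  walk <- function(node, visited) {
    best <<- max(best, length(visited))
    idx <- which(e$src_node == node)
    for (i in idx) {
      nxt <- e$dst_node[i]
      if (!nxt %in% visited) walk(nxt, c(visited, nxt))
    }
  }
  for (s in graph$nodes) walk(s, s)
  if (best < 2L) 0L else best
}

#' @export
print.path_metrics <- function(x, ...) {
  cat("Longest path:", x$longest_path, "nodes\n")
  cat("Average nodes per path:", format(x$avg_nodes_per_path, digits = 4), "\n")
  cat("Average paths per journey:", format(x$avg_paths_per_journey, digits = 4), "\n")
  invisible(x)
}

#' Write a per-journey metrics report as CSV
#'
#' One row per journey (from, to, path count, mean nodes per path) plus a
#' `summary` row carrying the three aggregate metrics.
#'
#' @param metrics a `path_metrics`
#' @param path output file path
#' @return the file path, invisibly
#' @export
write_metrics_csv <- function(metrics, path) {
  j <- metrics$journeys
  rows <- data.frame(
    journey = if (nrow(j)) paste(j$from, "->", j$to) else character(),
    n_paths = j$n_paths,
    avg_nodes = if (nrow(j)) j$total_nodes / j$n_paths else numeric(),
    stringsAsFactors = FALSE
  )
  rows <- rbind(rows, data.frame(
    journey = "summary",
    n_paths = metrics$avg_paths_per_journey,
    avg_nodes = metrics$avg_nodes_per_path,
    stringsAsFactors = FALSE
  ))
  rows$longest_path <- c(rep(NA, nrow(rows) - 1L), metrics$longest_path)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
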