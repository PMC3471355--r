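# Shared fixtures and independent oracles for the suite.

fx <- list(
  cabio = fixture_cabio(),
  pir = fixture_pir(),
  dom = fixture_domain_ontology()
)

gen_fixture_ontology <- function(model, dom = fx$dom) {
  generate_ontology(model, strip_disjointness(extract_module(dom, model_concepts(model))))
}

onto_cabio <- gen_fixture_ontology(fx$cabio)
onto_pir <- gen_fixture_ontology(fx$pir)

# ---- random digraphs (no parallel edges) as association graphs --------------

random_digraph_model <- function(n, p, seed) {
  generate_synthetic_model(n_classes = n, depth = 1, assoc_density = p,
                           vocab = fx$dom, seed = seed)
}

# independent simple-path oracle: igraph's exhaustive enumeration
igraph_simple_paths <- function(graph, from, to) {
  e <- graph$edges
  if (!nrow(e)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$src_node, to = e$dst_node), directed = TRUE,
    vertices = data.frame(name = graph$nodes))
  paths <- igraph::all_simple_paths(g, from = from, to = to, mode = "out")
  lapply(paths, function(p) igraph::as_ids(p))
}

# independent reachability-closure oracle for classification
igraph_closure <- function(edges, terms) {
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  d <- igraph::distances(g, mode = "out")
  out <- lapply(terms, function(t) sort(terms[is.finite(d[t, ])]))
  names(out) <- terms
  out
}

# brute-force pairwise concept subsumption (reflexive) in a domain ontology
dom_subsumes <- function(onto, a, b) b %in% concept_ancestors(onto, a)

# ---- random query ASTs -------------------------------------------------------

random_query_ast <- function(seed, max_depth = 3) {
  set.seed(seed)
  concepts <- c("Alpha", "Beta", "Gamma", "Delta")
  attrs <- c("Name", "Code")
  rand_attr_node <- function() {
    if (runif(1) < 0.7) {
      q_attr(q_and(list(q_concept(sample(attrs, 1)),
                        q_value(sample(c("EQUAL_TO", "LESS_THAN", "LIKE"), 1),
                                paste0("x", sample(1:9, 1))))))
    } else q_attr(q_concept(sample(attrs, 1)))
  }
  rand_expr <- function(depth) {
    parts <- list(q_concept(sample(concepts, 1)))
    n_extra <- sample(0:2, 1)
    for (i in seq_len(n_extra)) {
      roll <- runif(1)
      if (roll < 0.4 && depth < max_depth) {
        parts[[length(parts) + 1L]] <- q_assoc(NULL, rand_expr(depth + 1))
      } else if (roll < 0.6 && depth < max_depth) {
        parts[[length(parts) + 1L]] <- q_assoc(paste0("role", sample(1:5, 1)),
                                               rand_expr(depth + 1))
      } else {
        parts[[length(parts) + 1L]] <- rand_attr_node()
      }
    }
    q_and(parts)
  }
  rand_expr(1)
}

count_values <- function(x) {
  n <- 0L
  walk <- function(y) {
    if (y$kind == "value") n <<- n + 1L
    if (!is.null(y$args)) lapply(y$args, walk)
    if (!is.null(y$filler)) walk(y$filler)
    invisible()
  }
  walk(x)
  n
}

# ---- random flat/nested comprehensions over a synthetic store ----------------

random_comprehension_case <- function(seed) {
  set.seed(seed)
  model <- generate_synthetic_model(n_classes = 5, depth = 2, assoc_density = 0.3,
                                    vocab = fx$dom, seed = seed, prefix = "syn")
  store <- build_store(model, n_per_class = 2, seed = seed + 1000)
  onto <- gen_fixture_ontology(model)
  graph <- association_graph(onto)
  catalog <- ontoquery:::name_catalog(onto)
  fresh <- ontoquery:::new_var_counter()
  mv <- ontoquery:::mcc_var; mg <- ontoquery:::mcc_gen
  me <- ontoquery:::mcc_extent; mp <- ontoquery:::mcc_path
  mf <- ontoquery:::mcc_filter; ml <- ontoquery:::mcc_lit
  # random chain of role hops starting at a random class, nested with
  # probability 1/2 at each hop to exercise unnesting
  build <- function(node, depth) {
    v <- fresh()
    quals <- list(mg(v, me(catalog$class_name[[node]])))
    cls_local <- split_term(node)$local
    cls <- model_class(model, cls_local)
    for (at in cls$attributes) {
      if (runif(1) < 0.3)
        quals[[length(quals) + 1L]] <- mf(mp(v, at$name), "EQUAL_TO",
                                          ml(sample(c("alpha", "17"), 1)))
    }
    out_edges <- graph$edges[graph$edges$src_node == node, , drop = FALSE]
    if (nrow(out_edges) && depth < 3 && runif(1) < 0.7) {
      i <- sample(nrow(out_edges), 1)
      w <- fresh()
      quals[[length(quals) + 1L]] <- mg(w, mp(v, out_edges$role[i]))
      child <- build(out_edges$target[i], depth + 1)
      if (runif(1) < 0.5) {
        quals[[length(quals) + 1L]] <- mg(w, child)          # nested
      } else {
        ch <- child$qualifiers
        hv <- child$header$var
        ch <- lapply(ch, ontoquery:::subst_var, from = hv, to = w)
        quals <- c(quals, ch)                                 # pre-flattened
      }
    }
    comprehension("bag", mv(v), quals)
  }
  start <- sample(graph$nodes, 1)
  list(comp = build(start, 1), store = store)
}

bag_ids <- function(bag) sort(vapply(bag, function(o)
  if (is.list(o)) o$id else as.character(o), character(1)))

# the hops of a single-chain hop tree, outermost first
unlist_branches <- function(tree) {
  out <- list()
  node <- tree
  while (length(node$branches)) {
    out[[length(out) + 1L]] <- node$branches[[1]]
    node <- node$branches[[1]]$child
  }
  out
}
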