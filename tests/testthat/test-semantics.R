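test_that("classification reproduces the fixture hierarchies", {
  h <- classify(onto_cabio)
  expect_true(is_subsumed(h, "cabio:SNPPhysicalLocation", "cabio:Location"))
  expect_true(is_subsumed(h, "cabio:SNPPhysicalLocation", "u:UMLClass"))
  expect_true(is_subsumed(h, "cabio:SNPPhysicalLocation", "n:Location"))
  expect_false(is_subsumed(h, "cabio:Location", "cabio:SNPPhysicalLocation"))
})

test_that("a single subsumption classifies to exactly its closure", {
  o <- ontoquery:::new_generated_ontology("iri", "x", character(),
         list(ax_transitive("u:hasAssociation"), ax_sub("x:A", "x:B")))
  h <- classify(o)
  expect_setequal(h$supers[["x:A"]], c("x:A", "x:B"))
  expect_setequal(h$supers[["x:B"]], "x:B")
})

test_that("classification equals reachability closure on random DAGs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    terms <- paste0("x:T", 1:n)
    ax <- list(ax_transitive("u:hasAssociation"))
    edges <- data.frame(from = character(), to = character())
    for (k in 1:50) {
      ij <- sort(sample(n, 2))          # edge low -> high keeps it acyclic
      ax[[length(ax) + 1L]] <- ax_sub(terms[ij[1]], terms[ij[2]])
      edges <- rbind(edges, data.frame(from = terms[ij[1]], to = terms[ij[2]]))
    }
    h <- classify(ontoquery:::new_generated_ontology("iri", "x", character(), ax))
    oracle <- igraph_closure(unique(edges), terms)
    for (t in intersect(h$terms, terms))
      expect_setequal(h$supers[[t]], oracle[[t]])
  }
})

test_that("cyclic subsumptions surface as equivalence classes", {
  o <- ontoquery:::new_generated_ontology("iri", "x", character(),
         list(ax_sub("x:A", "x:B"), ax_sub("x:B", "x:A")))
  h <- classify(o)
  expect_true(is_subsumed(h, "x:A", "x:B") && is_subsumed(h, "x:B", "x:A"))
})

test_that("uml_elements_for retrieves annotated classes and attributes", {
  h <- classify(onto_cabio)
  expect_identical(uml_elements_for("n:Chromosome", h, "class"), "cabio:Chromosome")
  expect_identical(uml_elements_for("n:Name", h, "attribute"), "cabio:Chromosome_number")
  # a concept annotating no element of the requested kind yields the empty set
  expect_length(uml_elements_for("n:Gene_Symbol", h, "class"), 0L)
  expect_error(uml_elements_for("n:NotAThing", h, "class"), "unknown concept")
})

test_that("the association graph has one edge per existential, inherited included", {
  g <- association_graph(onto_cabio)
  hit <- g$edges[g$edges$source == "cabio:SNPPhysicalLocation" &
                 g$edges$target == "cabio:Chromosome", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$property, "cabio:Location_chromosome_Chromosome")
  expect_identical(hit$role, "chromosome")
  # edgeless model
  m <- information_model("p", "1", "x",
                         classes = list(class_spec("A", annotation("Gene"))))
  g0 <- association_graph(gen_fixture_ontology(m))
  expect_identical(nrow(g0$edges), 0L)
  # chain of k classes: k-1 declared edges plus inherited ones per the oracle
  k <- 5
  classes <- lapply(1:k, function(i) class_spec(paste0("C", i), annotation("Gene")))
  assocs <- lapply(1:(k - 1), function(i)
    association_spec(paste0("C", i), paste0("C", i + 1), paste0("to", i + 1)))
  chain <- information_model("p", "1", "x", classes = classes, associations = assocs)
  gc <- association_graph(gen_fixture_ontology(chain))
  expect_identical(nrow(gc$edges), as.integer(k - 1))
})

test_that("find_paths reproduces the worked-example class sequences", {
  g <- association_graph(onto_cabio)
  p1 <- find_paths(g, "cabio:SNP", "cabio:Chromosome")
  expect_gte(length(p1), 1L)
  expect_identical(path_classes(p1[[1]]),
                   c("cabio:SNP", "cabio:SNPPhysicalLocation", "cabio:Chromosome"))
  p2 <- find_paths(g, "cabio:NucleicAcidSequence", "cabio:Protein")
  expect_identical(path_classes(p2[[1]]),
                   c("cabio:NucleicAcidSequence", "cabio:Gene", "cabio:Protein"))
  # start == end gives the single zero-hop path
  p0 <- find_paths(g, "cabio:Gene", "cabio:Gene")
  expect_length(p0, 1L)
  expect_length(p0[[1]]$edges, 0L)
  # no path -> empty collection
  expect_length(find_paths(g, "cabio:Chromosome", "cabio:Protein"), 0L)
})

test_that("find_paths equals exhaustive enumeration on 100 random digraphs", {
  for (seed in 1:100) {
    n <- sample(4:12, 1)
    m <- random_digraph_model(n, 1.5 / n, seed)
    g <- association_graph(gen_fixture_ontology(m))
    nodes <- g$nodes
    from <- nodes[1 + seed %% length(nodes)]
    to <- nodes[1 + (seed + 2) %% length(nodes)]
    if (from == to) next
    mine <- lapply(find_paths(g, from, to), path_classes)
    oracle <- igraph_simple_paths(g, from, to)
    key <- function(p) paste(p, collapse = ">")
    expect_setequal(vapply(mine, key, character(1)),
                    vapply(oracle, key, character(1)))
  }
})

test_that("paths come back shortest-first and max_paths truncates", {
  # two routes A->C: direct and via B
  m <- information_model("p", "1", "x",
    classes = lapply(c("A", "B", "C"), function(x) class_spec(x, annotation("Gene"))),
    associations = list(association_spec("A", "C", "direct"),
                        association_spec("A", "B", "viaB"),
                        association_spec("B", "C", "onC")))
  g <- association_graph(gen_fixture_ontology(m))
  ps <- find_paths(g, "x:A", "x:C")
  expect_length(ps, 2L)
  expect_length(ps[[1]]$edges, 1L)
  expect_length(ps[[2]]$edges, 2L)
  expect_length(find_paths(g, "x:A", "x:C", max_paths = 1), 1L)
})

test_that("merging is axiom-union, commutative up to multiset, and guards prefixes", {
  merged <- merge_ontologies(list(onto_cabio, onto_pir))
  expect_identical(length(merged$axioms),
                   length(onto_cabio$axioms) + length(onto_pir$axioms) - 1L)
  h <- classify(merged)
  expect_true("cabio:Protein" %in% h$terms && "pir:Protein" %in% h$terms)
  ba <- merge_ontologies(list(onto_pir, onto_cabio))
  key <- function(o) sort(vapply(o$axioms, axiom_render, character(1)))
  expect_identical(key(merged), key(ba))
  expect_identical(merge_ontologies(list(onto_cabio))$axioms, onto_cabio$axioms)
  expect_error(merge_ontologies(list(onto_cabio, onto_cabio)), "prefix collision")
})

test_that("join discovery finds exactly the shared-concept class/attribute pairs", {
  merged <- merge_ontologies(list(onto_cabio, onto_pir))
  jcs <- discover_join_conditions(merged)
  expect_length(jcs, 2L)
  pairs <- vapply(jcs, function(j) paste(j$local_class, j$foreign_class), character(1))
  expect_setequal(pairs, c("cabio:Gene pir:Gene", "cabio:Protein pir:Protein"))
  gene <- jcs[[which(pairs == "cabio:Gene pir:Gene")]]
  expect_identical(gene$local_attribute, "cabio:Gene_symbol")
  expect_identical(gene$foreign_attribute, "pir:Gene_name")
  prot <- jcs[[which(pairs == "cabio:Protein pir:Protein")]]
  expect_identical(prot$local_attribute, "cabio:Protein_uniProtCode")
  expect_identical(prot$foreign_attribute, "pir:Protein_uniprotkbEntryName")
  expect_true(all(vapply(jcs, function(j) j$predicate == "EQUAL_TO", logical(1))))
  # swapping model order yields the same unordered pairs
  jcs2 <- discover_join_conditions(merge_ontologies(list(onto_pir, onto_cabio)))
  unordered <- function(js) sort(vapply(js, function(j)
    paste(sort(c(j$local_class, j$foreign_class)), collapse = "|"), character(1)))
  expect_identical(unordered(jcs), unordered(jcs2))
})

test_that("self-merge yields mirror joins; disjoint vocabularies yield none", {
  twin <- fx$pir; twin$prefix <- "pir2"
  jcs <- discover_join_conditions(
    merge_ontologies(list(onto_pir, gen_fixture_ontology(twin))))
  mirrors <- vapply(jcs, function(j)
    ontoquery:::term_local(j$local_class) == ontoquery:::term_local(j$foreign_class),
    logical(1))
  # every annotated class with an annotated attribute has its mirror pair
  expect_true(all(c("Protein", "Gene", "Organism") %in%
    ontoquery:::term_local(vapply(jcs[mirrors], `[[`, character(1), "local_class"))))
  other <- information_model("Other", "1", "oth", classes = list(
    class_spec("Band", annotation("Chromosome_Band"), attributes = list(
      attribute_spec("label", "string", annotation("Chromosome_Band"))))))
  jnone <- discover_join_conditions(
    merge_ontologies(list(onto_pir, gen_fixture_ontology(other))))
  expect_length(jnone, 0L)
})

test_that("applying a join connects the models, idempotently", {
  merged <- merge_ontologies(list(onto_cabio, onto_pir))
  g0 <- association_graph(merged)
  expect_false(ontoquery:::reachable(g0, "cabio:NucleicAcidSequence", "pir:Organism"))
  jcs <- discover_join_conditions(merged)
  prot <- jcs[[2]]
  joined <- apply_join(merged, prot)
  g1 <- association_graph(joined)
  expect_true(ontoquery:::reachable(g1, "cabio:NucleicAcidSequence", "pir:Organism"))
  expect_identical(apply_join(joined, prot)$axioms, joined$axioms)
})

test_that("path metrics: chain, edgeless, and random graphs vs brute force", {
  k <- 5
  classes <- lapply(1:k, function(i) class_spec(paste0("C", i), annotation("Gene")))
  assocs <- lapply(1:(k - 1), function(i)
    association_spec(paste0("C", i), paste0("C", i + 1), paste0("to", i + 1)))
  chain <- information_model("p", "1", "x", classes = classes, associations = assocs)
  pm <- path_metrics(association_graph(gen_fixture_ontology(chain)))
  expect_identical(pm$longest_path, 5L)
  expect_identical(pm$avg_paths_per_journey, 1)
  # edgeless
  lone <- information_model("p", "1", "x",
                            classes = list(class_spec("A", annotation("Gene"))))
  pm0 <- path_metrics(association_graph(gen_fixture_ontology(lone)))
  expect_identical(unlist(pm0[c("longest_path", "avg_nodes_per_path",
                                "avg_paths_per_journey")], use.names = FALSE),
                   c(0, 0, 0))
  # random graphs vs an independent enumerator
  for (seed in 1:15) {
    n <- sample(3:9, 1)
    g <- association_graph(gen_fixture_ontology(random_digraph_model(n, 1.5 / n, seed)))
    pm <- path_metrics(g)
    # oracle: enumerate all simple paths between all ordered pairs via igraph
    all_paths <- list()
    for (a in g$nodes) for (b in g$nodes) {
      if (a == b) next
      for (p in igraph_simple_paths(g, a, b))
        all_paths[[length(all_paths) + 1L]] <- p
    }
    if (!length(all_paths)) {
      expect_identical(pm$longest_path, 0L)
      next
    }
    lens <- vapply(all_paths, length, integer(1))
    expect_identical(as.integer(pm$longest_path), max(lens))
    expect_equal(pm$avg_nodes_per_path, mean(lens))
    journeys <- table(vapply(all_paths, function(p)
      paste(p[1], p[length(p)]), character(1)))
    expect_equal(pm$avg_paths_per_journey, mean(as.numeric(journeys)))
  }
})

test_that("satisfiability tracks the association graph and attribute attachment", {
  # Query 1 after stripping, over the caBIO ontology
  expr <- query_to_ce(q_and(list(
    q_concept("cabio:SNP"),
    q_assoc(NULL, q_and(list(q_concept("cabio:Chromosome"),
                             q_attr(q_concept("cabio:Chromosome_number"))))))))
  res <- is_satisfiable(expr, onto_cabio)
  expect_true(res$satisfiable)
  # an attribute of an unrelated class is diagnosed
  bad <- query_to_ce(q_and(list(q_concept("cabio:SNP"),
                                q_attr(q_concept("cabio:Chromosome_number")))))
  res2 <- is_satisfiable(bad, onto_cabio)
  expect_false(res2$satisfiable)
  expect_match(res2$diagnosis, "not attached")
  # a missing association is diagnosed with the class pair
  unreach <- query_to_ce(q_and(list(q_concept("cabio:Chromosome"),
                                    q_assoc(NULL, q_concept("cabio:Protein")))))
  res3 <- is_satisfiable(unreach, onto_cabio)
  expect_false(res3$satisfiable)
  expect_match(res3$diagnosis, "no association path")
  # unknown terms are an error, not unsatisfiability
  expect_error(is_satisfiable(query_to_ce(q_concept("cabio:Nope")), onto_cabio),
               "unknown term")
})

test_that("randomly generated graph-walking expressions are always satisfiable", {
  g <- association_graph(onto_cabio)
  for (seed in 1:20) {
    set.seed(seed)
    # random walk from a random node builds a satisfiable expression
    start <- sample(g$nodes, 1)
    expr <- q_concept(start)
    cur <- start
    for (step in 1:2) {
      nxt <- g$edges[g$edges$src_node == cur, , drop = FALSE]
      if (!nrow(nxt)) break
      i <- sample(nrow(nxt), 1)
      expr <- q_and(list(expr, q_assoc(NULL, q_concept(nxt$target[i]))))
      cur <- nxt$dst_node[i]
    }
    expect_true(is_satisfiable(query_to_ce(expr), onto_cabio)$satisfiable)
  }
})
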