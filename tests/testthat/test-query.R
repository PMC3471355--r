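test_that("the worked-example query texts parse to the expected trees", {
  q1 <- parse_query(fixture_query(1))
  expect_identical(q1$kind, "and")
  expect_identical(q1$args[[1]]$name, "Single_Nucleotide_Polymorphisms")
  a <- q1$args[[2]]
  expect_identical(a$kind, "assoc")
  expect_null(a$prop)
  filler <- a$filler
  expect_identical(filler$args[[1]]$name, "Chromosome")
  attr_node <- filler$args[[2]]
  expect_identical(attr_node$kind, "attr")
  expect_identical(attr_node$filler$args[[1]]$name, "Name")
  expect_identical(attr_node$filler$args[[2]]$op, "EQUAL_TO")
  expect_identical(attr_node$filler$args[[2]]$literal, "17")
  q2 <- parse_query(fixture_query(2))
  expect_length(q2$args, 3L)
  # a bare concept parses to a leaf
  expect_identical(parse_query("Gene")$kind, "concept")
})

test_that("syntax errors report their position", {
  expect_error(parse_query("Gene and (Chromosome"), "offset|end of query")
  expect_error(parse_query("Gene and"), "end of query")
  expect_error(parse_query("Gene ??"), "offset 6")
  expect_error(parse_query('hasValue value "unterminated'), "unterminated")
})

test_that("value restrictions are only legal inside attribute fillers", {
  expect_error(parse_query('Gene and hasValue value "x"'), "outside an attribute")
  expect_silent(parse_query('Gene and hasAttribute some (Name and hasValue value "x")'))
  expect_error(parse_query('Gene and hasAttribute some (hasValue value "x")'),
               "must contain a concept")
})

test_that("comparison operators map onto the CQL predicate enum", {
  for (case in list(c("<", "LESS_THAN"), c("<=", "LESS_THAN_EQUAL_TO"),
                    c(">", "GREATER_THAN"), c(">=", "GREATER_THAN_EQUAL_TO"),
                    c("!=", "NOT_EQUAL_TO"))) {
    q <- parse_query(paste0('Gene and hasAttribute some (Name and hasValue ',
                            case[1], ' "3")'))
    expect_identical(q$args[[2]]$filler$args[[2]]$op, case[2])
  }
})

test_that("disjunction needs explicit parentheses and round-trips", {
  q <- parse_query("hasAssociation some (Gene or Protein)")
  expect_identical(q$filler$kind, "or")
  expect_true(q_equal(parse_query(q_render(q)), q))
})

test_that("render-parse is the identity on random query trees", {
  for (seed in 1:50) {
    q <- random_query_ast(seed)
    expect_true(q_equal(parse_query(q_render(q)), q))
  }
})

test_that("strip/reinsert is an exact round trip", {
  q2 <- parse_query(fixture_query(2))
  s <- strip_values(q2)
  expect_identical(count_values(s$expr), 0L)
  expect_length(s$bindings, 2L)
  lits <- sort(vapply(s$bindings, function(b) b$values[[1]]$literal, character(1)))
  expect_identical(lits, c("BRCA1", "homo sapiens"))
  expect_true(q_equal(reinsert_values(s$expr, s$bindings), q2))
  # value-free query: identity and empty bindings
  s0 <- strip_values(parse_query("Gene"))
  expect_length(s0$bindings, 0L)
  # property: round trip on random queries
  for (seed in 1:50) {
    q <- random_query_ast(seed)
    s <- strip_values(q)
    expect_identical(count_values(s$expr), 0L)
    expect_true(q_equal(reinsert_values(s$expr, s$bindings), q))
  }
})

test_that("UML extraction maps the worked examples to their printed candidates", {
  ontos <- list(onto_cabio, onto_pir)
  q2 <- parse_query(fixture_query(2))
  cands <- extract_uml(q2, ontos)
  expect_length(cands, 2L)
  printed <- cands[[2]]$mapping
  expect_identical(unname(printed[c("Nucleotide_Sequences", "Gene", "Gene_Symbol",
                                    "Organisms", "Scientific_Name")]),
                   c("cabio:NucleicAcidSequence", "pir:Gene", "pir:Gene_name",
                     "pir:Organism", "pir:Organism_scientificName"))
  # a concept with no UML counterpart is an error naming the concept
  expect_error(extract_uml(parse_query("Chromosome_Band"), ontos),
               "Chromosome_Band")
})

test_that("candidate substitutions are the filtered Cartesian product", {
  # two classes annotated with one concept x three with another: 6 combos
  mk <- function(n, concept, prefix) {
    information_model(prefix, "1", prefix, classes = lapply(seq_len(n), function(i)
      class_spec(paste0("K", i), annotation(concept))))
  }
  m1 <- mk(2, "Gene", "aa"); m2 <- mk(3, "Protein", "bb")
  ontos <- lapply(list(m1, m2), gen_fixture_ontology)
  q <- parse_query("Gene and hasAssociation some (Protein)")
  # no attribute concepts -> no filtering; the full product is returned
  cands <- extract_uml(q, ontos)
  expect_length(cands, 6L)
  # deterministic ordering: first concept most significant
  firsts <- vapply(cands, function(s) s$mapping[["Gene"]], character(1))
  expect_identical(firsts, rep(c("aa:K1", "aa:K2"), each = 3))
  # a concept with exactly one candidate everywhere -> single substitution
  expect_length(extract_uml(parse_query("Organisms"), list(onto_pir)), 1L)
})

test_that("attribute candidates must live on their enclosing class", {
  q2 <- parse_query(fixture_query(2))
  cands <- extract_uml(q2, list(onto_cabio, onto_pir))
  for (s in cands) {
    gene_prefix <- ontoquery:::term_prefix(s$mapping[["Gene"]])
    sym_prefix <- ontoquery:::term_prefix(s$mapping[["Gene_Symbol"]])
    expect_identical(gene_prefix, sym_prefix)
  }
})
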