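test_that("AST constructors enforce the grammar's local invariants", {
  expect_error(cql_group("AND", list(cql_attribute("a", "EQUAL_TO", "1"))),
               "length")
  expect_error(cql_attribute("a", "IS_NULL", "oops"), "takes no value")
  expect_silent(cql_attribute("a", "IS_NULL"))
  expect_error(dcql_foreign_association(
    join = list(predicate = "LIKE", local_attribute = "x", foreign_attribute = "y"),
    object = cql_object("C"), url = "http://s/"), "foreign predicate")
  expect_error(cql_query(cql_object("C", "not-a-child")))
})

test_that("XML emission is deterministic and parse-back is the identity", {
  q <- cql_query(cql_object("gov.example.A",
        cql_group("AND", list(
          cql_attribute("name", "EQUAL_TO", "x"),
          cql_association("toB", cql_object("gov.example.B"))))))
  x1 <- emit_xml(q); x2 <- emit_xml(q)
  expect_identical(x1, x2)
  expect_true(cql_equal(parse_xml(x1), q))
})

test_that("documents violating the single-child object rule are rejected", {
  bad <- paste0(
    '<CQLQuery xmlns="http://ontoquery.example.org/schema/cql1"><Target>',
    '<Object name="A">',
    '<Attribute name="a" predicate="EQUAL_TO" value="1"/>',
    '<Attribute name="b" predicate="EQUAL_TO" value="2"/>',
    '</Object></Target></CQLQuery>')
  expect_error(parse_xml(bad), "cqlObject")
  one_member <- paste0(
    '<CQLQuery xmlns="http://ontoquery.example.org/schema/cql1"><Target>',
    '<Object name="A"><Group logicalOp="AND">',
    '<Attribute name="a" predicate="EQUAL_TO" value="1"/>',
    '</Group></Object></Target></CQLQuery>')
  expect_error(parse_xml(one_member), "Group")
})

test_that("200 grammar-generated queries round-trip through emit/parse", {
  for (seed in 1:200) {
    q <- random_cql_query(seed, dcql = seed %% 3 == 0)
    expect_true(cql_equal(parse_xml(emit_xml(q)), q))
  }
})

test_that("MCC-to-CQL places target, associations, attributes and groups", {
  # chain comprehension: spine reads class role class role class
  chain <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
    ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("NucleicAcidSequence", "cabio")),
    ontoquery:::mcc_gen("v1", ontoquery:::mcc_path("v0", "geneCollection")),
    ontoquery:::mcc_gen("v1", ontoquery:::mcc_extent("Gene", "cabio")),
    ontoquery:::mcc_gen("v2", ontoquery:::mcc_path("v1", "proteinCollection")),
    ontoquery:::mcc_gen("v2", ontoquery:::mcc_extent("Protein", "cabio"))))
  q <- from_mcc_cql(chain)
  expect_identical(cql_spine(q),
                   c("NucleicAcidSequence", "geneCollection", "Gene",
                     "proteinCollection", "Protein"))
  expect_true(cql_equal(parse_xml(emit_xml(q)), q))
  # single generator -> target-only query
  single <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
    ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("Gene", "cabio"))))
  q1 <- from_mcc_cql(single)
  expect_null(q1$target$child)
  # two filters on one variable -> AND group with two attribute members
  twof <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
    ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("Gene", "cabio")),
    ontoquery:::mcc_filter(ontoquery:::mcc_path("v0", "symbol"), "EQUAL_TO",
                           ontoquery:::mcc_lit("BRCA1")),
    ontoquery:::mcc_filter(ontoquery:::mcc_path("v0", "id"), "LIKE",
                           ontoquery:::mcc_lit("EGF%"))))
  q2 <- from_mcc_cql(twof)
  expect_s3_class(q2$target$child, "cql_group")
  expect_identical(q2$target$child$op, "AND")
  expect_length(q2$target$child$members, 2L)
  expect_true(all(vapply(q2$target$child$members, inherits, logical(1),
                         "cql_attribute")))
})

test_that("MCC-to-DCQL builds one foreign association per join filter", {
  services <- c(aa = "http://aa/", bb = "http://bb/")
  comp <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
    ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("aa.X", "aa")),
    ontoquery:::mcc_gen("v1", ontoquery:::mcc_extent("bb.Y", "bb")),
    ontoquery:::mcc_filter(ontoquery:::mcc_path("v0", "k"), "EQUAL_TO",
                           ontoquery:::mcc_path("v1", "k2"))))
  q <- from_mcc_dcql(comp, services)
  expect_s3_class(q, "dcql_query")
  fa <- q$target$child
  expect_s3_class(fa, "dcql_foreign_association")
  expect_identical(fa$join$local_attribute, "k")
  expect_identical(fa$join$foreign_attribute, "k2")
  expect_identical(fa$url, "http://bb/")
  expect_true(cql_equal(parse_xml(emit_xml(q)), q))
  # degenerate single-service input is redirected
  single <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
    ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("aa.X", "aa"))))
  expect_error(from_mcc_dcql(single, services), "from_mcc_cql")
  expect_error(from_mcc_cql(comp), "from_mcc_dcql")
})

test_that("random two-service comprehensions emit exactly one foreign association", {
  for (seed in 1:20) {
    set.seed(seed)
    comp <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
      ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("aa.X", "aa")),
      ontoquery:::mcc_gen("v1", ontoquery:::mcc_path("v0", "toZ")),
      ontoquery:::mcc_gen("v1", ontoquery:::mcc_extent("aa.Z", "aa")),
      ontoquery:::mcc_gen("v2", ontoquery:::mcc_extent("bb.Y", "bb")),
      ontoquery:::mcc_filter(ontoquery:::mcc_path(sample(c("v0", "v1"), 1), "k"),
                             sample(dcql_foreign_predicates(), 1),
                             ontoquery:::mcc_path("v2", "k2"))))
    q <- from_mcc_dcql(comp, c(aa = "http://aa/", bb = "http://bb/"))
    back <- parse_xml(emit_xml(q))
    n_fa <- 0L
    count_fa <- function(o) {
      kids <- if (is.null(o$child)) list()
              else if (inherits(o$child, "cql_group")) o$child$members
              else list(o$child)
      for (k in kids) {
        if (inherits(k, "dcql_foreign_association")) {
          n_fa <<- n_fa + 1L; count_fa(k$object)
        }
        if (inherits(k, "cql_association")) count_fa(k$object)
      }
    }
    count_fa(back$target)
    expect_identical(n_fa, 1L)
  }
})

test_that("the interpreter agrees with the evaluator on the simple store", {
  st <- simple_store <- object_store(list(
    list(id = "a1", class = "A", classes = "A", attrs = list(name = "x"),
         links = list(toB = c("b1"))),
    list(id = "b1", class = "B", classes = "B", attrs = list(code = "1"),
         links = list())))
  comp <- ontoquery:::comprehension("bag", ontoquery:::mcc_var("v0"), list(
    ontoquery:::mcc_gen("v0", ontoquery:::mcc_extent("A", "x")),
    ontoquery:::mcc_gen("v1", ontoquery:::mcc_path("v0", "toB")),
    ontoquery:::mcc_gen("v1", ontoquery:::mcc_extent("B", "x"))))
  ids_eval <- unique(bag_ids(evaluate(comp, st)))
  ids_cql <- interpret_cql(from_mcc_cql(comp), st)
  expect_identical(ids_eval, "a1")
  expect_identical(ids_cql, "a1")
})
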