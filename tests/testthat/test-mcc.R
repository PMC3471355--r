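simple_store <- function() {
  object_store(list(
    list(id = "a1", class = "A", classes = "A", attrs = list(name = "x"),
         links = list(toB = c("b1", "b2"))),
    list(id = "a2", class = "A", classes = "A", attrs = list(name = "y"),
         links = list(toB = "b2")),
    list(id = "a3", class = "A", classes = "A", attrs = list(name = "x"),
         links = list(toB = character())),
    list(id = "b1", class = "B", classes = "B", attrs = list(code = "1"),
         links = list()),
    list(id = "b2", class = "B", classes = "B", attrs = list(code = "2"),
         links = list())
  ))
}

mkc <- function(...) ontoquery:::comprehension(...)
mv <- function(v) ontoquery:::mcc_var(v)
mg <- function(v, s) ontoquery:::mcc_gen(v, s)
me <- function(cl) ontoquery:::mcc_extent(cl)
mp <- function(v, m) ontoquery:::mcc_path(v, m)
mf <- function(l, op, r) ontoquery:::mcc_filter(l, op, r)
ml <- function(x) ontoquery:::mcc_lit(x)

test_that("a bare class translates to a single-generator comprehension", {
  m <- information_model("p", "1", "x",
                         classes = list(class_spec("A", annotation("Gene"))))
  o <- gen_fixture_ontology(m)
  c <- translate_expr(q_concept("x:A"), o)
  expect_identical(c$monoid, "bag")
  expect_identical(c$header$var, "v0")
  expect_length(c$qualifiers, 1L)
  expect_identical(c$qualifiers[[1]]$source$class, "x.A")
})

test_that("a depth-d role chain yields 2d+1 generators and d+1 variables", {
  for (d in 1:3) {
    classes <- lapply(0:d, function(i) class_spec(paste0("C", i), annotation("Gene")))
    assocs <- lapply(seq_len(d), function(i)
      association_spec(paste0("C", i - 1), paste0("C", i), paste0("r", i)))
    m <- information_model("p", "1", "x", classes = classes, associations = assocs)
    o <- gen_fixture_ontology(m)
    expr <- q_concept(paste0("x:C", d))
    for (i in rev(seq_len(d)))
      expr <- q_and(list(q_concept(paste0("x:C", i - 1)),
                         q_assoc(paste0("x:C", i - 1, "_r", i, "_C", i), expr)))
    c <- translate_expr(expr, o)
    gens <- Filter(function(q) q$kind == "generator", c$qualifiers)
    expect_length(gens, 2 * d + 1)
    expect_length(mcc_variables(c), d + 1)
    expect_error(translate_expr(q_assoc(NULL, q_concept("x:C1")), o),
                 "hasAssociation")
  }
})

test_that("untranslatable generic association nodes are rejected", {
  m <- information_model("p", "1", "x",
                         classes = list(class_spec("A", annotation("Gene"))))
  o <- gen_fixture_ontology(m)
  expect_error(
    translate_expr(q_and(list(q_concept("x:A"), q_assoc(NULL, q_concept("x:A")))), o),
    "generic hasAssociation")
})

test_that("evaluation implements extent, path, membership and filter semantics", {
  st <- simple_store()
  # extent identity
  c0 <- mkc("bag", mv("v0"), list(mg("v0", me("A"))))
  expect_identical(bag_ids(evaluate(c0, st)), c("a1", "a2", "a3"))
  # chain with membership constraint
  c1 <- mkc("bag", mv("v1"),
            list(mg("v0", me("A")), mg("v1", mp("v0", "toB")), mg("v1", me("B"))))
  expect_identical(bag_ids(evaluate(c1, st)), c("b1", "b2", "b2"))
  # filter that matches nothing returns the zero element
  c2 <- mkc("bag", mv("v0"),
            list(mg("v0", me("A")), mf(mp("v0", "name"), "EQUAL_TO", ml("zzz"))))
  expect_length(evaluate(c2, st), 0L)
  # or-monoid collapses to a truth value
  c3 <- mkc("or", mv("v0"),
            list(mg("v0", me("A")), mf(mp("v0", "name"), "EQUAL_TO", ml("x"))))
  expect_true(evaluate(c3, st))
  c4 <- mkc("or", mv("v0"),
            list(mg("v0", me("A")), mf(mp("v0", "name"), "EQUAL_TO", ml("zzz"))))
  expect_false(evaluate(c4, st))
})

test_that("the monoid laws hold for the bag accumulator on sampled values", {
  # associativity and identity of bag union, observed through the evaluator
  st <- simple_store()
  bags <- list(
    evaluate(mkc("bag", mv("v0"), list(mg("v0", me("A")))), st),
    evaluate(mkc("bag", mv("v0"), list(mg("v0", me("B")))), st),
    list()
  )
  merge_bags <- function(a, b) c(a, b)
  expect_identical(bag_ids(merge_bags(merge_bags(bags[[1]], bags[[2]]), bags[[3]])),
                   bag_ids(merge_bags(bags[[1]], merge_bags(bags[[2]], bags[[3]]))))
  expect_identical(bag_ids(merge_bags(bags[[1]], list())), bag_ids(bags[[1]]))
})

test_that("normalization unnests, coalesces, renumbers — and is idempotent", {
  nested <- mkc("bag", mv("w"),
    list(mg("w", me("A")),
         mg("z", mp("w", "toB")),
         mg("z", mkc("bag", mv("q"), list(mg("q", me("B")))))))
  n1 <- normalize(nested)
  expect_identical(mcc_variables(n1), c("v0", "v1"))
  expect_length(n1$qualifiers, 3L)
  expect_true(mcc_well_formed(n1))
  expect_identical(normalize(n1), n1)
  # duplicate generators over the same source coalesce
  dup <- mkc("bag", mv("v0"), list(mg("v0", me("A")), mg("v0", me("A"))))
  expect_length(normalize(dup)$qualifiers, 1L)
})

test_that("normalization preserves evaluator semantics on 200 random cases", {
  for (seed in 1:200) {
    case <- random_comprehension_case(seed)
    before <- evaluate(case$comp, case$store)
    after <- evaluate(normalize(case$comp), case$store)
    expect_identical(bag_ids(before), bag_ids(after))
    expect_true(mcc_well_formed(normalize(case$comp)))
  }
})

test_that("render/read round-trips flat comprehensions", {
  c1 <- mkc("bag", mv("v0"),
            list(mg("v0", me("gov.example.A")),
                 mg("v1", mp("v0", "toB")),
                 mg("v1", me("gov.example.B")),
                 mf(mp("v1", "code"), "EQUAL_TO", ml("2")),
                 mf(mp("v0", "name"), "LESS_THAN", mp("v1", "code"))))
  txt <- render_mcc(c1)
  expect_match(txt, "^⊎\\{v0 \\| ")
  back <- read_mcc(txt)
  expect_identical(render_mcc(back), txt)
  expect_identical(mcc_variables(back), mcc_variables(c1))
  for (seed in 1:25) {
    case <- random_comprehension_case(seed)
    n <- normalize(case$comp)
    expect_identical(render_mcc(read_mcc(render_mcc(n))), render_mcc(n))
  }
})

test_that("translation is compositional: sub-trees embed in the whole", {
  o <- onto_cabio
  whole <- translate_expr(q_and(list(
    q_concept("cabio:NucleicAcidSequence"),
    q_assoc("cabio:NucleicAcidSequence_geneCollection_Gene",
            q_and(list(q_concept("cabio:Gene"),
                       q_assoc("cabio:Gene_proteinCollection_Protein",
                               q_concept("cabio:Protein"))))))), o)
  sub <- translate_expr(q_and(list(q_concept("cabio:Gene"),
                                   q_assoc("cabio:Gene_proteinCollection_Protein",
                                           q_concept("cabio:Protein")))), o)
  whole_srcs <- mcc_generator_sources(normalize(whole))
  sub_srcs <- mcc_generator_sources(normalize(sub))
  # the sub-translation's extent sequence occurs inside the whole's
  sub_extents <- grep("\\.", sub_srcs, invert = TRUE, value = TRUE)
  whole_extents <- grep("\\.", whole_srcs, invert = TRUE, value = TRUE)
  expect_true(all(sub_extents %in% whole_extents))
})
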