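u <- ontoquery:::uml_terms()

has_axiom <- function(onto, ax) {
  any(vapply(onto$axioms, function(a) ontoquery:::axiom_equal(a, ax), logical(1)))
}

test_that("the generated caBIO ontology contains the core structural axioms", {
  o <- onto_cabio
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome", u$class)))
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome_number", u$attribute)))
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome_number",
                                  ce_data(u$has_value, "xsd:string"))))
  expect_true(has_axiom(o, ax_subprop("cabio:Chromosome_locationCollection_Location",
                                      u$has_association)))
  expect_true(has_axiom(o, ax_sub("cabio:CytogeneticLocation", "cabio:Location")))
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome",
    ce_some("cabio:Chromosome_locationCollection_Location", "cabio:Location"))))
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome",
    ce_some(u$has_attribute, "cabio:Chromosome_number"))))
  # exactly one transitivity declaration
  kinds <- vapply(o$axioms, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "transitive"), 1L)
})

test_that("associations are inherited explicitly along the subclass chain", {
  expect_true(has_axiom(onto_cabio, ax_sub("cabio:SNPPhysicalLocation",
    ce_some("cabio:Location_chromosome_Chromosome", "cabio:Chromosome"))))
  # class with no descendants contributes nothing
  m <- information_model("p", "1", "x", classes = list(
    class_spec("A", annotation("Gene")), class_spec("B", annotation("Protein"))),
    associations = list(association_spec("A", "B", "b")))
  expect_length(inherited_association_axioms(m), 0L)
  # a chain of k subclasses under one association yields exactly k axioms
  k <- 4
  classes <- list(class_spec("Top", annotation("Gene")),
                  class_spec("Range", annotation("Protein")))
  prev <- "Top"
  for (i in seq_len(k)) {
    classes[[length(classes) + 1L]] <-
      class_spec(paste0("S", i), annotation("Gene"), superclasses = prev)
    prev <- paste0("S", i)
  }
  chain <- information_model("p", "1", "x", classes = classes,
                             associations = list(association_spec("Top", "Range", "r")))
  expect_length(inherited_association_axioms(chain), k)
})

test_that("annotation axioms use the list pattern with significant order", {
  o <- onto_cabio
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome", "n:Chromosome")))
  expect_true(has_axiom(o, ax_sub("cabio:Chromosome_number", "n:Name")))
  # qualifier-list encoding nests in order
  lst <- u
  eq11 <- ax_sub("cabio:SNPPhysicalLocation",
    ce_and(ce_named("n:Location"),
           ce_and(ce_named(lst$list_class),
                  ce_some(lst$has_contents, "n:Chromosome"),
                  ce_some(lst$has_next,
                          ce_and(ce_named(lst$list_class),
                                 ce_some(lst$has_contents,
                                         "n:Single_Nucleotide_Polymorphism"))))))
  expect_true(has_axiom(o, eq11))
  # reversing the qualifier list changes the axiom
  m1 <- information_model("p", "1", "x", classes = list(
    class_spec("A", annotation("Location", c("Chromosome", "Gene")))))
  m2 <- information_model("p", "1", "x", classes = list(
    class_spec("A", annotation("Location", c("Gene", "Chromosome")))))
  a1 <- annotation_axioms(m1)[[1]]; a2 <- annotation_axioms(m2)[[1]]
  expect_false(ontoquery:::axiom_equal(a1, a2))
})

test_that("an empty model generates only the scaffold", {
  e <- information_model("Empty", "0", "e")
  o <- generate_ontology(e, fx$dom)
  kinds <- vapply(o$axioms, `[[`, character(1), "kind")
  expect_true(all(kinds %in% c("transitive", "sub_class", "disjoint")))
  # the only sub_class axioms are the embedded module subsumptions
  subs <- Filter(function(a) a$kind == "sub_class", o$axioms)
  expect_true(all(vapply(subs, function(a)
    ontoquery:::term_prefix(a$sub$term) == "n", logical(1))))
})

test_that("generation requires the module to cover every annotation concept", {
  tiny <- domain_ontology(list(concept("Gene")))
  m <- information_model("p", "1", "x", classes = list(
    class_spec("A", annotation("Protein"))))
  expect_error(generate_ontology(m, tiny), "missing from module")
})

test_that("module extraction preserves entailments over the signature", {
  # trivial cases
  expect_identical(extract_module(fx$dom, concept_ids(fx$dom)), fx$dom)
  empty <- extract_module(fx$dom, character())
  expect_length(empty$concepts, 0L)
  # signature-entailment preservation on 50 random toy ontologies
  for (seed in 1:50) {
    onto <- generate_synthetic_ontology(n_concepts = sample(5:30, 1),
                                        p_parent = 0.7, seed = seed)
    ids <- concept_ids(onto)
    sig <- sample(ids, min(length(ids), sample(1:5, 1)))
    mod <- extract_module(onto, sig)
    for (a in sig) for (b in sig)
      expect_identical(dom_subsumes(mod, a, b), dom_subsumes(onto, a, b))
  }
})

test_that("disjointness stripping removes exactly the disjoint axioms", {
  with2 <- fx$dom
  expect_identical(nrow(strip_disjointness(with2)$disjointness), 0L)
  none <- strip_disjointness(with2)
  expect_identical(strip_disjointness(none), none)
  # on generated ontologies: multiset difference is only disjointness
  for (seed in 1:10) {
    m <- generate_synthetic_model(6, 2, 0.2, fx$dom, seed = seed)
    onto <- generate_ontology(m, extract_module(fx$dom, model_concepts(m)))
    stripped <- strip_disjointness(onto)
    expect_identical(stripped$axioms,
                     Filter(function(a) a$kind != "disjoint", onto$axioms))
  }
})

test_that("serialization is deterministic and declares transitivity", {
  f1 <- serialize_ontology(onto_cabio, "functional")
  f2 <- serialize_ontology(onto_cabio, "functional")
  expect_identical(f1, f2)
  expect_match(f1, "TransitiveObjectProperty(u:hasAssociation)", fixed = TRUE)
  t1 <- serialize_ontology(onto_cabio, "turtle")
  expect_identical(t1, serialize_ontology(onto_cabio, "turtle"))
  expect_match(t1, "owl:TransitiveObjectProperty")
  # empty ontology yields a header-only document
  e <- generate_ontology(information_model("Empty", "0", "e"), domain_ontology())
  expect_match(serialize_ontology(e, "functional"), "^Prefix\\(")
})

test_that("generated ontologies observe the EL discipline", {
  expect_true(check_el(onto_cabio)$ok)
  expect_true(check_el(onto_pir)$ok)
  for (seed in 1:100) {
    m <- generate_synthetic_model(sample(2:10, 1), 3, 0.2, fx$dom, seed = seed)
    expect_true(check_el(gen_fixture_ontology(m))$ok)
  }
  # a leftover disjointness axiom is flagged
  dirty <- generate_ontology(fx$cabio, extract_module(fx$dom, model_concepts(fx$cabio)))
  expect_false(check_el(dirty)$ok)
})

test_that("the structural axiom count matches its closed form", {
  for (seed in 1:20) {
    m <- generate_synthetic_model(sample(1:10, 1), 3, 0.25, fx$dom, seed = seed)
    o <- generate_ontology(m, domain_ontology(fx$dom$concepts))  # no module axioms
    cc <- length(m$classes)
    aa <- sum(vapply(m$classes, function(cl) length(cl$attributes), integer(1)))
    ss <- length(m$associations)
    hh <- sum(vapply(m$classes, function(cl) length(cl$superclasses), integer(1)))
    inh <- sum(vapply(m$associations, function(a)
      length(model_descendants(m, a$source)), integer(1)))
    # transitivity + class/attr/assoc structure + inheritance
    # + one concept-annotation axiom per element + one name annotation per term
    expected <- 1 + cc + 3 * aa + 2 * ss + hh + inh + (cc + aa) + (cc + aa + ss)
    expect_identical(length(o$axioms), as.integer(expected))
  }
})
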