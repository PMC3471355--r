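#' @title Customised UML-to-OWL transformation
#' @description Generates an EL-style OWL ontology from an annotated
#'   information model. UML classes and attributes both become OWL classes
#'   (subclasses of `u:UMLClass` / `u:UMLAttribute`), so that concept
#'   annotations on attributes are first-class; associations become object
#'   properties declared under the single transitive upper property
#'   `u:hasAssociation`; inherited associations are made explicit on every
#'   descendant of the declaring class; and annotations (primary concept plus
#'   ordered qualifiers) are encoded with an OWL list pattern. The generated
#'   ontologies are TBox-only and avoid universal quantification, staying
#'   within the EL profile.
#' @name owlgen
NULL

uml_terms <- function() {
  list(class = "u:UMLClass", attribute = "u:UMLAttribute",
       has_association = "u:hasAssociation", has_attribute = "u:hasAttribute",
       has_value = "u:hasValue",
       list_class = "l:OWLList", has_contents = "l:hasContents", has_next = "l:hasNext")
}

xsd_datatype <- function(dt) {
  c(string = "xsd:string", integer = "xsd:integer", decimal = "xsd:decimal",
    boolean = "xsd:boolean", date = "xsd:date")[[dt]]
}

class_term <- function(model, name) term(model$prefix, name)
attribute_term <- function(model, class_name, attr_name)
  term(model$prefix, paste0(class_name, "_", attr_name))
association_property <- function(model, assoc)
  term(model$prefix, paste0(assoc$source, "_", assoc$role, "_", assoc$target))

qualified_class_name <- function(model, name) {
  base <- if (!is.null(model$namespace)) model$namespace else model$prefix
  paste0(base, ".", name)
}

new_generated_ontology <- function(iri, prefixes, imports, axioms) {
  structure(list(iri = iri, prefixes = prefixes, imports = imports, axioms = axioms),
            class = "generated_ontology")
}

#' @export
print.generated_ontology <- function(x, ...) {
  cat("Generated ontology <", x$iri, ">: ", length(x$axioms), " axioms, prefixes: ",
      paste(x$prefixes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate the OWL ontology for an information model
#'
#' Emits, in a fixed order: the transitivity declaration for
#' `u:hasAssociation`; the domain-ontology module's subsumption (and any
#' remaining disjointness) axioms; per class `C` the axiom
#' `C SubClassOf u:UMLClass` and its superclass links; per attribute `a` of
#' `C` the class `C_a` with `C_a SubClassOf u:UMLAttribute`,
#' `C_a SubClassOf u:hasValue some <xsd type>` and
#' `C SubClassOf u:hasAttribute some C_a`; per association the property
#' `Source_role_Target SubPropertyOf u:hasAssociation` and
#' `Source SubClassOf Source_role_Target some Target`; the explicit
#' inherited-association axioms; the concept-annotation axioms (list
#' pattern); and `ClassName`/`AttributeName`/`RoleName` annotation
#' assertions for every generated term.
#'
#' @param model an [information_model()]
#' @param module a [domain_ontology()] covering every concept the model uses
#' @return a `generated_ontology`
#' @export
generate_ontology <- function(model, module) {
  validate_model(model)
  u <- uml_terms()
  missing <- setdiff(model_concepts(model), concept_ids(module))
  if (length(missing))
    stop("annotation concept missing from module: ", paste(missing, collapse = ", "))

  ax <- list(ax_transitive(u$has_association))
  for (i in seq_len(nrow(module$subsumptions)))
    ax <- c(ax, list(ax_sub(term("n", module$subsumptions[i, 1]),
                            term("n", module$subsumptions[i, 2]))))
  for (i in seq_len(nrow(module$disjointness)))
    ax <- c(ax, list(ax_disjoint(term("n", module$disjointness[i, 1]),
                                 term("n", module$disjointness[i, 2]))))

  for (cl in model$classes) {
    ct <- class_term(model, cl$name)
    ax <- c(ax, list(ax_sub(ct, u$class)))
    for (s in cl$superclasses)
      ax <- c(ax, list(ax_sub(ct, class_term(model, s))))
    for (at in cl$attributes) {
      att <- attribute_term(model, cl$name, at$name)
      ax <- c(ax, list(
        ax_sub(att, u$attribute),
        ax_sub(att, ce_data(u$has_value, xsd_datatype(at$datatype))),
        ax_sub(ct, ce_some(u$has_attribute, att))
      ))
    }
  }
  for (a in model$associations) {
    prop <- association_property(model, a)
    ax <- c(ax, list(
      ax_subprop(prop, u$has_association),
      ax_sub(class_term(model, a$source), ce_some(prop, class_term(model, a$target)))
    ))
  }
  ax <- c(ax, inherited_association_axioms(model))
  ax <- c(ax, annotation_axioms(model))

  # name annotations consumed by the MCC translation
  for (cl in model$classes) {
    ax <- c(ax, list(ax_annot(class_term(model, cl$name), "ClassName",
                              qualified_class_name(model, cl$name))))
    for (at in cl$attributes)
      ax <- c(ax, list(ax_annot(attribute_term(model, cl$name, at$name),
                                "AttributeName", at$name)))
  }
  for (a in model$associations)
    ax <- c(ax, list(ax_annot(association_property(model, a), "RoleName", a$role)))

  new_generated_ontology(
    iri = paste0("http://ontoquery.example.org/ontology/", model$prefix),
    prefixes = model$prefix,
    imports = c("uml-model", "list", paste0("module-", model$prefix)),
    axioms = ax
  )
}

#' Explicit inherited-association axioms
#'
#' For every association declared on class `D` with role `r` and range `R`,
#' and every (transitive) descendant `S` of `D`, emits
#' `S SubClassOf D_r_R some R`, keeping the declaring class in the property
#' name. This materialises the UML semantics that subclasses inherit their
#' ancestors' associations.
#'
#' @param model an [information_model()]
#' @return list of axioms
#' @export
inherited_association_axioms <- function(model) {
  ax <- list()
  for (a in model$associations) {
    prop <- association_property(model, a)
    for (s in model_descendants(model, a$source))
      ax <- c(ax, list(ax_sub(class_term(model, s),
                              ce_some(prop, class_term(model, a$target)))))
  }
  ax
}

qualifier_list_expression <- function(qualifiers) {
  u <- uml_terms()
  q1 <- ce_some(u$has_contents, term("n", qualifiers[1]))
  if (length(qualifiers) == 1L) {
    ce_and(ce_named(u$list_class), q1)
  } else {
    ce_and(ce_named(u$list_class), q1,
           ce_some(u$has_next, qualifier_list_expression(qualifiers[-1])))
  }
}

#' Concept-annotation axioms (list pattern)
#'
#' An element annotated with primary `P` and no qualifiers yields
#' `Element SubClassOf n:P`. With qualifiers `q1..qk` it yields
#' `Element SubClassOf n:P and (l:OWLList and l:hasContents some n:q1 and
#' l:hasNext some ( ... l:hasContents some n:qk))`, nesting in qualifier
#' order, so that reversing the qualifier list produces a structurally
#' different axiom.
#'
#' @param model an [information_model()]
#' @return list of axioms
#' @export
annotation_axioms <- function(model) {
  one <- function(subject, ann) {
    primary <- term("n", ann$primary)
    if (!length(ann$qualifiers)) return(ax_sub(subject, primary))
    ax_sub(subject, ce_and(ce_named(primary),
                           qualifier_list_expression(ann$qualifiers)))
  }
  ax <- list()
  for (cl in model$classes) {
    ax <- c(ax, list(one(class_term(model, cl$name), cl$annotation)))
    for (at in cl$attributes)
      ax <- c(ax, list(one(attribute_term(model, cl$name, at$name), at$annotation)))
  }
  ax
}

## ---- module extraction & disjointness stripping ----------------------------

#' Extract a signature module from a domain ontology
#'
#' Syntactic bottom-locality over the subsumption/disjointness language: the
#' signature is closed upward under asserted subsumption, every subsumption
#' axiom whose child lies in the closure is kept, and a disjointness axiom is
#' kept when both concepts lie in the closure. The result preserves every
#' subsumption entailment between signature terms.
#'
#' @param ontology a [domain_ontology()]
#' @param signature character vector of concept ids
#' @return a [domain_ontology()] restricted to the module
#' @export
extract_module <- function(ontology, signature) {
  ids <- concept_ids(ontology)
  unknown <- setdiff(signature, ids)
  if (length(unknown)) stop("unknown signature term: ", paste(unknown, collapse = ", "))
  sig <- unique(signature)
  repeat {
    keep <- ontology$subsumptions[, 1] %in% sig
    grown <- unique(c(sig, ontology$subsumptions[keep, 2]))
    if (length(grown) == length(sig)) break
    sig <- grown
  }
  subs <- ontology$subsumptions[ontology$subsumptions[, 1] %in% sig &
                                ontology$subsumptions[, 2] %in% sig, , drop = FALSE]
  disj <- ontology$disjointness[ontology$disjointness[, 1] %in% sig &
                                ontology$disjointness[, 2] %in% sig, , drop = FALSE]
  keep_concepts <- ontology$concepts[vapply(ontology$concepts,
                                            function(k) k$id %in% sig, logical(1))]
  domain_ontology(keep_concepts, subs, disj)
}

#' Remove disjointness axioms
#'
#' All other axioms are preserved in order. Works on both domain ontologies
#' and generated ontologies.
#'
#' @param ontology a [domain_ontology()] or `generated_ontology`
#' @return same type, without disjointness
#' @export
strip_disjointness <- function(ontology) {
  if (inherits(ontology, "domain_ontology")) {
    ontology$disjointness <- as_pair_matrix(NULL)
    return(ontology)
  }
  if (inherits(ontology, "generated_ontology")) {
    ontology$axioms <- Filter(function(a) a$kind != "disjoint", ontology$axioms)
    return(ontology)
  }
  stop("unsupported ontology type")
}

#' EL-discipline compliance check
#'
#' Verifies that a generated ontology uses only the constructs this package's
#' EL-style reasoner understands: no universal quantification (which the
#' expression language cannot even build), no disjointness axioms, and
#' exactly one transitive-property declaration (for `u:hasAssociation`).
#'
#' @param ontology a `generated_ontology`
#' @return list with `ok` (logical) and `issues` (character vector)
#' @export
check_el <- function(ontology) {
  issues <- character()
  kinds <- vapply(ontology$axioms, `[[`, character(1), "kind")
  if (sum(kinds == "transitive") != 1L)
    issues <- c(issues, "expected exactly one transitive-property declaration")
  trans <- ontology$axioms[kinds == "transitive"]
  if (length(trans) && trans[[1]]$prop != uml_terms()$has_association)
    issues <- c(issues, "transitive property is not u:hasAssociation")
  if (any(kinds == "disjoint"))
    issues <- c(issues, "disjointness axioms present")
  check_expr <- function(e) {
    if (!is_ce(e)) return(invisible())
    if (!e$kind %in% c("named", "and", "or", "some", "value", "data"))
      issues <<- c(issues, paste0("non-EL construct: ", e$kind))
    if (e$kind %in% c("and", "or")) lapply(e$args, check_expr)
    if (e$kind == "some") check_expr(e$filler)
    invisible()
  }
  for (a in ontology$axioms) {
    if (a$kind == "sub_class") { check_expr(a$sub); check_expr(a$super) }
  }
  list(ok = !length(issues), issues = issues)
}

## ---- serialization ---------------------------------------------------------

prefix_iri <- function(p) {
  std <- c(xsd = "http://www.w3.org/2001/XMLSchema#",
           owl = "http://www.w3.org/2002/07/owl#",
           rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
           rdfs = "http://www.w3.org/2000/01/rdf-schema#")
  if (p %in% names(std)) return(std[[p]])
  paste0("http://ontoquery.example.org/ns/", p, "#")
}

serialize_prefixes <- function(ontology) {
  used <- c("u", "n", "l", "xsd", ontology$prefixes)
  unique(used)
}

render_ce_functional <- function(e) {
  switch(e$kind,
    named = e$term,
    and = paste0("ObjectIntersectionOf(",
                 paste(vapply(e$args, render_ce_functional, character(1)), collapse = " "), ")"),
    or = paste0("ObjectUnionOf(",
                paste(vapply(e$args, render_ce_functional, character(1)), collapse = " "), ")"),
    some = paste0("ObjectSomeValuesFrom(", e$prop, " ", render_ce_functional(e$filler), ")"),
    data = paste0("DataSomeValuesFrom(", e$prop, " ", e$datatype, ")"),
    value = paste0("DataHasValue(", e$prop, " \"", e$value, "\")"),
    stop("cannot serialize expression kind: ", e$kind))
}

render_axiom_functional <- function(a) {
  switch(a$kind,
    sub_class = paste0("SubClassOf(", render_ce_functional(a$sub), " ",
                       render_ce_functional(a$super), ")"),
    equivalent = paste0("EquivalentClasses(", a$a, " ", a$b, ")"),
    sub_property = paste0("SubObjectPropertyOf(", a$sub, " ", a$super, ")"),
    transitive = paste0("TransitiveObjectProperty(", a$prop, ")"),
    annotation = paste0("AnnotationAssertion(u:", a$property, " ", a$subject,
                        " \"", a$value, "\")"),
    disjoint = paste0("DisjointClasses(", a$a, " ", a$b, ")"))
}

render_ce_turtle <- function(e) {
  switch(e$kind,
    named = e$term,
    and = paste0("[ rdf:type owl:Class ; owl:intersectionOf ( ",
                 paste(vapply(e$args, render_ce_turtle, character(1)), collapse = " "), " ) ]"),
    or = paste0("[ rdf:type owl:Class ; owl:unionOf ( ",
                paste(vapply(e$args, render_ce_turtle, character(1)), collapse = " "), " ) ]"),
    some = paste0("[ rdf:type owl:Restriction ; owl:onProperty ", e$prop,
                  " ; owl:someValuesFrom ", render_ce_turtle(e$filler), " ]"),
    data = paste0("[ rdf:type owl:Restriction ; owl:onProperty ", e$prop,
                  " ; owl:someValuesFrom ", e$datatype, " ]"),
    value = paste0("[ rdf:type owl:Restriction ; owl:onProperty ", e$prop,
                   " ; owl:hasValue \"", e$value, "\" ]"),
    stop("cannot serialize expression kind: ", e$kind))
}

render_axiom_turtle <- function(a) {
  switch(a$kind,
    sub_class = paste0(render_ce_turtle(a$sub), " rdfs:subClassOf ",
                       render_ce_turtle(a$super), " ."),
    equivalent = paste0(a$a, " owl:equivalentClass ", a$b, " ."),
    sub_property = paste0(a$sub, " rdfs:subPropertyOf ", a$super, " ."),
    transitive = paste0(a$prop, " rdf:type owl:TransitiveObjectProperty ."),
    annotation = paste0(a$subject, " u:", a$property, " \"", a$value, "\" ."),
    disjoint = paste0(a$a, " owl:disjointWith ", a$b, " ."))
}

#' Serialize a generated ontology
#'
#' Deterministic (axiom order is preserved; serializing twice yields
#' byte-identical output) in OWL 2 functional syntax or Turtle.
#'
#' @param ontology a `generated_ontology`
#' @param dialect `"functional"` or `"turtle"`
#' @return character scalar
#' @export
serialize_ontology <- function(ontology, dialect = c("functional", "turtle")) {
  dialect <- match.arg(dialect)
  pfx <- serialize_prefixes(ontology)
  if (dialect == "functional") {
    header <- c(
      vapply(pfx, function(p) paste0("Prefix(", p, ":=<", prefix_iri(p), ">)"),
             character(1)),
      paste0("Ontology(<", ontology$iri, ">"),
      vapply(ontology$imports, function(im)
        paste0("  Import(<http://ontoquery.example.org/import/", im, ">)"), character(1))
    )
    body <- vapply(ontology$axioms, function(a)
      paste0("  ", render_axiom_functional(a)), character(1))
    return(paste(c(header, body, ")"), collapse = "\n"))
  }
  header <- c(
    vapply(c(pfx, "owl", "rdf", "rdfs"), function(p)
      paste0("@prefix ", p, ": <", prefix_iri(p), "> ."), character(1)),
    paste0("<", ontology$iri, "> rdf:type owl:Ontology ."),
    "u:ClassName rdf:type owl:AnnotationProperty .",
    "u:AttributeName rdf:type owl:AnnotationProperty .",
    "u:RoleName rdf:type owl:AnnotationProperty ."
  )
  body <- vapply(ontology$axioms, render_axiom_turtle, character(1))
  paste(c(header, body, ""), collapse = "\n")
}
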