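#' @title Annotated information models
#' @description Constructors and validators for the UML-style information
#'   models this package consumes: classes with typed, concept-annotated
#'   attributes, directed associations with role names, superclass links, and
#'   a per-model namespace prefix. Every model element carries a concept
#'   annotation: a primary concept from the domain ontology plus an ordered
#'   (possibly empty) qualifier list.
#' @name information-models
NULL

model_datatypes <- function() c("string", "integer", "decimal", "boolean", "date")

#' Concept of a domain ontology
#' @param id opaque non-empty identifier, unique within its ontology
#' @param name display name (defaults to the id)
#' @param definition optional text
#' @return list of class `oq_concept`
#' @export
concept <- function(id, name = id, definition = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name,
                 definition = if (is.null(definition)) NULL else as.character(definition)),
            class = "oq_concept")
}

#' Concept annotation: primary concept plus ordered qualifier list
#' @param primary concept id (character scalar)
#' @param qualifiers character vector of concept ids; order is significant
#' @return list of class `oq_annotation`
#' @export
annotation <- function(primary, qualifiers = character()) {
  stopifnot(is.character(primary), length(primary) == 1L, nzchar(primary))
  structure(list(primary = primary, qualifiers = as.character(qualifiers)),
            class = "oq_annotation")
}

#' Attribute of a model class
#' @param name attribute name, unique within its class
#' @param datatype one of `string`, `integer`, `decimal`, `boolean`, `date`
#' @param annotation an [annotation()]
#' @return list of class `oq_attribute`
#' @export
attribute_spec <- function(name, datatype, annotation) {
  stopifnot(nzchar(name), datatype %in% model_datatypes(), inherits(annotation, "oq_annotation"))
  structure(list(name = name, datatype = datatype, annotation = annotation),
            class = "oq_attribute")
}

#' Class of an information model
#' @param name class name
#' @param annotation an [annotation()]
#' @param superclasses character vector of class names within the same model
#' @param attributes list of [attribute_spec()]s, order preserved
#' @return list of class `oq_class`
#' @export
class_spec <- function(name, annotation, superclasses = character(), attributes = list()) {
  stopifnot(nzchar(name), inherits(annotation, "oq_annotation"))
  structure(list(name = name, superclasses = as.character(superclasses),
                 attributes = attributes, annotation = annotation),
            class = "oq_class")
}

#' Directed association between two model classes
#' @param source,target class names
#' @param role role name used to navigate from source to target;
#'   `(source, role)` is unique within a model
#' @return list of class `oq_association`
#' @export
association_spec <- function(source, target, role) {
  stopifnot(nzchar(source), nzchar(target), nzchar(role))
  structure(list(source = source, target = target, role = role),
            class = "oq_association")
}

#' Annotated information model of one data source
#'
#' @param project_name project/display name
#' @param version version string
#' @param prefix short namespace token, unique among co-loaded models
#' @param classes list of [class_spec()]s
#' @param associations list of [association_spec()]s
#' @param service_url optional data-service URL
#' @param namespace optional package-style namespace prepended to class names
#'   when fully-qualified names are required (query targets)
#' @return object of class `information_model`
#' @export
information_model <- function(project_name, version, prefix, classes = list(),
                              associations = list(), service_url = NULL,
                              namespace = NULL) {
  m <- structure(list(project_name = project_name, version = version,
                      prefix = prefix,
                      service_url = if (is.null(service_url)) NULL else as.character(service_url),
                      namespace = if (is.null(namespace)) NULL else as.character(namespace),
                      classes = classes, associations = associations),
                 class = "information_model")
  validate_model(m)
  m
}

#' Class names of a model
#' @param model an [information_model()]
#' @return character vector
#' @export
model_class_names <- function(model) {
  vapply(model$classes, `[[`, character(1), "name")
}

#' Look up a class by name
#' @param model an [information_model()]
#' @param name class name
#' @return the [class_spec()], or `NULL`
#' @export
model_class <- function(model, name) {
  i <- match(name, model_class_names(model))
  if (is.na(i)) NULL else model$classes[[i]]
}

#' Validate an information model
#'
#' Checks that class names are unique, superclass and association references
#' resolve, attribute names are unique within their class, `(source, role)`
#' pairs are unique, and the subclass graph is acyclic. Violations are
#' reported with an element path.
#'
#' @param model an [information_model()]
#' @return the model, invisibly; errors on violation
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "information_model"))
  if (!nzchar(model$prefix)) stop("model prefix must be non-empty")
  cn <- model_class_names(model)
  dup <- cn[duplicated(cn)]
  if (length(dup)) stop("duplicate class name: classes/", dup[1])
  for (cl in model$classes) {
    an <- vapply(cl$attributes, `[[`, character(1), "name")
    if (anyDuplicated(an))
      stop("duplicate attribute name: classes/", cl$name, "/attributes/", an[duplicated(an)][1])
    for (s in cl$superclasses)
      if (!s %in% cn)
        stop("dangling superclass reference: classes/", cl$name, " -> ", s)
  }
  keys <- character()
  for (i in seq_along(model$associations)) {
    a <- model$associations[[i]]
    if (!a$source %in% cn)
      stop("dangling association source: associations/", i, " -> ", a$source)
    if (!a$target %in% cn)
      stop("dangling association target: associations/", i, " -> ", a$target)
    k <- paste0(a$source, "#", a$role)
    if (k %in% keys)
      stop("duplicate (source, role) pair: associations/", i, " -> ", k)
    keys <- c(keys, k)
  }
  # subclass cycle check: DFS over superclass edges
  visiting <- character(); done <- character()
  visit <- function(name) {
    if (name %in% done) return(invisible())
    if (name %in% visiting) stop("subclass cycle involving class ", name)
    visiting <<- c(visiting, name)
    for (s in model_class(model, name)$superclasses) visit(s)
    visiting <<- setdiff(visiting, name)
    done <<- c(done, name)
  }
  for (nm in cn) visit(nm)
  invisible(model)
}

#' All ancestors of a class via superclass links (excluding itself)
#' @param model information model
#' @param name class name
#' @return character vector
#' @export
model_ancestors <- function(model, name) {
  out <- character(); queue <- model_class(model, name)$superclasses
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (!x %in% out) {
      out <- c(out, x)
      queue <- c(queue, model_class(model, x)$superclasses)
    }
  }
  out
}

#' All descendants of a class via superclass links (excluding itself)
#' @param model information model
#' @param name class name
#' @return character vector
#' @export
model_descendants <- function(model, name) {
  cn <- model_class_names(model)
  cn[vapply(cn, function(x) name %in% model_ancestors(model, x), logical(1))]
}

#' @export
print.information_model <- function(x, ...) {
  cat("Information model '", x$project_name, "' v", x$version,
      " (prefix ", x$prefix, ")\n", sep = "")
  cat("  classes:     ", length(x$classes), "\n")
  cat("  associations:", length(x$associations), "\n")
  invisible(x)
}

## ---- domain ontology -------------------------------------------------------

#' Toy domain ontology: concepts, subsumptions, disjointness
#'
#' @param concepts list of [concept()]s
#' @param subsumptions two-column character matrix (or list of pairs) of
#'   `(child id, parent id)`; the graph must be acyclic
#' @param disjointness two-column character matrix (or list of pairs) of
#'   mutually disjoint concept ids
#' @return object of class `domain_ontology`
#' @export
domain_ontology <- function(concepts = list(), subsumptions = NULL, disjointness = NULL) {
  subs <- as_pair_matrix(subsumptions)
  disj <- as_pair_matrix(disjointness)
  o <- structure(list(concepts = concepts, subsumptions = subs, disjointness = disj),
                 class = "domain_ontology")
  validate_domain_ontology(o)
  o
}

as_pair_matrix <- function(x) {
  if (is.null(x) || (is.list(x) && !length(x))) {
    return(matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  }
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(p) c(p[[1]], p[[2]])))
  x <- matrix(as.character(x), ncol = 2)
  dimnames(x) <- list(NULL, c("from", "to"))
  x
}

concept_ids <- function(onto) vapply(onto$concepts, `[[`, character(1), "id")

validate_domain_ontology <- function(onto) {
  ids <- concept_ids(onto)
  if (anyDuplicated(ids)) stop("duplicate concept id: ", ids[duplicated(ids)][1])
  refs <- c(onto$subsumptions, onto$disjointness)
  bad <- setdiff(refs, ids)
  if (length(bad)) stop("unknown concept in subsumption/disjointness: ", bad[1])
  # acyclicity of subsumption graph
  parents <- function(id) onto$subsumptions[onto$subsumptions[, 1] == id, 2]
  visiting <- character(); done <- character()
  visit <- function(id) {
    if (id %in% done) return(invisible())
    if (id %in% visiting) stop("cycle in concept subsumption at ", id)
    visiting <<- c(visiting, id)
    for (p in parents(id)) visit(p)
    visiting <<- setdiff(visiting, id)
    done <<- c(done, id)
  }
  for (id in ids) visit(id)
  invisible(onto)
}

#' Ancestor concept ids (reflexive) under the subsumption graph
#' @param onto domain ontology
#' @param id concept id
#' @return character vector including `id`
#' @export
concept_ancestors <- function(onto, id) {
  out <- id; queue <- id
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    ps <- onto$subsumptions[onto$subsumptions[, 1] == x, 2]
    new <- setdiff(ps, out)
    out <- c(out, new); queue <- c(queue, new)
  }
  out
}

#' @export
print.domain_ontology <- function(x, ...) {
  cat("Domain ontology:", length(x$concepts), "concepts,",
      nrow(x$subsumptions), "subsumptions,",
      nrow(x$disjointness), "disjointness pairs\n")
  invisible(x)
}

#' Concept annotations used anywhere in a model
#' @param model information model
#' @return character vector of concept ids (primary and qualifiers)
#' @export
model_concepts <- function(model) {
  out <- character()
  for (cl in model$classes) {
    out <- c(out, cl$annotation$primary, cl$annotation$qualifiers)
    for (at in cl$attributes)
      out <- c(out, at$annotation$primary, at$annotation$qualifiers)
  }
  unique(out)
}
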