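#' @title Model interchange format
#' @description A small, explicit XML schema (with a structurally identical
#'   JSON mirror) for annotated information models. The XML layout is:
#'   \preformatted{
#'   <informationModel project="..." version="..." prefix="..."
#'                     serviceURL="..."? namespace="..."?>
#'     <class name="...">
#'       <superclass name="..."/>*
#'       <annotation primary="..."> <qualifier concept="..."/>* </annotation>
#'       <attribute name="..." datatype="...">
#'         <annotation .../>
#'       </attribute>*
#'     </class>*
#'     <association source="..." target="..." role="..."/>*
#'   </informationModel>}
#'   The JSON mirror uses the same field names. Round-tripping either format
#'   reproduces a structurally identical model.
#' @name model-io
NULL

#' Serialize an information model
#' @param model an [information_model()]
#' @param format `"xml"` or `"json"`
#' @return character scalar with the serialized document
#' @export
write_model <- function(model, format = c("xml", "json")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") return(model_to_json(model))
  model_to_xml(model)
}

#' Read an information model
#' @param text serialized document (character scalar) or a file path
#' @param format `"xml"` or `"json"`
#' @return an [information_model()]; invariant violations error with element paths
#' @export
read_model <- function(text, format = c("xml", "json")) {
  format <- match.arg(format)
  text <- slurp(text)
  if (format == "json") model_from_json(text) else model_from_xml(text)
}

slurp <- function(text) {
  if (length(text) == 1L && !grepl("[<{\n]", text) && file.exists(text))
    return(paste(readLines(text, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
  paste(text, collapse = "\n")
}

## ---- JSON ------------------------------------------------------------------

annotation_to_list <- function(a) {
  list(primary = a$primary, qualifiers = as.list(a$qualifiers))
}

annotation_from_list <- function(x) {
  annotation(x$primary, unlist(x$qualifiers) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_to_json <- function(model) {
  doc <- list(
    project = model$project_name,
    version = model$version,
    prefix = model$prefix,
    serviceURL = model$service_url,
    namespace = model$namespace,
    classes = lapply(model$classes, function(cl) list(
      name = cl$name,
      superclasses = as.list(cl$superclasses),
      annotation = annotation_to_list(cl$annotation),
      attributes = lapply(cl$attributes, function(at) list(
        name = at$name, datatype = at$datatype,
        annotation = annotation_to_list(at$annotation)
      ))
    )),
    associations = lapply(model$associations, function(a)
      list(source = a$source, target = a$target, role = a$role))
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
}

model_from_json <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  information_model(
    project_name = x$project, version = x$version, prefix = x$prefix,
    service_url = x$serviceURL, namespace = x$namespace,
    classes = lapply(x$classes %||% list(), function(cl) class_spec(
      name = cl$name,
      annotation = annotation_from_list(cl$annotation),
      superclasses = unlist(cl$superclasses) %||% character(),
      attributes = lapply(cl$attributes %||% list(), function(at)
        attribute_spec(at$name, at$datatype, annotation_from_list(at$annotation)))
    )),
    associations = lapply(x$associations %||% list(), function(a)
      association_spec(a$source, a$target, a$role))
  )
}

## ---- XML -------------------------------------------------------------------

xml_annotation <- function(parent, a) {
  node <- xml2::xml_add_child(parent, "annotation", primary = a$primary)
  for (q in a$qualifiers) xml2::xml_add_child(node, "qualifier", concept = q)
  node
}

model_to_xml <- function(model) {
  doc <- xml2::xml_new_root("informationModel",
                            project = model$project_name,
                            version = model$version,
                            prefix = model$prefix)
  if (!is.null(model$service_url)) xml2::xml_set_attr(doc, "serviceURL", model$service_url)
  if (!is.null(model$namespace)) xml2::xml_set_attr(doc, "namespace", model$namespace)
  for (cl in model$classes) {
    cnode <- xml2::xml_add_child(doc, "class", name = cl$name)
    for (s in cl$superclasses) xml2::xml_add_child(cnode, "superclass", name = s)
    xml_annotation(cnode, cl$annotation)
    for (at in cl$attributes) {
      anode <- xml2::xml_add_child(cnode, "attribute", name = at$name, datatype = at$datatype)
      xml_annotation(anode, at$annotation)
    }
  }
  for (a in model$associations)
    xml2::xml_add_child(doc, "association", source = a$source, target = a$target, role = a$role)
  as.character(doc)
}

read_annotation_node <- function(parent) {
  node <- xml2::xml_find_first(parent, "./annotation")
  if (inherits(node, "xml_missing")) stop("missing annotation element")
  quals <- vapply(xml2::xml_find_all(node, "./qualifier"),
                  function(q) xml2::xml_attr(q, "concept"), character(1))
  annotation(xml2::xml_attr(node, "primary"), quals)
}

model_from_xml <- function(text) {
  doc <- xml2::read_xml(text)
  if (xml2::xml_name(doc) != "informationModel")
    stop("root element must be <informationModel>")
  attr_or_null <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else v
  }
  classes <- lapply(xml2::xml_find_all(doc, "./class"), function(cnode) {
    sups <- vapply(xml2::xml_find_all(cnode, "./superclass"),
                   function(s) xml2::xml_attr(s, "name"), character(1))
    atts <- lapply(xml2::xml_find_all(cnode, "./attribute"), function(anode) {
      attribute_spec(xml2::xml_attr(anode, "name"),
                     xml2::xml_attr(anode, "datatype"),
                     read_annotation_node(anode))
    })
    class_spec(xml2::xml_attr(cnode, "name"), read_annotation_node(cnode),
               superclasses = sups, attributes = atts)
  })
  assocs <- lapply(xml2::xml_find_all(doc, "./association"), function(anode)
    association_spec(xml2::xml_attr(anode, "source"),
                     xml2::xml_attr(anode, "target"),
                     xml2::xml_attr(anode, "role")))
  information_model(
    project_name = xml2::xml_attr(doc, "project"),
    version = xml2::xml_attr(doc, "version"),
    prefix = xml2::xml_attr(doc, "prefix"),
    service_url = attr_or_null(doc, "serviceURL"),
    namespace = attr_or_null(doc, "namespace"),
    classes = classes, associations = assocs
  )
}

## ---- domain ontology I/O ---------------------------------------------------

#' Serialize a domain ontology as JSON
#' @param onto a [domain_ontology()]
#' @return character scalar
#' @export
write_domain_ontology <- function(onto) {
  doc <- list(
    concepts = lapply(onto$concepts, function(k)
      c(list(id = k$id, name = k$name),
        if (!is.null(k$definition)) list(definition = k$definition))),
    subsumptions = apply(onto$subsumptions, 1, function(r) as.list(unname(r)), simplify = FALSE),
    disjointness = apply(onto$disjointness, 1, function(r) as.list(unname(r)), simplify = FALSE)
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
}

#' Read a domain ontology from JSON
#' @param text JSON text or file path
#' @return a [domain_ontology()]
#' @export
read_domain_ontology <- function(text) {
  x <- jsonlite::fromJSON(slurp(text), simplifyVector = FALSE)
  domain_ontology(
    concepts = lapply(x$concepts %||% list(), function(k)
      concept(k$id, k$name %||% k$id, k$definition)),
    subsumptions = lapply(x$subsumptions %||% list(), unlist),
    disjointness = lapply(x$disjointness %||% list(), unlist)
  )
}
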