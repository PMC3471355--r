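#' @title Terms, class expressions and axioms
#' @description Internal representation of the OWL-like axiom language used by
#'   the generated ontologies. Terms are prefixed names (`"cabio:Chromosome"`,
#'   `"u:UMLClass"`, `"n:Name"`, `"l:OWLList"`); class expressions and axioms
#'   are tagged lists. Only the EL-style constructs needed by the
#'   transformation exist: named classes, intersections, unions, existential
#'   restrictions, data-has-value (with a comparison operator for query
#'   restrictions) and data-range restrictions. There is deliberately no
#'   universal quantification.
#' @name terms
NULL

#' Build a prefixed term
#'
#' @param prefix namespace token (model prefix, or `"u"`, `"n"`, `"l"`)
#' @param local local name
#' @return character scalar `"prefix:local"`
#' @export
term <- function(prefix, local) {
  stopifnot(is.character(prefix), is.character(local), nzchar(prefix), nzchar(local))
  paste0(prefix, ":", local)
}

#' Split a prefixed term into prefix and local name
#'
#' @param x term string
#' @return list with `prefix` and `local`
#' @export
split_term <- function(x) {
  i <- regexpr(":", x, fixed = TRUE)
  if (i < 0) stop("not a prefixed term: ", x)
  list(prefix = substr(x, 1L, i - 1L), local = substr(x, i + 1L, nchar(x)))
}

term_prefix <- function(x) vapply(x, function(t) split_term(t)$prefix, character(1), USE.NAMES = FALSE)
term_local  <- function(x) vapply(x, function(t) split_term(t)$local,  character(1), USE.NAMES = FALSE)

## ---- class expressions -----------------------------------------------------

new_ce <- function(kind, ...) structure(list(kind = kind, ...), class = "oq_ce")

#' Class-expression constructors
#'
#' `ce_named` wraps a term; `ce_and`/`ce_or` take two or more
#' sub-expressions; `ce_some` is an existential restriction over an object
#' property; `ce_value` restricts a data property to a literal under a
#' comparison operator (`EQUAL_TO` by default); `ce_data` restricts a data
#' property to a datatype.
#'
#' @param x term string
#' @param ... sub-expressions (or a single list of them)
#' @param prop property term
#' @param filler class expression
#' @param value literal (character scalar)
#' @param op comparison operator name, one of the CQL predicate names
#' @param datatype XSD datatype term, e.g. `"xsd:string"`
#' @return an object of class `oq_ce`
#' @name class_expression
NULL

#' @rdname class_expression
#' @export
ce_named <- function(x) {
  if (inherits(x, "oq_ce")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  new_ce("named", term = x)
}

ce_args <- function(dots) {
  if (length(dots) == 1L && is.list(dots[[1]]) && !inherits(dots[[1]], "oq_ce")) dots <- dots[[1]]
  lapply(dots, ce_named)
}

#' @rdname class_expression
#' @export
ce_and <- function(...) {
  args <- ce_args(list(...))
  if (length(args) < 2L) stop("intersection needs at least 2 members")
  new_ce("and", args = args)
}

#' @rdname class_expression
#' @export
ce_or <- function(...) {
  args <- ce_args(list(...))
  if (length(args) < 2L) stop("union needs at least 2 members")
  new_ce("or", args = args)
}

#' @rdname class_expression
#' @export
ce_some <- function(prop, filler) new_ce("some", prop = prop, filler = ce_named(filler))

#' @rdname class_expression
#' @export
ce_value <- function(prop, value, op = "EQUAL_TO") {
  stopifnot(op %in% cql_predicates())
  new_ce("value", prop = prop, value = as.character(value), op = op)
}

#' @rdname class_expression
#' @export
ce_data <- function(prop, datatype) new_ce("data", prop = prop, datatype = datatype)

is_ce <- function(x) inherits(x, "oq_ce")

#' Structural equality of class expressions
#' @param a,b class expressions
#' @return logical
#' @export
ce_equal <- function(a, b) identical(unclass_rec(a), unclass_rec(b))

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}

#' Render a class expression in Manchester-like text
#' @param x class expression
#' @return character scalar
#' @export
ce_render <- function(x) {
  stopifnot(is_ce(x))
  switch(x$kind,
    named = x$term,
    and   = paste(vapply(x$args, ce_render_paren, character(1)), collapse = " and "),
    or    = paste(vapply(x$args, ce_render_paren, character(1)), collapse = " or "),
    some  = paste0(x$prop, " some ", ce_render_paren(x$filler)),
    value = paste0(x$prop, " ", comparison_symbol(x$op), " \"", x$value, "\""),
    data  = paste0(x$prop, " some ", x$datatype),
    stop("unknown expression kind: ", x$kind)
  )
}

ce_render_paren <- function(x) {
  if (x$kind %in% c("and", "or")) paste0("(", ce_render(x), ")") else ce_render(x)
}

comparison_symbol <- function(op) {
  c(EQUAL_TO = "=", NOT_EQUAL_TO = "!=", LIKE = "like",
    LESS_THAN = "<", LESS_THAN_EQUAL_TO = "<=",
    GREATER_THAN = ">", GREATER_THAN_EQUAL_TO = ">=",
    IS_NULL = "is null", IS_NOT_NULL = "is not null")[[op]]
}

symbol_comparison <- function(sym) {
  m <- c("=" = "EQUAL_TO", "!=" = "NOT_EQUAL_TO", "<" = "LESS_THAN",
         "<=" = "LESS_THAN_EQUAL_TO", ">" = "GREATER_THAN",
         ">=" = "GREATER_THAN_EQUAL_TO", "like" = "LIKE")
  if (!sym %in% names(m)) stop("unknown comparison operator: ", sym)
  m[[sym]]
}

## ---- axioms ----------------------------------------------------------------

new_axiom <- function(kind, ...) structure(list(kind = kind, ...), class = "oq_axiom")

#' Axiom constructors
#'
#' The axiom language mirrors what the UML-to-OWL transformation emits:
#' subsumption between class expressions, equivalence between named classes,
#' object sub-properties, a transitivity declaration, annotation assertions
#' (`ClassName`, `AttributeName`, `RoleName`) and concept disjointness.
#'
#' @param sub,super class expressions (or terms) / property terms
#' @param a,b named class terms / concept terms
#' @param prop object property term
#' @param subject annotated term
#' @param property one of `"ClassName"`, `"AttributeName"`, `"RoleName"`
#' @param value non-empty annotation string
#' @return an object of class `oq_axiom`
#' @name axiom
NULL

#' @rdname axiom
#' @export
ax_sub <- function(sub, super) new_axiom("sub_class", sub = ce_named(sub), super = ce_named(super))

#' @rdname axiom
#' @export
ax_equiv <- function(a, b) new_axiom("equivalent", a = a, b = b)

#' @rdname axiom
#' @export
ax_subprop <- function(sub, super) new_axiom("sub_property", sub = sub, super = super)

#' @rdname axiom
#' @export
ax_transitive <- function(prop) new_axiom("transitive", prop = prop)

#' @rdname axiom
#' @export
ax_annot <- function(subject, property, value) {
  stopifnot(property %in% c("ClassName", "AttributeName", "RoleName"), nzchar(value))
  new_axiom("annotation", subject = subject, property = property, value = value)
}

#' @rdname axiom
#' @export
ax_disjoint <- function(a, b) new_axiom("disjoint", a = a, b = b)

is_axiom <- function(x) inherits(x, "oq_axiom")

axiom_equal <- function(a, b) identical(unclass_rec(a), unclass_rec(b))

#' Render an axiom as text
#' @param x axiom
#' @return character scalar
#' @export
axiom_render <- function(x) {
  stopifnot(is_axiom(x))
  switch(x$kind,
    sub_class   = paste0(ce_render_paren(x$sub), " SubClassOf ", ce_render_paren(x$super)),
    equivalent  = paste0(x$a, " EquivalentTo ", x$b),
    sub_property = paste0(x$sub, " SubPropertyOf ", x$super),
    transitive  = paste0("Transitive(", x$prop, ")"),
    annotation  = paste0(x$property, "(", x$subject, ") = \"", x$value, "\""),
    disjoint    = paste0(x$a, " DisjointWith ", x$b),
    stop("unknown axiom kind: ", x$kind)
  )
}

#' The CQL predicate vocabulary
#' @return character vector of the nine predicate names
#' @export
cql_predicates <- function() {
  c("EQUAL_TO", "NOT_EQUAL_TO", "LIKE", "IS_NULL", "IS_NOT_NULL",
    "LESS_THAN", "LESS_THAN_EQUAL_TO", "GREATER_THAN", "GREATER_THAN_EQUAL_TO")
}

#' The DCQL foreign-predicate vocabulary (no LIKE / IS_NULL / IS_NOT_NULL)
#' @return character vector of the six foreign predicate names
#' @export
dcql_foreign_predicates <- function() {
  c("EQUAL_TO", "NOT_EQUAL_TO", "LESS_THAN", "LESS_THAN_EQUAL_TO",
    "GREATER_THAN", "GREATER_THAN_EQUAL_TO")
}
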