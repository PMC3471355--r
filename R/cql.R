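#' @title CQL and DCQL
#' @description ASTs mirroring the target query-language grammars, the
#'   comprehension-to-CQL/DCQL translation, deterministic XML emission, a
#'   grammar-checking parser for round-trip validation, and a direct
#'   interpreter over the in-memory object store. CQL is navigational: a
#'   query names one target class and constrains it with at most one child
#'   (an attribute predicate, a role-named association to a nested object,
#'   or a logical group of two or more of these). DCQL extends CQL with
#'   foreign associations, whose join condition relates an attribute of the
#'   enclosing class to an attribute of a class in a remote service.
#' @name cql
NULL

#' CQL AST constructors
#'
#' @param name fully-qualified class name / attribute name
#' @param child optional single child: `cql_attribute`, `cql_association` or
#'   `cql_group`
#' @param predicate one of [cql_predicates()] (foreign associations are
#'   restricted to [dcql_foreign_predicates()])
#' @param value literal; must be empty for `IS_NULL`/`IS_NOT_NULL`
#' @param role association role name
#' @param object nested `cql_object`
#' @param op `"AND"` or `"OR"`
#' @param members list of two or more children
#' @name cql_ast
NULL

#' @rdname cql_ast
#' @export
cql_object <- function(name, child = NULL) {
  stopifnot(nzchar(name))
  if (!is.null(child))
    stopifnot(inherits(child, c("cql_attribute", "cql_association",
                                "cql_group", "dcql_foreign_association")))
  structure(list(name = name, child = child), class = "cql_object")
}

#' @rdname cql_ast
#' @export
cql_attribute <- function(name, predicate, value = "") {
  stopifnot(predicate %in% cql_predicates())
  if (predicate %in% c("IS_NULL", "IS_NOT_NULL") && nzchar(value))
    stop(predicate, " takes no value")
  structure(list(name = name, predicate = predicate, value = as.character(value)),
            class = "cql_attribute")
}

#' @rdname cql_ast
#' @export
cql_association <- function(role, object) {
  stopifnot(nzchar(role), inherits(object, "cql_object"))
  structure(list(role = role, object = object), class = "cql_association")
}

#' @rdname cql_ast
#' @export
cql_group <- function(op, members) {
  stopifnot(op %in% c("AND", "OR"), length(members) >= 2L)
  structure(list(op = op, members = members), class = "cql_group")
}

#' @rdname cql_ast
#' @export
cql_query <- function(target, modifier = NULL) {
  stopifnot(inherits(target, "cql_object"))
  structure(list(target = target, modifier = modifier), class = "cql_query")
}

#' @rdname cql_ast
#' @param join list with `predicate`, `local_attribute`, `foreign_attribute`
#' @param url target service URL of the foreign object
#' @export
dcql_foreign_association <- function(join, object, url) {
  stopifnot(is.list(join),
            all(c("predicate", "local_attribute", "foreign_attribute") %in% names(join)))
  if (!join$predicate %in% dcql_foreign_predicates())
    stop("foreign predicate not allowed: ", join$predicate)
  stopifnot(inherits(object, "cql_object"), nzchar(url))
  structure(list(join = join, object = object, url = url),
            class = "dcql_foreign_association")
}

#' @rdname cql_ast
#' @param target_object `cql_object` (may contain foreign associations)
#' @param urls ordered non-empty character vector of target service URLs
#' @export
dcql_query <- function(target_object, urls) {
  stopifnot(inherits(target_object, "cql_object"), length(urls) >= 1L)
  structure(list(target = target_object, urls = as.character(urls)),
            class = "dcql_query")
}

#' Navigational class/role spine of a query
#'
#' The alternating sequence of class names and role names along the chain of
#' (foreign) associations, e.g.
#' `NucleicAcidSequence geneCollection Gene proteinCollection Protein`.
#'
#' @param q `cql_query`, `dcql_query` or `cql_object`
#' @return character vector
#' @export
cql_spine <- function(q) {
  obj <- if (inherits(q, c("cql_query", "dcql_query"))) q$target else q
  walk <- function(o) {
    out <- o$name
    kids <- if (is.null(o$child)) list()
            else if (inherits(o$child, "cql_group")) o$child$members
            else list(o$child)
    for (k in kids) {
      if (inherits(k, "cql_association")) out <- c(out, k$role, walk(k$object))
      if (inherits(k, "dcql_foreign_association")) out <- c(out, walk(k$object))
    }
    out
  }
  walk(obj)
}

## ---- MCC -> CQL ------------------------------------------------------------

# reconstruct the per-variable object structure of a flat comprehension
comprehension_structure <- function(c) {
  vars <- list()     # var -> list(class, parent_var, role, attrs, children)
  order <- character()
  for (q in c$qualifiers) {
    if (q$kind == "generator") {
      s <- q$source
      if (s$kind == "extent") {
        if (is.null(vars[[q$var]])) {
          vars[[q$var]] <- list(class = s$class, prefix = s$prefix,
                                parent = NA_character_, role = NA_character_,
                                attrs = list(), children = character())
          order <- c(order, q$var)
        } else {
          vars[[q$var]]$class <- s$class
          vars[[q$var]]$prefix <- s$prefix
        }
      } else if (s$kind == "path") {
        if (is.null(vars[[q$var]])) {
          vars[[q$var]] <- list(class = NA_character_, prefix = NA_character_,
                                parent = s$var, role = s$member,
                                attrs = list(), children = character())
          order <- c(order, q$var)
          if (!is.null(vars[[s$var]]))
            vars[[s$var]]$children <- c(vars[[s$var]]$children, q$var)
        }
      } else stop("comprehension must be normalized before target translation")
    }
  }
  filters <- list(); joins <- list()
  for (q in c$qualifiers) {
    if (q$kind != "filter") next
    if (q$lhs$kind == "path" && q$rhs$kind == "path") {
      joins[[length(joins) + 1L]] <- q
    } else if (q$lhs$kind == "path") {
      filters[[length(filters) + 1L]] <- q
    } else stop("filter must reference a bound variable on its left side")
  }
  list(vars = vars, order = order, filters = filters, joins = joins,
       header = c$header$var)
}

build_object_tree <- function(var, st, service_vars) {
  v <- st$vars[[var]]
  kids <- list()
  for (f in st$filters) {
    if (f$lhs$var == var)
      kids[[length(kids) + 1L]] <- cql_attribute(f$lhs$member, f$op, f$rhs$value)
  }
  for (ch in v$children) {
    if (!ch %in% service_vars) next
    kids[[length(kids) + 1L]] <-
      cql_association(st$vars[[ch]]$role, build_object_tree(ch, st, service_vars))
  }
  child <- if (!length(kids)) NULL
           else if (length(kids) == 1L) kids[[1]]
           else cql_group("AND", kids)
  cql_object(v$class, child)
}

#' Translate a normalized comprehension into a CQL query
#'
#' The target is the class of the header variable; each path/extent
#' generator pair becomes a nested association with the path's role name;
#' each filter becomes an attribute predicate on its variable's object;
#' multiple children of one object are wrapped in an AND group. Requires a
#' single-service bag comprehension (no join filters).
#'
#' @param c normalized `mcc_comprehension`
#' @return a `cql_query`
#' @export
from_mcc_cql <- function(c) {
  if (c$monoid != "bag") stop("CQL targets require the bag accumulator")
  st <- comprehension_structure(c)
  if (length(st$joins))
    stop("comprehension contains join filters; use from_mcc_dcql")
  prefixes <- unique(stats::na.omit(vapply(st$vars, `[[`, character(1), "prefix")))
  if (length(prefixes) > 1L)
    stop("comprehension spans several services; use from_mcc_dcql")
  cql_query(build_object_tree(st$header, st, names(st$vars)))
}

service_of_var <- function(st, var) {
  v <- st$vars[[var]]
  while (is.na(v$prefix) && !is.na(v$parent)) v <- st$vars[[v$parent]]
  root <- var
  while (!is.na(st$vars[[root]]$parent)) root <- st$vars[[root]]$parent
  st$vars[[root]]$prefix
}

#' Translate a normalized comprehension with join filters into DCQL
#'
#' The header variable's service supplies the target object; every join
#' filter (a filter between path expressions on variables of different
#' services) becomes a foreign association attached to its local variable's
#' object, carrying the join condition (foreign predicate, local and foreign
#' attribute names) and the foreign service's object tree and URL.
#'
#' @param c normalized `mcc_comprehension` spanning at least two services
#' @param services named character vector: model prefix -> service URL
#' @return a `dcql_query`
#' @export
from_mcc_dcql <- function(c, services) {
  if (c$monoid != "bag") stop("DCQL targets require the bag accumulator")
  st <- comprehension_structure(c)
  var_service <- vapply(names(st$vars), function(v) service_of_var(st, v),
                        character(1))
  if (length(unique(var_service)) < 2L || !length(st$joins))
    stop("single-service comprehension: use from_mcc_cql")
  missing <- setdiff(unique(var_service), names(services))
  if (length(missing)) stop("missing service URL for prefix: ", missing[1])
  local_service <- var_service[[st$header]]
  # build per-service trees, then hang foreign associations at the join vars
  foreign_assocs <- list()
  for (j in st$joins) {
    lv <- j$lhs$var; fv <- j$rhs$var
    if (var_service[[lv]] == var_service[[fv]])
      stop("join filter links variables of the same service")
    if (var_service[[lv]] != local_service) { tmp <- lv; lv <- fv; fv <- tmp
      j <- mcc_filter(mcc_path(lv, j$rhs$member), j$op, mcc_path(fv, j$lhs$member)) }
    if (!j$op %in% dcql_foreign_predicates())
      stop("foreign predicate not allowed: ", j$op)
    fs <- var_service[[fv]]
    foreign_obj <- build_object_tree(fv, st, names(st$vars)[var_service == fs])
    foreign_assocs[[length(foreign_assocs) + 1L]] <- list(
      at_var = lv,
      fa = dcql_foreign_association(
        join = list(predicate = j$op,
                    local_attribute = j$lhs$member,
                    foreign_attribute = j$rhs$member),
        object = foreign_obj,
        url = unname(services[[fs]])))
  }
  local_vars <- names(st$vars)[var_service == local_service]
  target <- build_object_tree_fa(st$header, st, local_vars, foreign_assocs)
  dcql_query(target, unname(services[[local_service]]))
}

build_object_tree_fa <- function(var, st, service_vars, foreign_assocs) {
  v <- st$vars[[var]]
  kids <- list()
  for (f in st$filters) {
    if (f$lhs$var == var)
      kids[[length(kids) + 1L]] <- cql_attribute(f$lhs$member, f$op, f$rhs$value)
  }
  for (fa in foreign_assocs) {
    if (fa$at_var == var) kids[[length(kids) + 1L]] <- fa$fa
  }
  for (ch in v$children) {
    if (!ch %in% service_vars) next
    kids[[length(kids) + 1L]] <-
      cql_association(st$vars[[ch]]$role,
                      build_object_tree_fa(ch, st, service_vars, foreign_assocs))
  }
  child <- if (!length(kids)) NULL
           else if (length(kids) == 1L) kids[[1]]
           else cql_group("AND", kids)
  cql_object(v$class, child)
}

## ---- XML emission ----------------------------------------------------------

cql_ns <- "http://ontoquery.example.org/schema/cql1"
dcql_ns <- "http://ontoquery.example.org/schema/dcql1"

emit_child <- function(parent, k) {
  if (inherits(k, "cql_attribute")) {
    xml2::xml_add_child(parent, "Attribute", name = k$name,
                        predicate = k$predicate, value = k$value)
  } else if (inherits(k, "cql_association")) {
    node <- xml2::xml_add_child(parent, "Association", roleName = k$role)
    emit_object(node, k$object)
  } else if (inherits(k, "cql_group")) {
    node <- xml2::xml_add_child(parent, "Group", logicalOp = k$op)
    for (m in k$members) emit_child(node, m)
  } else if (inherits(k, "dcql_foreign_association")) {
    node <- xml2::xml_add_child(parent, "ForeignAssociation",
                                targetServiceURL = k$url)
    xml2::xml_add_child(node, "JoinCondition",
                        predicate = k$join$predicate,
                        localAttributeName = k$join$local_attribute,
                        foreignAttributeName = k$join$foreign_attribute)
    fo <- xml2::xml_add_child(node, "ForeignObject")
    emit_object(fo, k$object)
  } else stop("unknown child type")
  invisible()
}

emit_object <- function(parent, obj) {
  node <- xml2::xml_add_child(parent, "Object", name = obj$name)
  if (!is.null(obj$child)) emit_child(node, obj$child)
  invisible(node)
}

#' Emit a CQL or DCQL query as XML
#'
#' Deterministic, namespace-qualified document; emitting the same AST twice
#' yields byte-identical text.
#'
#' @param q a `cql_query` or `dcql_query`
#' @return character scalar of XML
#' @export
emit_xml <- function(q) {
  if (inherits(q, "cql_query")) {
    doc <- xml2::xml_new_root("CQLQuery", xmlns = cql_ns)
    tgt <- xml2::xml_add_child(doc, "Target")
    emit_object(tgt, q$target)
    if (!is.null(q$modifier)) {
      xml2::xml_add_child(doc, "QueryModifier",
                          countOnly = tolower(as.character(q$modifier$count_only)))
    }
    return(as.character(doc))
  }
  if (inherits(q, "dcql_query")) {
    doc <- xml2::xml_new_root("DCQLQuery", xmlns = dcql_ns)
    tgt <- xml2::xml_add_child(doc, "TargetObject")
    emit_object(tgt, q$target)
    for (u in q$urls) {
      n <- xml2::xml_add_child(doc, "targetServiceURL")
      xml2::xml_set_text(n, u)
    }
    return(as.character(doc))
  }
  stop("not a CQL/DCQL query")
}

## ---- parsing ---------------------------------------------------------------

parse_object_node <- function(node, dcql) {
  kids <- xml2::xml_children(node)
  if (length(kids) > 1L)
    stop("grammar violation at <cqlObject>: an Object takes at most one child")
  child <- if (length(kids)) parse_child_node(kids[[1]], dcql) else NULL
  cql_object(xml2::xml_attr(node, "name"), child)
}

parse_child_node <- function(node, dcql) {
  nm <- xml2::xml_name(node)
  if (nm == "Attribute") {
    return(cql_attribute(xml2::xml_attr(node, "name"),
                         xml2::xml_attr(node, "predicate"),
                         xml2::xml_attr(node, "value")))
  }
  if (nm == "Association") {
    objs <- xml2::xml_children(node)
    if (length(objs) != 1L || xml2::xml_name(objs[[1]]) != "Object")
      stop("grammar violation at <Association>: exactly one Object expected")
    return(cql_association(xml2::xml_attr(node, "roleName"),
                           parse_object_node(objs[[1]], dcql)))
  }
  if (nm == "Group") {
    members <- lapply(xml2::xml_children(node), parse_child_node, dcql = dcql)
    if (length(members) < 2L)
      stop("grammar violation at <Group>: at least two members required")
    return(cql_group(xml2::xml_attr(node, "logicalOp"), members))
  }
  if (nm == "ForeignAssociation") {
    if (!dcql) stop("grammar violation: ForeignAssociation outside DCQL")
    jc <- xml2::xml_find_first(node, "./*[local-name()='JoinCondition']")
    fo <- xml2::xml_find_first(node, "./*[local-name()='ForeignObject']")
    if (inherits(jc, "xml_missing") || inherits(fo, "xml_missing"))
      stop("grammar violation at <ForeignAssociation>: JoinCondition and ForeignObject required")
    objs <- xml2::xml_children(fo)
    if (length(objs) != 1L)
      stop("grammar violation at <ForeignObject>: exactly one Object expected")
    return(dcql_foreign_association(
      join = list(predicate = xml2::xml_attr(jc, "predicate"),
                  local_attribute = xml2::xml_attr(jc, "localAttributeName"),
                  foreign_attribute = xml2::xml_attr(jc, "foreignAttributeName")),
      object = parse_object_node(objs[[1]], dcql),
      url = xml2::xml_attr(node, "targetServiceURL")))
  }
  stop("grammar violation: unexpected element <", nm, ">")
}

#' Parse a CQL or DCQL XML document
#'
#' Accepts exactly the language of the target grammars (single optional
#' child per object, groups of two or more members, the restricted foreign
#' predicate set) and names the violated production on rejection.
#' `parse_xml(emit_xml(q))` is structurally equal to `q`.
#'
#' @param text XML text
#' @return a `cql_query` or `dcql_query`
#' @export
parse_xml <- function(text) {
  doc <- xml2::read_xml(text)
  root <- xml2::xml_name(doc)
  if (root == "CQLQuery") {
    tgt <- xml2::xml_find_first(doc, "./*[local-name()='Target']")
    if (inherits(tgt, "xml_missing")) stop("grammar violation: <Target> required")
    objs <- xml2::xml_children(tgt)
    if (length(objs) != 1L) stop("grammar violation at <Target>: one Object expected")
    return(cql_query(parse_object_node(objs[[1]], dcql = FALSE)))
  }
  if (root == "DCQLQuery") {
    tgt <- xml2::xml_find_first(doc, "./*[local-name()='TargetObject']")
    if (inherits(tgt, "xml_missing")) stop("grammar violation: <TargetObject> required")
    objs <- xml2::xml_children(tgt)
    if (length(objs) != 1L) stop("grammar violation at <TargetObject>: one Object expected")
    urls <- vapply(xml2::xml_find_all(doc, "./*[local-name()='targetServiceURL']"),
                   xml2::xml_text, character(1))
    if (!length(urls)) stop("grammar violation: at least one targetServiceURL required")
    return(dcql_query(parse_object_node(objs[[1]], dcql = TRUE), urls))
  }
  stop("grammar violation: unknown root <", root, ">")
}

#' Structural equality of query ASTs
#' @param a,b queries or AST nodes
#' @return logical
#' @export
cql_equal <- function(a, b) identical(unclass_rec(a), unclass_rec(b))

## ---- random grammar walker -------------------------------------------------

#' Generate a random grammar-conformant query
#'
#' Walks the CQL (or DCQL) productions with bounded depth, for round-trip
#' testing of the emitter and parser.
#'
#' @param seed integer seed
#' @param dcql generate a DCQL query with a foreign association
#' @param max_depth nesting bound
#' @return a `cql_query` or `dcql_query`
#' @export
random_cql_query <- function(seed = 1, dcql = FALSE, max_depth = 3) {
  with_local_seed(seed, {
    rand_name <- function() paste0("C", sample(1:9, 1), sample(letters, 1))
    rand_attr <- function() {
      p <- sample(cql_predicates(), 1)
      cql_attribute(paste0("a", sample(1:9, 1)), p,
                    if (p %in% c("IS_NULL", "IS_NOT_NULL")) "" else
                      paste0("x", sample(1:99, 1)))
    }
    rand_object <- function(depth) {
      child <- NULL
      if (depth < max_depth) {
        roll <- runif(1)
        if (roll < 0.3) child <- rand_attr()
        else if (roll < 0.6) child <- cql_association(
          paste0("role", sample(1:9, 1)), rand_object(depth + 1))
        else if (roll < 0.8) {
          n <- sample(2:3, 1)
          members <- lapply(seq_len(n), function(i) {
            if (runif(1) < 0.5) rand_attr()
            else cql_association(paste0("role", sample(1:9, 1)),
                                 rand_object(depth + 1))
          })
          child <- cql_group(sample(c("AND", "OR"), 1), members)
        }
      }
      cql_object(rand_name(), child)
    }
    if (!dcql) return(cql_query(rand_object(1)))
    fa <- dcql_foreign_association(
      join = list(predicate = sample(dcql_foreign_predicates(), 1),
                  local_attribute = paste0("a", sample(1:9, 1)),
                  foreign_attribute = paste0("b", sample(1:9, 1))),
      object = rand_object(2),
      url = paste0("http://svc", sample(1:9, 1), ".example.org/"))
    base <- rand_object(2)
    target <- if (is.null(base$child)) cql_object(base$name, fa)
              else cql_object(base$name, cql_group("AND", list(base$child, fa)))
    dcql_query(target, paste0("http://svc0.example.org/"))
  })
}

## ---- interpreter -----------------------------------------------------------

#' Interpret a CQL query directly over an object store
#'
#' Independent operational semantics for emitted queries: returns the ids of
#' the target-class instances satisfying the constraint tree (associations
#' are satisfied when at least one linked object satisfies the nested
#' object; groups combine by AND/OR).
#'
#' @param q a `cql_query`
#' @param store an [object_store()]
#' @return character vector of matching object ids, sorted
#' @export
interpret_cql <- function(q, store) {
  stopifnot(inherits(q, "cql_query"))
  sat_obj <- function(obj, ast) {
    if (!ast$name %in% obj$classes) return(FALSE)
    if (is.null(ast$child)) return(TRUE)
    sat_child(obj, ast$child)
  }
  sat_child <- function(obj, k) {
    if (inherits(k, "cql_attribute")) {
      val <- obj$attrs[[k$name]]
      if (is.null(val)) val <- ""
      return(isTRUE(compare_values(val, k$predicate, k$value)))
    }
    if (inherits(k, "cql_association")) {
      ids <- obj$links[[k$role]]
      if (is.null(ids)) return(FALSE)
      return(any(vapply(ids, function(id) sat_obj(store$objects[[id]], k$object),
                        logical(1))))
    }
    if (inherits(k, "cql_group")) {
      vals <- vapply(k$members, function(m) sat_child(obj, m), logical(1))
      return(if (k$op == "AND") all(vals) else any(vals))
    }
    stop("cannot interpret child of class ", class(k)[1])
  }
  ext <- store_extent(store, q$target$name)
  sort(vapply(Filter(function(o) sat_obj(o, q$target), ext), `[[`, character(1), "id"))
}
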