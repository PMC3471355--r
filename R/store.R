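#' @title In-memory object store
#' @description A tiny synthetic object database used as the semantics
#'   oracle: objects carry an identity, a (qualified) class name, attribute
#'   values and association links by role name. The comprehension evaluator
#'   and the CQL interpreter both run against it, which is what lets the
#'   test suite check that emitted target queries mean the same thing as
#'   their intermediate comprehensions.
#' @name object-store
NULL

#' Construct an object store
#'
#' @param objects list of objects, each a list with `id`, `class` (qualified
#'   class name), `classes` (the class and its ancestors, qualified — the
#'   polymorphic extent membership), `attrs` (named list of scalar values)
#'   and `links` (named list: role name -> character vector of object ids)
#' @return object of class `object_store`
#' @export
object_store <- function(objects) {
  ids <- vapply(objects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate object id")
  names(objects) <- ids
  # resolve links and check referential integrity
  for (o in objects) for (role in names(o$links)) {
    missing <- setdiff(o$links[[role]], ids)
    if (length(missing)) stop("link to missing object: ", missing[1])
  }
  structure(list(objects = objects), class = "object_store")
}

#' @export
print.object_store <- function(x, ...) {
  cat("Object store with", length(x$objects), "objects\n")
  invisible(x)
}

store_extent <- function(store, class_name) {
  unname(Filter(function(o) class_name %in% o$classes, store$objects))
}

#' Build a random object store for an information model
#'
#' Creates `n_per_class` instances of every class with random short string
#' attribute values (drawn from a small pool so that filters sometimes
#' match) and, for every association applicable to an object's class
#' (declared or inherited), links to a random subset of the target class's
#' instances. Deterministic for a fixed seed.
#'
#' @param model an [information_model()]
#' @param n_per_class instances per class
#' @param seed integer seed
#' @param values pool of attribute values
#' @return an [object_store()]
#' @export
build_store <- function(model, n_per_class = 3, seed = 1,
                        values = c("alpha", "beta", "gamma", "17")) {
  with_local_seed(seed, {
    qname <- function(nm) qualified_class_name(model, nm)
    objs <- list()
    for (cl in model$classes) {
      ancs <- c(cl$name, model_ancestors(model, cl$name))
      for (i in seq_len(n_per_class)) {
        attrs <- list()
        for (anc in ancs) for (at in model_class(model, anc)$attributes)
          attrs[[at$name]] <- sample(values, 1)
        objs[[length(objs) + 1L]] <- list(
          id = paste0(cl$name, "#", i),
          class = qname(cl$name),
          classes = vapply(ancs, qname, character(1), USE.NAMES = FALSE),
          attrs = attrs,
          links = list())
      }
    }
    names(objs) <- vapply(objs, `[[`, character(1), "id")
    # links: association applies to declaring class and its descendants
    for (a in model$associations) {
      holders <- c(a$source, model_descendants(model, a$source))
      targets <- names(objs)[vapply(objs, function(o)
        qname(a$target) %in% o$classes, logical(1))]
      for (id in names(objs)) {
        o <- objs[[id]]
        cls_local <- sub("#.*$", "", id)
        if (!cls_local %in% holders) next
        k <- sample(0:min(2, length(targets)), 1)
        objs[[id]]$links[[a$role]] <-
          if (k > 0) sample(targets, k) else character()
      }
    }
    object_store(unname(objs))
  })
}
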