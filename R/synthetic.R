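#' @title Synthetic model generation
#' @description A seeded generator of random annotated information models,
#'   emulating metadata-registry projects: a class hierarchy of bounded
#'   depth, a few typed attributes per class, concept annotations drawn from
#'   a supplied vocabulary, and directed associations sampled independently
#'   per ordered class pair with a fixed density. Used throughout the test
#'   suite as the source of round-trip, ontology-law and pipeline cases.
#' @name synthetic
NULL

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random annotated information model
#'
#' Deterministic for a fixed argument set including `seed`. Each class gets a
#' primary concept (and occasionally qualifiers) drawn uniformly from the
#' vocabulary, zero to three annotated attributes, and at most one superclass
#' chosen so that no inheritance chain exceeds `depth` classes. Each ordered
#' pair of distinct classes receives an association independently with
#' probability `assoc_density`; the role name is derived from the target
#' class, so `(source, role)` pairs are unique by construction.
#'
#' @param n_classes number of classes (>= 1)
#' @param depth maximum hierarchy depth in classes (>= 1)
#' @param assoc_density association probability per ordered class pair, in
#'   `[0, 1]`
#' @param vocab a [domain_ontology()] supplying annotation concepts
#' @param seed integer seed
#' @param prefix model prefix
#' @return an [information_model()]
#' @export
generate_synthetic_model <- function(n_classes, depth = 3, assoc_density = 0.1,
                                     vocab = fixture_domain_ontology(), seed = 1,
                                     prefix = "syn") {
  stopifnot(n_classes >= 1, depth >= 1, assoc_density >= 0, assoc_density <= 1)
  ids <- concept_ids(vocab)
  if (!length(ids)) stop("empty vocabulary")
  with_local_seed(seed, {
    cn <- sprintf("Class%02d", seq_len(n_classes))
    level <- integer(n_classes)  # depth of each class, 1-based
    supers <- vector("list", n_classes)
    rand_annotation <- function() {
      nq <- if (runif(1) < 0.3) sample(1:2, 1) else 0L
      annotation(sample(ids, 1), if (nq) sample(ids, nq) else character())
    }
    classes <- vector("list", n_classes)
    for (i in seq_len(n_classes)) {
      parent <- character(); level[i] <- 1L
      if (i > 1L && depth > 1L && runif(1) < 0.5) {
        eligible <- which(level[seq_len(i - 1L)] < depth)
        if (length(eligible)) {
          p <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
          parent <- cn[p]; level[i] <- level[p] + 1L
        }
      }
      n_attr <- sample(0:3, 1)
      atts <- lapply(seq_len(n_attr), function(k)
        attribute_spec(paste0("attr", k), sample(model_datatypes(), 1), rand_annotation()))
      classes[[i]] <- class_spec(cn[i], rand_annotation(),
                                 superclasses = parent, attributes = atts)
    }
    assocs <- list()
    for (i in seq_len(n_classes)) for (j in seq_len(n_classes)) {
      if (i != j && runif(1) < assoc_density) {
        role <- paste0(tolower(substr(cn[j], 1, 1)), substr(cn[j], 2, nchar(cn[j])),
                       "Collection")
        assocs[[length(assocs) + 1L]] <- association_spec(cn[i], cn[j], role)
      }
    }
    information_model(project_name = paste0("Synthetic-", seed), version = "1.0",
                      prefix = prefix, classes = classes, associations = assocs)
  })
}

#' Generate a random toy domain ontology
#'
#' Concepts `K01..Kn`, a random forest of subsumptions (each concept may pick
#' one parent among earlier concepts) and optional random disjointness pairs.
#' Used as the signature-preservation oracle input for module extraction.
#'
#' @param n_concepts number of concepts
#' @param p_parent probability a concept has a parent
#' @param n_disjoint number of disjointness pairs to sample
#' @param seed integer seed
#' @return a [domain_ontology()]
#' @export
generate_synthetic_ontology <- function(n_concepts = 12, p_parent = 0.6,
                                        n_disjoint = 1, seed = 1) {
  stopifnot(n_concepts >= 1)
  with_local_seed(seed, {
    ids <- sprintf("K%02d", seq_len(n_concepts))
    subs <- list()
    for (i in seq_along(ids)) {
      if (i > 1L && runif(1) < p_parent) {
        p <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1)
        subs[[length(subs) + 1L]] <- c(ids[i], ids[p])
      }
    }
    disj <- list()
    if (n_disjoint > 0 && n_concepts >= 2) {
      for (k in seq_len(n_disjoint)) {
        pair <- sample(ids, 2)
        disj[[length(disj) + 1L]] <- pair
      }
    }
    domain_ontology(lapply(ids, concept), subs, disj)
  })
}
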