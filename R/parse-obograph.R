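#' Parse an obographs JSON ontology
#'
#' Reads the JSON graph serialization that the Gene Ontology publishes:
#' `nodes` become class/property declarations (with labels and the
#' deprecated flag), `is_a` edges become atomic SubClassOf axioms, every
#' other edge `sub -P-> obj` becomes `sub SubClassOf (P some obj)`,
#' `logicalDefinitionAxioms` become EquivalentClasses between the defined
#' class and the genus/differentia conjunction, and `propertyChainAxioms`
#' become binary property-chain axioms. IRIs are normalized to CURIEs.
#'
#' @param text a JSON string, a file path, or a parsed list (as from
#'   [jsonlite::fromJSON()] with `simplifyVector = FALSE`).
#' @return an [el_ontology()].
#' @export
parse_obograph <- function(text) {
  if (is.character(text)) {
    doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  } else {
    doc <- text
  }
  graphs <- if (!is.null(doc$graphs)) doc$graphs else list(doc)
  parts <- lapply(graphs, parse_obograph_one)
  if (length(parts) == 1L) parts[[1L]] else merge_ontologies(parts)
}

parse_obograph_one <- function(g) {
  nodes <- g$nodes %||% list()
  edges <- g$edges %||% list()

  cls <- list()
  prp <- list()
  for (nd in nodes) {
    if (is.null(nd$id)) {
      stop("obographs parse error: node without an id field", call. = FALSE)
    }
    id <- curie(nd$id)
    type <- nd$type %||% "CLASS"
    rec <- list(
      id = id,
      label = nd$lbl %||% NA_character_,
      deprecated = isTRUE(nd$meta$deprecated)
    )
    if (identical(type, "PROPERTY")) prp[[id]] <- rec else cls[[id]] <- rec
  }

  declared <- names(cls)
  axioms <- list()
  extra_props <- character()
  for (ed in edges) {
    if (is.null(ed$sub) || is.null(ed$obj) || is.null(ed$pred)) {
      stop("obographs parse error: edge with missing sub/pred/obj", call. = FALSE)
    }
    sub <- curie(ed$sub)
    obj <- curie(ed$obj)
    for (x in c(sub, obj)) {
      if (!x %in% declared) {
        stop("obographs referential error: edge references undeclared node ", x,
          call. = FALSE
        )
      }
    }
    if (identical(ed$pred, "is_a")) {
      axioms <- c(axioms, list(ax_sub(sub, obj)))
    } else {
      p <- curie(ed$pred)
      extra_props <- c(extra_props, p)
      axioms <- c(axioms, list(ax_sub(sub, ce_some(p, obj))))
    }
  }

  for (ld in g$logicalDefinitionAxioms %||% list()) {
    defined <- curie(ld$definedClassId)
    genus <- vapply(ld$genusIds %||% list(), function(x) curie(x), character(1))
    restr <- lapply(ld$restrictions %||% list(), function(r) {
      p <- curie(r$propertyId)
      extra_props <<- c(extra_props, p)
      ce_some(p, curie(r$fillerId))
    })
    conjuncts <- c(lapply(genus, ce_named), restr)
    if (length(conjuncts) == 0L) next
    rhs <- if (length(conjuncts) == 1L) conjuncts[[1L]] else do.call(ce_and, conjuncts)
    axioms <- c(axioms, list(ax_equiv(ce_named(defined), rhs)))
  }

  for (pc in g$propertyChainAxioms %||% list()) {
    chain <- vapply(pc$chainPredicateIds, function(x) curie(x), character(1))
    if (length(chain) != 2L) {
      stop("only binary property chains are supported (got length ", length(chain), ")",
        call. = FALSE
      )
    }
    sup <- curie(pc$predicateId)
    extra_props <- c(extra_props, chain, sup)
    axioms <- c(axioms, list(ax_chain(chain[1L], chain[2L], sup)))
  }

  cls_tbl <- tibble::tibble(
    id = names(cls),
    label = vapply(cls, function(x) x$label, character(1), USE.NAMES = FALSE),
    obsolete = vapply(cls, function(x) x$deprecated, logical(1), USE.NAMES = FALSE)
  )
  prp_ids <- union(names(prp), unique(extra_props))
  prp_tbl <- tibble::tibble(
    id = prp_ids,
    label = vapply(
      prp_ids,
      function(i) if (!is.null(prp[[i]])) prp[[i]]$label else NA_character_,
      character(1)
    ),
    transitive = FALSE,
    reflexive = FALSE
  )
  el_ontology(classes = cls_tbl, properties = prp_tbl, axioms = axioms)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
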