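#' Construct an EL ontology
#'
#' An `el_ontology` bundles the class inventory, the object-property inventory
#' and the logical axioms of an EL-profile ontology (e.g. GO merged with its
#' CL/Uberon/ChEBI imports). Classes and properties referenced by axioms must
#' be declared; undeclared references are an error so that downstream
#' reasoning never meets a dangling identifier.
#'
#' @param classes tibble with columns `id`, and optionally `label`,
#'   `obsolete`; or a character vector of class ids.
#' @param properties tibble with columns `id`, and optionally `label`,
#'   `transitive`, `reflexive`; or a character vector of property ids.
#' @param axioms list of [ax_sub()]-style axioms. Duplicate axioms (after
#'   canonical ordering of conjuncts) are collapsed.
#' @param check validate referential closure (default `TRUE`).
#' @return an object of class `el_ontology` with elements `classes`
#'   (tibble: id, label, namespace, obsolete), `properties` (tibble: id,
#'   label, transitive, reflexive) and `axioms` (list).
#' @examples
#' el_ontology(
#'   classes = c("GO:1", "GO:2"),
#'   properties = "part_of",
#'   axioms = list(ax_sub("GO:1", ce_some("part_of", "GO:2")))
#' )
#' @export
el_ontology <- function(classes = character(), properties = character(),
                        axioms = list(), check = TRUE) {
  classes <- as_class_tbl(classes)
  properties <- as_prop_tbl(properties)
  if (anyDuplicated(classes$id)) {
    stop("duplicate class ids: ",
      paste(unique(classes$id[duplicated(classes$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(properties$id)) {
    stop("duplicate property ids: ",
      paste(unique(properties$id[duplicated(properties$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  keys <- vapply(axioms, axiom_key, character(1))
  axioms <- axioms[!duplicated(keys)]
  axioms <- axioms[order(keys[!duplicated(keys)])]
  ont <- structure(
    list(classes = classes, properties = properties, axioms = axioms),
    class = "el_ontology"
  )
  if (check) validate_ontology(ont)
  ont
}

as_class_tbl <- function(x) {
  if (is.character(x)) x <- tibble::tibble(id = x)
  x <- tibble::as_tibble(x)
  stopifnot("id" %in% names(x))
  x$id <- curie(x$id)
  if (!"label" %in% names(x)) x$label <- NA_character_
  if (!"obsolete" %in% names(x)) x$obsolete <- FALSE
  x$obsolete[is.na(x$obsolete)] <- FALSE
  x$namespace <- curie_prefix(x$id)
  x[, c("id", "label", "namespace", "obsolete")]
}

as_prop_tbl <- function(x) {
  if (is.character(x)) x <- tibble::tibble(id = x)
  x <- tibble::as_tibble(x)
  stopifnot("id" %in% names(x))
  x$id <- curie(x$id)
  if (!"label" %in% names(x)) x$label <- NA_character_
  if (!"transitive" %in% names(x)) x$transitive <- FALSE
  if (!"reflexive" %in% names(x)) x$reflexive <- FALSE
  x$transitive[is.na(x$transitive)] <- FALSE
  x$reflexive[is.na(x$reflexive)] <- FALSE
  x[, c("id", "label", "transitive", "reflexive")]
}

validate_ontology <- function(ont) {
  cls <- unique(unlist(lapply(ont$axioms, axiom_class_ids), use.names = FALSE))
  missing_cls <- setdiff(cls, ont$classes$id)
  if (length(missing_cls)) {
    stop("axioms reference undeclared classes: ",
      paste(missing_cls, collapse = ", "),
      call. = FALSE
    )
  }
  prp <- unique(unlist(lapply(ont$axioms, axiom_prop_ids), use.names = FALSE))
  missing_prp <- setdiff(prp, ont$properties$id)
  if (length(missing_prp)) {
    stop("axioms reference undeclared properties: ",
      paste(missing_prp, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(ont)
}

#' @export
print.el_ontology <- function(x, ...) {
  cat(
    "<el_ontology> ", nrow(x$classes), " classes, ",
    nrow(x$properties), " properties, ",
    length(x$axioms), " axioms\n",
    sep = ""
  )
  invisible(x)
}

#' Merge ontologies
#'
#' Takes the union of classes, properties and axioms of several ontologies,
#' as when GO is combined with its ChEBI, CL and Uberon import modules.
#' Duplicate declarations collapse; where the same id carries different
#' labels the first occurrence wins with a warning. The same property id
#' declared with conflicting `transitive`/`reflexive` flags is an error,
#' since that changes entailments.
#'
#' @param parts nonempty list of `el_ontology` objects (or several ontologies
#'   passed via `...`).
#' @param ... ontologies, if `parts` is a single ontology.
#' @return a merged `el_ontology`.
#' @export
merge_ontologies <- function(parts, ...) {
  if (inherits(parts, "el_ontology")) parts <- c(list(parts), list(...))
  stopifnot(length(parts) >= 1L)
  for (p in parts) stopifnot(inherits(p, "el_ontology"))

  classes <- dplyr::bind_rows(lapply(parts, `[[`, "classes"))
  cl_lab <- dplyr::distinct(classes[!is.na(classes$label), c("id", "label")])
  dup_lab <- unique(cl_lab$id[duplicated(cl_lab$id)])
  if (length(dup_lab)) {
    warning(
      "conflicting labels for ", paste(dup_lab, collapse = ", "),
      "; keeping first occurrence",
      call. = FALSE
    )
  }
  classes <- classes |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      label = first_non_na(.data$label),
      obsolete = any(.data$obsolete),
      .groups = "drop"
    )

  props <- dplyr::bind_rows(lapply(parts, `[[`, "properties"))
  flag_conflict <- props |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      conflict = dplyr::n_distinct(.data$transitive) > 1L ||
        dplyr::n_distinct(.data$reflexive) > 1L,
      .groups = "drop"
    )
  if (any(flag_conflict$conflict)) {
    stop("conflicting transitive/reflexive flags for properties: ",
      paste(flag_conflict$id[flag_conflict$conflict], collapse = ", "),
      call. = FALSE
    )
  }
  pr_lab <- dplyr::distinct(props[!is.na(props$label), c("id", "label")])
  dup_plab <- unique(pr_lab$id[duplicated(pr_lab$id)])
  if (length(dup_plab)) {
    warning(
      "conflicting labels for ", paste(dup_plab, collapse = ", "),
      "; keeping first occurrence",
      call. = FALSE
    )
  }
  props <- props |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      label = first_non_na(.data$label),
      transitive = .data$transitive[1L],
      reflexive = .data$reflexive[1L],
      .groups = "drop"
    )

  el_ontology(
    classes = classes,
    properties = props,
    axioms = unlist(lapply(parts, `[[`, "axioms"), recursive = FALSE)
  )
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[1L] else NA_character_
}

#' Extend an ontology with additional declarations and axioms
#'
#' Existing declarations win on conflict; new axioms are appended (and
#' deduplicated against the existing ones).
#'
#' @param ont an `el_ontology`.
#' @param classes,properties declarations to add (character vector or
#'   tibble, as in [el_ontology()]).
#' @param axioms list of axioms to add.
#' @return the extended `el_ontology`.
#' @export
ont_extend <- function(ont, classes = character(), properties = character(),
                       axioms = list()) {
  el_ontology(
    classes = dplyr::bind_rows(ont$classes, as_class_tbl(classes)) |>
      dplyr::distinct(.data$id, .keep_all = TRUE),
    properties = dplyr::bind_rows(ont$properties, as_prop_tbl(properties)) |>
      dplyr::distinct(.data$id, .keep_all = TRUE),
    axioms = c(ont$axioms, axioms)
  )
}

#' Look up class labels
#' @param ont an `el_ontology`.
#' @param ids character vector of class ids.
#' @return character vector of labels (`NA` where absent).
#' @export
class_labels <- function(ont, ids) {
  ont$classes$label[match(curie(ids), ont$classes$id)]
}
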