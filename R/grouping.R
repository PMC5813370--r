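# Grouping object properties: bespoke super-properties whose subproperties
# and property chains emulate disjunction within OWL 2 EL. A single query
# `grouping_property some filler` then returns the union of what the member
# routes return; a reflexive grouping property additionally returns the
# filler class itself (the "a synapse OR part of a synapse" pattern).

#' Define a grouping property
#'
#' @param name id of the grouping super-property; must differ from all
#'   member property ids.
#' @param subproperties character vector of property ids placed directly
#'   under the grouping property.
#' @param chains list of length-2 character vectors `c(r1, r2)`; each chain
#'   induces a named intermediate property `r1_o_r2` with
#'   `r1 o r2 -> r1_o_r2` and `r1_o_r2` a subproperty of the grouping
#'   property.
#' @param reflexive should the grouping property be reflexive?
#' @param template human-readable description template containing the
#'   `{filler}` placeholder (at least once); instantiated by
#'   [describe_query()].
#' @return an object of class `grouping_spec`.
#' @examples
#' grouping_spec(
#'   "participant_OR_reg_participant",
#'   subproperties = "has_participant",
#'   chains = list(c("regulates", "has_participant")),
#'   template = "A process in which a {filler} participates, or that regulates a process in which a {filler} participates."
#' )
#' @export
grouping_spec <- function(name, subproperties = character(), chains = list(),
                          reflexive = FALSE, template = "{filler}") {
  stopifnot(is.character(name), length(name) == 1L)
  chains <- lapply(chains, function(ch) {
    ch <- as.character(ch)
    if (length(ch) != 2L) stop("each chain must have exactly two properties", call. = FALSE)
    ch
  })
  members <- c(subproperties, unlist(chains, use.names = FALSE))
  if (name %in% members) {
    stop("grouping property name must differ from its member properties", call. = FALSE)
  }
  if (!grepl("{filler}", template, fixed = TRUE)) {
    stop("description template must contain the {filler} placeholder", call. = FALSE)
  }
  structure(
    list(
      name = name, subproperties = unique(subproperties), chains = chains,
      reflexive = isTRUE(reflexive), template = template
    ),
    class = "grouping_spec"
  )
}

#' @export
print.grouping_spec <- function(x, ...) {
  cat(
    "<grouping_spec> ", x$name,
    if (x$reflexive) " (reflexive)", "\n  subproperties: ",
    paste(x$subproperties, collapse = ", "), "\n  chains: ",
    paste(vapply(x$chains, paste, character(1), collapse = " o "), collapse = "; "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Materialize a grouping property as axioms
#'
#' Emits `SubObjectPropertyOf(p, name)` for each subproperty; for each chain
#' `(r1, r2)` a named intermediate property `r1_o_r2`, the chain axiom
#' `r1 o r2 -> r1_o_r2`, and `SubObjectPropertyOf(r1_o_r2, name)`; and sets
#' the reflexive flag on the grouping property when requested.
#'
#' @param spec a [grouping_spec()].
#' @return list with `properties` (tibble: id, label, transitive, reflexive —
#'   declarations for the grouping property and chain intermediates) and
#'   `axioms` (list of axioms).
#' @export
make_grouping_property <- function(spec) {
  stopifnot(inherits(spec, "grouping_spec"))
  axioms <- lapply(spec$subproperties, function(p) ax_subprop(p, spec$name))
  chain_props <- character()
  for (ch in spec$chains) {
    inter <- paste0(ch[1L], "_o_", ch[2L])
    chain_props <- c(chain_props, inter)
    axioms <- c(
      axioms,
      list(ax_chain(ch[1L], ch[2L], inter), ax_subprop(inter, spec$name))
    )
  }
  list(
    properties = tibble::tibble(
      id = c(spec$name, chain_props),
      label = NA_character_,
      transitive = FALSE,
      reflexive = c(spec$reflexive, rep(FALSE, length(chain_props)))
    ),
    axioms = axioms
  )
}

#' Shipped grouping-property presets
#'
#' The preset grouping properties covering the documented query patterns:
#' `participant_OR_reg_participant` (direct participation plus the
#' `regulates o has_participant` chain), `occurs_in_OR_has_participant`,
#' the reflexive `structure_grouping` (self OR part OR
#' results-in-organization-of OR participant; the synapse-style pattern) and
#' `cell_grouping` (part OR participant OR occurs-in OR development; the
#' T-cell-style pattern). Presets are data, not code: they are read from a
#' JSON sidecar of the same shape accepted by [read_grouping_config()], so
#' new patterns are added by configuration.
#'
#' @param path optional path to a grouping-property config JSON; defaults to
#'   the packaged presets.
#' @return named list of [grouping_spec()] objects.
#' @export
standard_grouping_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grouping_presets.json", package = "owlsets")
  }
  read_grouping_config(path)
}

#' Read grouping-property definitions from a JSON config
#'
#' @param path JSON file: an array of objects with fields `name`,
#'   `subproperties`, `chains` (array of 2-element arrays), `reflexive`,
#'   `template`.
#' @return named list of [grouping_spec()] objects.
#' @export
read_grouping_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(x) {
    grouping_spec(
      name = x$name,
      subproperties = as.character(unlist(x$subproperties)),
      chains = lapply(x$chains, function(ch) as.character(unlist(ch))),
      reflexive = isTRUE(x$reflexive),
      template = x$template
    )
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' All axioms and declarations for the preset grouping vocabulary
#'
#' Combines [make_grouping_property()] over every preset and adds the base
#' relations they mention (`has_participant`, `occurs_in`, `part_of`,
#' `regulates` with its `positively_regulates`/`negatively_regulates`
#' subproperties, `results_in_development_of`,
#' `results_in_organization_of`). Applying the result twice yields the same
#' axiom multiset.
#'
#' @param groupings named list of [grouping_spec()]s (default: the presets).
#' @return list with `properties` (tibble of declarations) and `axioms`.
#' @export
standard_grouping_axioms <- function(groupings = standard_grouping_specs()) {
  base <- tibble::tibble(
    id = c(
      "has_participant", "occurs_in", "part_of", "regulates",
      "positively_regulates", "negatively_regulates",
      "results_in_development_of", "results_in_organization_of"
    ),
    label = gsub("_", " ", id),
    transitive = id == "part_of",
    reflexive = FALSE
  )
  axioms <- list(
    ax_subprop("positively_regulates", "regulates"),
    ax_subprop("negatively_regulates", "regulates")
  )
  props <- base
  for (spec in groupings) {
    made <- make_grouping_property(spec)
    props <- dplyr::bind_rows(props, made$properties)
    axioms <- c(axioms, made$axioms)
  }
  props <- dplyr::distinct(props, .data$id, .keep_all = TRUE)
  keys <- vapply(axioms, axiom_key, character(1))
  list(properties = props, axioms = axioms[!duplicated(keys)])
}

#' Add the grouping vocabulary to an ontology
#'
#' @param ont an [el_ontology()].
#' @param groupings named list of [grouping_spec()]s (default: presets).
#' @return the extended ontology.
#' @export
add_grouping_axioms <- function(ont, groupings = standard_grouping_specs()) {
  ax <- standard_grouping_axioms(groupings)
  ont_extend(ont, properties = ax$properties, axioms = ax$axioms)
}

#' Human-readable description of a mapping query
#'
#' Instantiates the grouping property's description template with the filler
#' class label, e.g. the `participant_OR_reg_participant` template applied
#' to the class labelled "cannabinoid" yields "A process in which a
#' cannabinoid participates, or that regulates a process in which a
#' cannabinoid participates." Every occurrence of `{filler}` is replaced.
#' A filler without a label falls back to its CURIE with a warning.
#'
#' @param spec a [grouping_spec()].
#' @param filler a class id plus `label`, given either as a one-row tibble /
#'   list with `id` and `label`, or a bare id with `label` supplied
#'   separately.
#' @param label optional label overriding the filler's.
#' @return length-one character description.
#' @export
describe_query <- function(spec, filler, label = NULL) {
  stopifnot(inherits(spec, "grouping_spec"))
  if (is.list(filler)) {
    label <- label %||% filler$label
    filler <- filler$id
  }
  if (is.null(label) || is.na(label) || !nzchar(label)) {
    warning("filler ", filler, " has no label; using its identifier in the description",
      call. = FALSE
    )
    label <- filler
  }
  gsub("{filler}", label, spec$template, fixed = TRUE)
}
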