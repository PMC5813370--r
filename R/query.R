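# DL queries: a fresh query class Q is made equivalent to the query
# expression, the extended ontology is normalized and saturated, and the
# named classes subsuming / subsumed by Q are read off the saturation.
# Several queries share one saturation (batching), which is how the mapping
# pipeline runs a whole mapping table against a single classification.

QUERY_PREFIX <- "Q"

#' Answer an EL DL query
#'
#' Returns the named classes equivalent to and strictly subsumed by an EL
#' class expression — the combined list a mapping query contributes to a
#' term set. Results are filtered to the requested CURIE prefixes (GO by
#' default) and to non-obsolete classes; obsolete classes that would have
#' matched are reported separately so that results tables can carry an
#' "is obsolete" column. Query-internal and normalization-internal classes
#' never appear.
#'
#' @param ont an [el_ontology()] (already containing any grouping-property
#'   axioms the expression relies on).
#' @param expr an [ce_named()]/[ce_and()]/[ce_some()] expression over the
#'   ontology's signature.
#' @param result_prefixes CURIE prefixes to keep (default `"GO"`).
#' @return an object of class `el_query_result`: `query_expr`, and tibbles
#'   `equivalents`, `descendants`, `obsolete` (columns id, label), each
#'   ordered lexicographically by id.
#' @examples
#' fx <- toy_cannabinoid_ontology()
#' q <- el_query(fx$ontology, ce_some("participant_OR_reg_participant", "CHEBI:67194"))
#' q$descendants$id
#' @export
el_query <- function(ont, expr, result_prefixes = "GO") {
  el_query_batch(ont, list(q = as_expr(expr)), result_prefixes)[[1L]]
}

#' Answer a batch of EL DL queries over one shared saturation
#'
#' @param ont an [el_ontology()].
#' @param exprs named list of query expressions.
#' @param result_prefixes CURIE prefixes to keep in results.
#' @return named list of `el_query_result` objects, one per expression.
#' @export
el_query_batch <- function(ont, exprs, result_prefixes = "GO") {
  stopifnot(inherits(ont, "el_ontology"), length(exprs) >= 1L)
  if (is.null(names(exprs)) || any(!nzchar(names(exprs)))) {
    stop("exprs must be a named list", call. = FALSE)
  }
  if (any(curie_prefix(ont$classes$id) == QUERY_PREFIX)) {
    stop("input ontology uses the reserved query-class prefix '", QUERY_PREFIX, ":'",
      call. = FALSE
    )
  }
  exprs <- lapply(exprs, as_expr)
  for (nm in names(exprs)) check_signature(ont, exprs[[nm]])

  qids <- paste0(QUERY_PREFIX, ":", seq_along(exprs))
  ext <- ont_extend(
    ont,
    classes = qids,
    axioms = purrr::map2(qids, exprs, function(q, e) ax_equiv(ce_named(q), e))
  )
  sat <- saturate(normalize(ext))

  keep <- ont$classes$id[ont$classes$namespace %in% result_prefixes]
  obsolete_ids <- ont$classes$id[ont$classes$obsolete]

  out <- purrr::map2(qids, exprs, function(q, e) {
    q_sup <- sat$subsumptions[[q]]
    below <- names(sat$subsumptions)[vapply(
      sat$subsumptions,
      function(s) q %in% s, logical(1)
    )]
    hits <- intersect(below, keep)
    equiv <- intersect(hits, q_sup)
    desc <- setdiff(hits, equiv)
    obs <- intersect(c(equiv, desc), obsolete_ids)
    equiv <- setdiff(equiv, obsolete_ids)
    desc <- setdiff(desc, obsolete_ids)
    structure(
      list(
        query_expr = e,
        equivalents = id_label_tbl(ont, sort(equiv)),
        descendants = id_label_tbl(ont, sort(desc)),
        obsolete = id_label_tbl(ont, sort(obs))
      ),
      class = "el_query_result"
    )
  })
  stats::setNames(out, names(exprs))
}

check_signature <- function(ont, expr) {
  miss_c <- setdiff(expr_class_ids(expr), ont$classes$id)
  if (length(miss_c)) {
    stop("query references undeclared classes: ", paste(miss_c, collapse = ", "),
      call. = FALSE
    )
  }
  miss_p <- setdiff(expr_prop_ids(expr), ont$properties$id)
  if (length(miss_p)) {
    stop("query references undeclared properties: ", paste(miss_p, collapse = ", "),
      call. = FALSE
    )
  }
  invisible()
}

id_label_tbl <- function(ont, ids) {
  tibble::tibble(id = ids, label = class_labels(ont, ids))
}

#' All classes returned by a query (equivalents plus descendants)
#' @param x an `el_query_result`.
#' @return character vector of class ids, sorted.
#' @export
query_hits <- function(x) {
  stopifnot(inherits(x, "el_query_result"))
  sort(c(x$equivalents$id, x$descendants$id))
}

#' @export
print.el_query_result <- function(x, ...) {
  cat(
    "<el_query_result> ", expr_key(x$query_expr), "\n  ",
    nrow(x$equivalents), " equivalent, ",
    nrow(x$descendants), " descendant, ",
    nrow(x$obsolete), " obsolete\n",
    sep = ""
  )
  invisible(x)
}
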