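# The TSV-driven mapping workflow: a mapping table assigns each vocabulary
# term one query (grouping property + single filler class); queries run in
# one batch over a shared classification; automated results are compared
# with manual mappings; blacklists remove rejected pairs; and the surviving
# pairs form the combined mapping table that downstream gene-set
# construction consumes.

#' Parse a mapping table
#'
#' @param tsv path to a TSV with header `term<TAB>property<TAB>filler`, or a
#'   character vector of lines, or a tibble with those columns.
#' @param ont optional [el_ontology()] used to resolve filler ids and labels.
#' @param groupings named list of [grouping_spec()]s used to fill the
#'   `description` column where the property is a known grouping property.
#' @return tibble with columns term, property, filler, description.
#' @export
parse_mapping_table <- function(tsv, ont = NULL,
                                groupings = standard_grouping_specs()) {
  tbl <- read_tsv_flex(tsv, c("term", "property", "filler"))
  if (anyDuplicated(tbl$term)) {
    dup <- unique(tbl$term[duplicated(tbl$term)])
    first_line <- which(tbl$term %in% dup)[1L] + 1L # +1 for the header
    stop("duplicate term(s) ", paste(dup, collapse = ", "),
      " in mapping table (first at line ", first_line, ")",
      call. = FALSE
    )
  }
  tbl$filler <- curie(tbl$filler)
  if (!is.null(ont)) {
    unresolved <- setdiff(tbl$filler, ont$classes$id)
    if (length(unresolved)) {
      stop("unresolvable filler id(s): ", paste(unresolved, collapse = ", "),
        call. = FALSE
      )
    }
  }
  tbl$description <- purrr::pmap_chr(
    tbl[, c("property", "filler")],
    function(property, filler) {
      spec <- groupings[[property]]
      if (is.null(spec)) return(NA_character_)
      label <- if (!is.null(ont)) class_labels(ont, filler) else NA_character_
      if (is.na(label)) label <- filler
      describe_query(spec, filler, label = label)
    }
  )
  tbl
}

read_tsv_flex <- function(x, cols) {
  if (is.data.frame(x)) {
    tbl <- tibble::as_tibble(x)
  } else {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
      x <- readLines(x, warn = FALSE)
    } else if (length(x) == 1L) {
      x <- strsplit(x, "\n", fixed = TRUE)[[1L]]
    }
    x <- x[nzchar(x)]
    if (!length(x)) stop("empty input: no header line", call. = FALSE)
    parts <- strsplit(x, "\t", fixed = TRUE)
    widths <- lengths(parts)
    if (any(widths != length(cols))) {
      bad <- which(widths != length(cols))[1L]
      stop("expected ", length(cols), " tab-separated columns but line ", bad,
        " has ", widths[bad],
        call. = FALSE
      )
    }
    header <- parts[[1L]]
    if (!identical(tolower(header), cols)) {
      stop("expected header '", paste(cols, collapse = "\t"), "'", call. = FALSE)
    }
    body <- parts[-1L]
    tbl <- tibble::as_tibble(
      stats::setNames(
        lapply(seq_along(cols), function(i) vapply(body, `[[`, character(1), i)),
        cols
      )
    )
  }
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    stop("mapping table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tbl[, cols]
}

#' Run all mapping queries of a mapping table
#'
#' One `grouping_property some filler` query per record, batched over a
#' single shared saturation. Each term's result is filtered to the GO
#' prefix (configurable).
#'
#' @param ont an [el_ontology()] that already includes the grouping axioms.
#' @param records tibble from [parse_mapping_table()].
#' @param result_prefixes CURIE prefixes retained in results.
#' @return named list (by term) of `el_query_result` objects.
#' @export
run_mappings <- function(ont, records, result_prefixes = "GO") {
  stopifnot(nrow(records) >= 1L)
  exprs <- stats::setNames(
    purrr::pmap(
      records[, c("property", "filler")],
      function(property, filler) ce_some(property, filler)
    ),
    records$term
  )
  el_query_batch(ont, exprs, result_prefixes)
}

#' Union of query results
#'
#' Supports terms mapped by more than one EL query (e.g. metabolism as
#' participation-union-transport): the union of equivalents and descendants
#' across results.
#'
#' @param results list of `el_query_result` objects (possibly empty).
#' @return sorted character vector of class ids.
#' @export
union_mappings <- function(results) {
  if (inherits(results, "el_query_result")) results <- list(results)
  ids <- unlist(lapply(results, query_hits), use.names = FALSE)
  sort(unique(as.character(ids)))
}

#' Compare automated and manual mappings for one term
#'
#' Builds the per-term results table: one row per class in the union of the
#' automated and manual sets, with 0/1 indicator columns. Manual ids that
#' are absent from the ontology (or marked obsolete there) get
#' `is_obsolete = 1` with a warning; `checked` starts at 0 and is the
#' curator's field.
#'
#' @param auto automated result: an `el_query_result` or character vector of
#'   class ids.
#' @param manual character vector of manually mapped GO ids.
#' @param blacklist character vector of blacklisted GO ids for this term.
#' @param ont the [el_ontology()] (for labels and obsolescence).
#' @param term term name recorded in the output.
#' @return a `mapping_result`: tibble with columns term, go_id, go_name,
#'   manual, auto, checked, blacklisted, is_obsolete, sorted by go_id.
#' @export
compare_mappings <- function(auto, manual = character(),
                             blacklist = character(), ont, term = "term") {
  if (inherits(auto, "el_query_result")) auto <- query_hits(auto)
  manual <- curie(manual)
  bad <- manual[!grepl("^[^:]+:.+$", manual)]
  if (length(bad)) {
    stop("syntactically invalid manual ids: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  ids <- sort(unique(c(auto, manual)))
  known <- ids %in% ont$classes$id
  obsolete <- ifelse(
    known,
    ont$classes$obsolete[match(ids, ont$classes$id)],
    TRUE
  )
  if (any(!known & ids %in% manual)) {
    warning(
      "manual id(s) not in the ontology, flagged obsolete: ",
      paste(ids[!known & ids %in% manual], collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    term = term,
    go_id = ids,
    go_name = class_labels(ont, ids),
    manual = as.integer(ids %in% manual),
    auto = as.integer(ids %in% auto),
    checked = 0L,
    blacklisted = as.integer(ids %in% curie(blacklist)),
    is_obsolete = as.integer(obsolete)
  )
  class(out) <- c("mapping_result", class(out))
  out
}

#' Combine reviewed mapping results into the final mapping table
#'
#' Keeps all automated, non-blacklisted, non-obsolete (term, GO id) pairs;
#' manual-only pairs are retained (provenance `"manual-retained"`) only when
#' `keep_manual_only` is set, and obsolete ids are always excluded.
#'
#' @param results a `mapping_result` or list of them (one per term).
#' @param keep_manual_only retain manual-only non-obsolete pairs?
#' @return tibble with columns term, go_id, provenance
#'   (`"auto"` / `"manual-retained"`), ordered by (term, go_id); never
#'   contains a blacklisted pair.
#' @export
emit_combined_mapping <- function(results, keep_manual_only = FALSE) {
  if (inherits(results, "mapping_result")) results <- list(results)
  rows <- dplyr::bind_rows(results)
  if (!nrow(rows)) {
    return(tibble::tibble(
      term = character(), go_id = character(), provenance = character()
    ))
  }
  auto_pairs <- rows |>
    dplyr::filter(.data$auto == 1L, .data$blacklisted == 0L, .data$is_obsolete == 0L) |>
    dplyr::transmute(.data$term, .data$go_id, provenance = "auto")
  manual_pairs <- if (keep_manual_only) {
    rows |>
      dplyr::filter(
        .data$manual == 1L, .data$auto == 0L,
        .data$blacklisted == 0L, .data$is_obsolete == 0L
      ) |>
      dplyr::transmute(.data$term, .data$go_id, provenance = "manual-retained")
  } else {
    NULL
  }
  out <- dplyr::bind_rows(auto_pairs, manual_pairs) |>
    dplyr::arrange(.data$term, .data$go_id)
  black <- rows[rows$blacklisted == 1L, c("term", "go_id")]
  stopifnot(nrow(dplyr::inner_join(out, black, by = c("term", "go_id"))) == 0L)
  out
}

#' Run the complete mapping pipeline
#'
#' Parses the mapping table, runs all queries in one batch, compares each
#' term against its manual mapping, applies the blacklist, and (optionally)
#' writes the per-term results TSVs, the combined mapping, a summary table
#' and the list of unmapped terms.
#'
#' @param ont an [el_ontology()] including grouping axioms.
#' @param mapping mapping table (path, lines or tibble; see
#'   [parse_mapping_table()]).
#' @param manual optional manual-mapping table with columns term, go_id.
#' @param blacklist optional blacklist table with columns term, go_id.
#' @param outdir optional output directory.
#' @param keep_manual_only passed to [emit_combined_mapping()].
#' @param result_prefixes CURIE prefixes retained in results.
#' @param groupings grouping specs for descriptions.
#' @return list with `records`, `results` (list of `mapping_result`),
#'   `combined`, `summary` (tibble: term, n_auto, n_manual, n_auto_only,
#'   n_manual_only), `unmapped` (tibble: term).
#' @export
run_mapping_pipeline <- function(ont, mapping, manual = NULL, blacklist = NULL,
                                 outdir = NULL, keep_manual_only = FALSE,
                                 result_prefixes = "GO",
                                 groupings = standard_grouping_specs()) {
  records <- parse_mapping_table(mapping, ont = ont, groupings = groupings)
  manual <- if (is.null(manual)) {
    tibble::tibble(term = character(), go_id = character())
  } else {
    read_tsv_flex(manual, c("term", "go_id"))
  }
  blacklist <- if (is.null(blacklist)) {
    tibble::tibble(term = character(), go_id = character())
  } else {
    read_tsv_flex(blacklist, c("term", "go_id"))
  }

  queries <- run_mappings(ont, records, result_prefixes)
  results <- lapply(records$term, function(tm) {
    compare_mappings(
      auto = queries[[tm]],
      manual = manual$go_id[manual$term == tm],
      blacklist = blacklist$go_id[blacklist$term == tm],
      ont = ont,
      term = tm
    )
  })
  names(results) <- records$term

  combined <- emit_combined_mapping(results, keep_manual_only = keep_manual_only)
  summary <- dplyr::bind_rows(results) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_auto = sum(.data$auto),
      n_manual = sum(.data$manual),
      n_auto_only = sum(.data$auto == 1L & .data$manual == 0L),
      n_manual_only = sum(.data$manual == 1L & .data$auto == 0L),
      .groups = "drop"
    )
  unmapped <- tibble::tibble(
    term = records$term[vapply(
      records$term,
      function(tm) length(query_hits(queries[[tm]])) == 0L, logical(1)
    )]
  )

  out <- list(
    records = records, results = results, combined = combined,
    summary = summary, unmapped = unmapped
  )
  if (!is.null(outdir)) write_mapping_outputs(out, outdir)
  out
}

#' Write mapping-pipeline outputs
#'
#' Per-term results TSVs use the layout `GO name, GO ID, manual, auto,
#' checked, black listed, is obsolete`; the combined mapping, summary and
#' unmapped tables are written alongside.
#'
#' @param pipeline result of [run_mapping_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_mapping_outputs <- function(pipeline, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (tm in names(pipeline$results)) {
    res <- pipeline$results[[tm]]
    tbl <- tibble::tibble(
      `GO name` = res$go_name, `GO ID` = res$go_id,
      manual = res$manual, auto = res$auto, checked = res$checked,
      `black listed` = res$blacklisted, `is obsolete` = res$is_obsolete
    )
    p <- file.path(outdir, paste0(gsub("[^A-Za-z0-9_-]", "_", tm), ".tsv"))
    utils::write.table(tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in c("combined", "summary", "unmapped")) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(pipeline[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
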