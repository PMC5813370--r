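#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment matrix
#'
#' Returns the long-form cell table as a plain tibble (one row per gene set
#' and condition, with p-value, `-log10 p` score and signed Z-score).
#'
#' @param x an `owl_enrichment` object from [enrichment_matrix()].
#' @param ... unused.
#' @return a tibble: set, condition, n_set, n_bg, p, score, z.
#' @export
tidy.owl_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "owl_enrichment")
  tibble::as_tibble(out)
}

#' One-row summary of an enrichment matrix
#'
#' @param x an `owl_enrichment` object.
#' @param ... unused.
#' @return a tibble: n_sets, n_conditions, n_universe, n_missing,
#'   min_p, max_abs_z.
#' @export
glance.owl_enrichment <- function(x, ...) {
  tibble::tibble(
    n_sets = dplyr::n_distinct(x$set),
    n_conditions = dplyr::n_distinct(x$condition),
    n_universe = attr(x, "universe_size"),
    n_missing = sum(is.na(x$z)),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    max_abs_z = suppressWarnings(max(abs(x$z), na.rm = TRUE))
  )
}

#' Heat map of an enrichment matrix
#'
#' Z-score heat map with rows (gene sets) and columns (conditions) in
#' euclidean-distance cluster order; over-representation in red,
#' under-representation in blue.
#'
#' @param object an `owl_enrichment` object.
#' @param linkage clustering linkage passed to [cluster_order()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.owl_enrichment <- function(object, linkage = "average", ...) {
  ord <- suppressWarnings(cluster_order(object, linkage = linkage))
  df <- tidy(object)
  df$set <- factor(df$set, levels = ord$rows)
  df$condition <- factor(df$condition, levels = ord$cols)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$set, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 0,
      na.value = "grey85"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a mapping-pipeline summary
#'
#' Bar chart of automated-only and manual-only mapping counts per term, the
#' per-corpus view of how far automation recapitulates a manual mapping.
#'
#' @param summary tibble from [run_mapping_pipeline()]`$summary`.
#' @return a ggplot object.
#' @export
plot_mapping_summary <- function(summary) {
  df <- tidyr::pivot_longer(
    summary[, c("term", "n_auto_only", "n_manual_only")],
    cols = c("n_auto_only", "n_manual_only"),
    names_to = "kind", values_to = "n"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$n, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(n_auto_only = "#2166ac", n_manual_only = "#b2182b"),
      labels = c(n_auto_only = "automated only", n_manual_only = "manual only")
    ) +
    ggplot2::labs(x = NULL, y = "mappings", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
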