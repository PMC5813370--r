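# Rank-based over-representation analysis: direct-annotation gene sets,
# Gini-index tissue signatures, Wilcoxon rank-sum enrichment scores
# (-log10 p) with signed Z-scores, Jaccard overlap, and clustered Z-score
# matrices for heat maps.
#
# Gene sets are represented long-form as tibbles (set, gene); expression
# matrices as tibbles with a `gene` column plus one column per sample, with
# an optional sample -> condition map.

#' Parse gene annotations (GAF 2.x or two-column TSV)
#'
#' Direct annotations only: no propagation over the ontology graph. GAF
#' records with a NOT qualifier are dropped; malformed lines are skipped
#' with a message; duplicates collapse.
#'
#' @param file path (or character vector of lines). A file whose first
#'   non-comment line has 15 or more tab-separated fields, or that starts
#'   with a `!gaf-version` header, is treated as GAF; otherwise as a TSV
#'   with columns `gene<TAB>go_id` (header optional).
#' @return tibble with columns gene, go_id (unique rows).
#' @export
parse_annotations <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) == 1L) {
    strsplit(file, "\n", fixed = TRUE)[[1L]]
  } else {
    file
  }
  is_gaf_header <- grepl("^!", lines)
  body <- lines[!is_gaf_header & nzchar(lines)]
  if (!length(body)) stop("no usable annotation lines", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  gaf <- any(is_gaf_header & grepl("^!gaf-version", lines)) ||
    length(parts[[1L]]) >= 15L

  if (gaf) {
    ok <- lengths(parts) >= 15L
    if (any(!ok)) message(sum(!ok), " malformed GAF line(s) skipped")
    parts <- parts[ok]
    qualifier <- vapply(parts, `[[`, character(1), 4L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
    ann <- tibble::tibble(
      gene = vapply(parts, `[[`, character(1), 3L)[keep],
      go_id = curie(vapply(parts, `[[`, character(1), 5L)[keep])
    )
  } else {
    ok <- lengths(parts) == 2L
    if (any(!ok)) message(sum(!ok), " malformed annotation line(s) skipped")
    parts <- parts[ok]
    ann <- tibble::tibble(
      gene = vapply(parts, `[[`, character(1), 1L),
      go_id = curie(vapply(parts, `[[`, character(1), 2L))
    )
    ann <- ann[!(tolower(ann$gene) == "gene"), , drop = FALSE] # optional header
  }
  ann <- dplyr::distinct(ann)
  if (!nrow(ann)) stop("no usable annotation lines", call. = FALSE)
  ann
}

#' Build controlled-vocabulary gene sets from a combined mapping
#'
#' For each term, the genes directly annotated to any of its mapped GO ids.
#' No propagation is applied: the mapped id set already contains the
#' descendant classes by construction of the DL query. Terms with no
#' annotated genes are dropped with a warning.
#'
#' @param annotations tibble (gene, go_id) from [parse_annotations()].
#' @param combined tibble with columns term, go_id (e.g. from
#'   [emit_combined_mapping()]).
#' @param suffix appended to the term to form the set name.
#' @return tibble (set, gene).
#' @export
build_gene_sets <- function(annotations, combined, suffix = " cv") {
  stopifnot(nrow(combined) >= 1L)
  sets <- combined |>
    dplyr::inner_join(annotations, by = "go_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$term, .data$gene) |>
    dplyr::transmute(set = paste0(.data$term, suffix), .data$gene) |>
    dplyr::arrange(.data$set, .data$gene)
  empty <- setdiff(paste0(unique(combined$term), suffix), unique(sets$set))
  if (length(empty)) {
    warning("term(s) with no annotated genes dropped: ",
      paste(sub(paste0(suffix, "$"), "", empty), collapse = ", "),
      call. = FALSE
    )
  }
  sets
}

#' Gini coefficient of a non-negative vector
#'
#' Population form over ordered pairs,
#' `G = sum_ij |v_i - v_j| / (2 n^2 mean(v))`, bounded by `(n-1)/n` and
#' attained by a one-hot vector. Used to flag tissue-restricted expression.
#'
#' @param v numeric vector, length >= 2, non-negative, not all zero.
#' @return Gini coefficient in `[0, (n-1)/n]`.
#' @examples
#' gini_coefficient(c(1, 0, 0, 0, 0)) # 0.8
#' @export
gini_coefficient <- function(v) {
  if (length(v) < 2L) stop("gini_coefficient() needs at least two values", call. = FALSE)
  if (any(is.na(v)) || any(v < 0)) {
    stop("gini_coefficient() needs non-negative, non-missing values", call. = FALSE)
  }
  if (all(v == 0)) {
    stop("gini_coefficient() is undefined for an all-zero vector", call. = FALSE)
  }
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / (2 * n^2 * mean(v))
}

#' Select tissue-enriched genes by Gini index
#'
#' Per gene, the Gini coefficient over per-condition mean expression; genes
#' strictly above the threshold are assigned to their maximum-expression
#' condition (ties broken by first condition in column order, with a
#' warning). All-zero genes are skipped.
#'
#' @param expression tibble: `gene` column plus one column per sample.
#' @param sample_map optional tibble (sample, condition); defaults to one
#'   condition per sample column.
#' @param threshold strict Gini threshold (default 0.7).
#' @return tibble (condition, gene, gini).
#' @export
select_tissue_enriched <- function(expression, sample_map = NULL, threshold = 0.7) {
  means <- condition_means(expression, sample_map)
  m <- means$matrix
  if (ncol(m) < 2L) stop("Gini selection needs at least two conditions", call. = FALSE)
  nonzero <- rowSums(m) > 0
  m <- m[nonzero, , drop = FALSE]
  g <- apply(m, 1L, gini_coefficient)
  sel <- g > threshold
  if (!any(sel)) {
    return(tibble::tibble(condition = character(), gene = character(), gini = double()))
  }
  msel <- m[sel, , drop = FALSE]
  which_top <- lapply(
    seq_len(nrow(msel)),
    function(i) which(msel[i, ] == max(msel[i, ]))
  )
  n_top <- lengths(which_top)
  if (any(n_top > 1L)) {
    warning(sum(n_top > 1L), " gene(s) tied on maximum condition; first condition kept",
      call. = FALSE
    )
  }
  tibble::tibble(
    condition = colnames(m)[vapply(which_top, `[[`, integer(1), 1L)],
    gene = rownames(msel),
    gini = unname(g[sel])
  ) |>
    dplyr::arrange(.data$condition, .data$gene)
}

# per-condition mean expression matrix (genes x conditions)
condition_means <- function(expression, sample_map = NULL) {
  stopifnot("gene" %in% names(expression))
  if (anyDuplicated(expression$gene)) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  samples <- setdiff(names(expression), "gene")
  vals <- as.matrix(expression[, samples])
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("expression values must be non-negative and non-missing", call. = FALSE)
  }
  rownames(vals) <- expression$gene
  if (is.null(sample_map)) {
    sample_map <- tibble::tibble(sample = samples, condition = samples)
  }
  miss <- setdiff(samples, sample_map$sample)
  if (length(miss)) {
    stop("sample(s) missing from sample map: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  conds <- unique(sample_map$condition[match(samples, sample_map$sample)])
  m <- vapply(
    conds,
    function(cond) {
      cols <- samples[sample_map$condition[match(samples, sample_map$sample)] == cond]
      rowMeans(vals[, cols, drop = FALSE])
    },
    numeric(nrow(vals))
  )
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(expression$gene, conds))
  list(matrix = m, conditions = conds)
}

#' Merge per-dataset tissue signatures
#'
#' Non-redundant union of tissue-enriched gene lists across datasets, named
#' `<condition><suffix>`.
#'
#' @param per_dataset list of tibbles (condition, gene) as returned by
#'   [select_tissue_enriched()] (condition names harmonized by the caller).
#' @param suffix set-name suffix (default `" ts"`).
#' @return tibble (set, gene).
#' @export
merge_signatures <- function(per_dataset, suffix = " ts") {
  if (is.data.frame(per_dataset)) per_dataset <- list(per_dataset)
  dplyr::bind_rows(per_dataset) |>
    dplyr::distinct(.data$condition, .data$gene) |>
    dplyr::transmute(set = paste0(.data$condition, suffix), .data$gene) |>
    dplyr::arrange(.data$set, .data$gene)
}

#' Build the per-condition gene vector
#'
#' Mean expression across the condition's samples, with mid-ranks; rank 1 is
#' the highest expression.
#'
#' @param expression tibble: `gene` column plus sample columns.
#' @param condition condition name.
#' @param sample_map optional tibble (sample, condition).
#' @return tibble (gene, mean_expr, rank), ordered by rank.
#' @export
build_gene_vector <- function(expression, condition, sample_map = NULL) {
  means <- condition_means(expression, sample_map)
  if (!condition %in% colnames(means$matrix)) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  mu <- means$matrix[, condition]
  tibble::tibble(
    gene = rownames(means$matrix),
    mean_expr = unname(mu),
    rank = unname(rank(-mu, ties.method = "average"))
  ) |>
    dplyr::arrange(.data$rank, .data$gene)
}

#' Wilcoxon rank-sum enrichment of a gene set in a gene vector
#'
#' Two-sided rank-sum test of in-set genes against the rest of the universe
#' within one expression-ranked vector; exact when the smaller group has at
#' most 8 genes and there are no ties, otherwise a normal approximation
#' with tie-corrected variance and continuity correction. The enrichment
#' score is `-log10(p)`; the Z-score is the signed rank-sum deviate,
#' positive when the set sits at higher expression.
#'
#' @param genes character vector: the gene set.
#' @param vec gene vector from [build_gene_vector()] (or any tibble with
#'   columns gene, mean_expr).
#' @param universe character vector of universe genes.
#' @return one-row tibble: n_set, n_bg, p, score, z.
#' @export
enrichment_score <- function(genes, vec, universe) {
  pool <- intersect(universe, vec$gene)
  in_set <- intersect(genes, pool)
  out_set <- setdiff(pool, genes)
  if (length(in_set) < 1L || length(out_set) < 1L) {
    stop("enrichment needs at least one in-set and one background gene in the universe",
      call. = FALSE
    )
  }
  x <- vec$mean_expr[match(in_set, vec$gene)]
  y <- vec$mean_expr[match(out_set, vec$gene)]
  wtest <- rank_sum_test(x, y)
  tibble::tibble(
    n_set = length(in_set), n_bg = length(out_set),
    p = wtest$p, score = -log10(wtest$p), z = wtest$z
  )
}

# Two-sided rank-sum p (exact via wilcox.test when admissible) and the
# continuity-corrected, tie-corrected normal deviate z.
rank_sum_test <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  ties <- table(r)
  has_ties <- any(ties > 1L)
  r1 <- sum(r[seq_len(n1)])
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(p = 1, z = 0))
  }
  dev <- r1 - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  if (dev == 0) z <- 0
  exact <- !has_ties && min(n1, n2) <= 8L
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  p <- min(max(p, .Machine$double.xmin), 1)
  list(p = p, z = z)
}

#' Enrichment matrix over a gene-set collection and expression conditions
#'
#' One Wilcoxon enrichment cell per (gene set, condition). By default the
#' universe is the union of genes over all sets in the collection
#' (intersected per condition with the measured genes); setting
#' `universe = "measured"` uses all measured genes instead. Sets with no
#' usable cell in a condition are recorded as missing with a warning.
#'
#' @param sets tibble (set, gene).
#' @param expression tibble: `gene` column plus sample columns.
#' @param sample_map optional tibble (sample, condition).
#' @param universe `"collection"` (default) or `"measured"`.
#' @return an `owl_enrichment` tibble: set, condition, n_set, n_bg, p,
#'   score, z (NA rows mark missing cells).
#' @export
enrichment_matrix <- function(sets, expression, sample_map = NULL,
                              universe = c("collection", "measured")) {
  universe <- match.arg(universe)
  stopifnot(nrow(sets) >= 1L)
  means <- condition_means(expression, sample_map)
  conds <- means$conditions
  uni <- if (universe == "collection") unique(sets$gene) else rownames(means$matrix)
  set_names <- unique(sets$set)
  genes_of <- split(sets$gene, sets$set)

  cells <- list()
  n_missing <- 0L
  for (cond in conds) {
    vec <- tibble::tibble(
      gene = rownames(means$matrix),
      mean_expr = means$matrix[, cond]
    )
    pool <- intersect(uni, vec$gene)
    for (nm in set_names) {
      g <- genes_of[[nm]]
      usable <- length(intersect(g, pool)) >= 1L &&
        length(setdiff(pool, g)) >= 1L
      if (!usable) {
        n_missing <- n_missing + 1L
        cells[[length(cells) + 1L]] <- tibble::tibble(
          set = nm, condition = cond, n_set = NA_integer_, n_bg = NA_integer_,
          p = NA_real_, score = NA_real_, z = NA_real_
        )
      } else {
        sc <- enrichment_score(g, vec, pool)
        cells[[length(cells) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(set = nm, condition = cond), sc
        )
      }
    }
  }
  if (n_missing > 0L) {
    warning(n_missing, " enrichment cell(s) missing (set outside the universe)",
      call. = FALSE
    )
  }
  out <- dplyr::bind_rows(cells)
  class(out) <- c("owl_enrichment", class(out))
  attr(out, "universe_size") <- length(uni)
  attr(out, "universe_mode") <- universe
  out
}

#' Jaccard index between two gene sets
#'
#' `|a intersect b| / |a union b|`; 0 means no overlap, 1 full overlap.
#'
#' @param a,b character vectors of genes (at least one nonempty).
#' @return number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("jaccard_index() is undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Cluster leaf orders for an enrichment heat map
#'
#' Agglomerative hierarchical clustering on euclidean distances of the
#' Z-score matrix (average linkage by default), giving deterministic leaf
#' orders for rows (gene sets) and columns (conditions). Missing Z cells
#' are imputed as 0 (neutral under the null) with a warning.
#'
#' @param x an `owl_enrichment` tibble or a numeric matrix of Z-scores.
#' @param axis `"both"`, `"rows"` or `"columns"`.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return list with `rows` and/or `cols`: character vectors in leaf order.
#' @export
cluster_order <- function(x, axis = c("both", "rows", "columns"),
                          linkage = c("average", "single", "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  m <- as_z_matrix(x)
  if (anyNA(m)) {
    warning("missing Z cells imputed as 0 for clustering", call. = FALSE)
    m[is.na(m)] <- 0
  }
  leaf_order <- function(mat) {
    if (nrow(mat) == 1L) return(rownames(mat))
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = linkage)
    rownames(mat)[hc$order]
  }
  out <- list()
  if (axis %in% c("both", "rows")) out$rows <- leaf_order(m)
  if (axis %in% c("both", "columns")) out$cols <- leaf_order(t(m))
  out
}

as_z_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!nrow(x) || !ncol(x)) stop("empty matrix", call. = FALSE)
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("set", "condition", "z") %in% names(x)))
  if (!nrow(x)) stop("empty enrichment table", call. = FALSE)
  wide <- tidyr::pivot_wider(
    x[, c("set", "condition", "z")],
    names_from = "condition", values_from = "z"
  )
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$set
  m
}

#' Write ordered enrichment matrices as TSV
#'
#' The Z-score and score matrices in the given row/column orders, fixed
#' six-decimal format so the files round-trip exactly.
#'
#' @param cells an `owl_enrichment` tibble.
#' @param row_order,col_order permutations of the sets / conditions
#'   (defaults: [cluster_order()]).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_matrix <- function(cells, row_order = NULL, col_order = NULL, dir = ".") {
  if (!nrow(cells)) stop("empty enrichment table", call. = FALSE)
  ord <- cluster_order(cells)
  row_order <- row_order %||% ord$rows
  col_order <- col_order %||% ord$cols
  stopifnot(
    setequal(row_order, unique(cells$set)),
    !anyDuplicated(row_order),
    setequal(col_order, unique(cells$condition)),
    !anyDuplicated(col_order)
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (what in c("z", "score")) {
    wide <- tidyr::pivot_wider(
      cells[, c("set", "condition", what)],
      names_from = "condition", values_from = dplyr::all_of(what)
    )
    m <- as.matrix(wide[, -1L])
    rownames(m) <- wide$set
    m <- m[row_order, col_order, drop = FALSE]
    out <- data.frame(set = rownames(m), apply(m, 2L, function(v) sprintf("%.6f", v)),
      check.names = FALSE
    )
    p <- file.path(dir, paste0(what, "_matrix.tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write gene sets in GMT layout
#'
#' One line per set: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets tibble (set, gene).
#' @param path output file.
#' @param descriptions optional named character vector of set descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  by_set <- split(sets$gene, sets$set)
  lines <- vapply(
    names(by_set),
    function(nm) {
      desc <- if (!is.null(descriptions) && !is.na(descriptions[nm])) {
        descriptions[[nm]]
      } else {
        "na"
      }
      paste(c(nm, desc, sort(unique(by_set[[nm]]))), collapse = "\t")
    },
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT file.
#' @return tibble (set, gene).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  dplyr::bind_rows(lapply(parts, function(p) {
    if (length(p) < 3L) stop("malformed GMT line: ", p[1L], call. = FALSE)
    tibble::tibble(set = p[1L], gene = p[-(1:2)])
  }))
}
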