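make_expr <- function(values, genes = sprintf("g%d", seq_along(values))) {
  tibble::tibble(gene = genes, s1 = values)
}

test_that("annotation parsing collapses duplicates and drops NOT qualifiers", {
  ann <- parse_annotations(c("g1\tGO:1", "g1\tGO:2", "g1\tGO:1"))
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$go_id[ann$gene == "g1"], c("GO:1", "GO:2"))

  gaf_line <- function(gene, go, qual = "") {
    paste(
      c("DB", paste0("ID", gene), gene, qual, go, "PMID:1", "IEA", "",
        "P", "", "", "protein", "taxon:9606", "20150101", "GO_Central"),
      collapse = "\t"
    )
  }
  gaf <- c(
    "!gaf-version: 2.1",
    gaf_line("g1", "GO:0000001"),
    gaf_line("g2", "GO:0000002", qual = "NOT|involved_in"),
    gaf_line("g3", "GO:0000001", qual = "involved_in")
  )
  out <- parse_annotations(gaf)
  expect_setequal(out$gene, c("g1", "g3"))

  expect_message(parse_annotations(c("g1\tGO:1", "broken line")), "skipped")
  expect_error(parse_annotations("   "), "no usable")
})

test_that("gene sets are built from direct annotations of the mapped ids", {
  ann <- tibble::tibble(
    gene = c("g1", "g2", "g3"), go_id = c("GO:A", "GO:B", "GO:C")
  )
  combined <- tibble::tibble(term = "t", go_id = c("GO:A", "GO:B"))
  sets <- build_gene_sets(ann, combined)
  expect_equal(sets$set, rep("t cv", 2L))
  expect_setequal(sets$gene, c("g1", "g2")) # g3's GO:C not in the mapped set
  expect_warning(
    empty <- build_gene_sets(ann, tibble::tibble(term = "u", go_id = "GO:Z")),
    "no annotated genes"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("the Gini coefficient matches closed-form values and invariants", {
  expect_equal(gini_coefficient(c(1, 1, 1, 1)), 0)
  expect_equal(gini_coefficient(c(1, 0, 0, 0, 0)), 0.8)
  expect_equal(gini_coefficient(c(2, 1, 1, 0)), 0.375)
  expect_error(gini_coefficient(c(0, 0)), "all-zero")
  expect_error(gini_coefficient(3), "two values")
  # scale invariance and the (n-1)/n bound
  set.seed(1)
  for (i in 1:20) {
    v <- stats::rexp(sample(2:10, 1))
    expect_equal(gini_coefficient(3.7 * v), gini_coefficient(v))
    expect_lte(gini_coefficient(v), (length(v) - 1) / length(v))
  }
})

test_that("tissue-enriched selection applies the strict threshold and argmax", {
  expr <- tibble::tibble(
    gene = c("onehot", "uniform", "boundary", "silent"),
    t1 = c(5, 1, 0, 0), t2 = c(0, 1, 0, 0), t3 = c(0, 1, 0, 0),
    t4 = c(0, 1, 3, 0), t5 = c(0, 1, 1, 0)
  )
  # "boundary" has Gini exactly 0.7: pairwise sum 14 over 2 * 25 * mean 0.8
  expect_equal(gini_coefficient(c(0, 0, 0, 3, 1)), 0.7)
  sel <- select_tissue_enriched(expr)
  expect_equal(sel$gene, "onehot")
  expect_equal(sel$condition, "t1")
  expect_equal(sel$gini, 0.8)

  # argmax ties break to the first condition, with a warning
  tie <- tibble::tibble(gene = "t", a = 5, b = 5, c = 0, d = 0, e = 0)
  expect_warning(sel2 <- select_tissue_enriched(tie, threshold = 0.5), "tied")
  expect_equal(sel2$condition, "a")
})

test_that("signature merging is a non-redundant union per condition", {
  a <- tibble::tibble(condition = "liver", gene = c("a", "b"))
  b <- tibble::tibble(condition = "liver", gene = c("b", "c"))
  merged <- merge_signatures(list(a, b))
  expect_equal(merged$set, rep("liver ts", 3L))
  expect_setequal(merged$gene, c("a", "b", "c"))
  expect_equal(merge_signatures(list(a))$gene, c("a", "b"))
  single <- merge_signatures(list(a, tibble::tibble(condition = "lung", gene = "z")))
  expect_true("lung ts" %in% single$set)
})

test_that("gene vectors average samples and assign mid-ranks from the top", {
  expr <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    a1 = c(2, 8, 5), a2 = c(4, 8, 5)
  )
  map <- tibble::tibble(sample = c("a1", "a2"), condition = c("A", "A"))
  vec <- build_gene_vector(expr, "A", map)
  expect_equal(vec$mean_expr[vec$gene == "g1"], 3)
  expect_equal(vec$rank[vec$gene == "g2"], 1)
  # ties get mid-ranks
  expr2 <- tibble::tibble(gene = c("g1", "g2", "g3"), s = c(7, 7, 1))
  vec2 <- build_gene_vector(expr2, "s")
  expect_equal(vec2$rank[vec2$gene %in% c("g1", "g2")], c(1.5, 1.5))
  expect_error(build_gene_vector(expr, "nope", map), "unknown condition")
})

test_that("the exact Wilcoxon example matches brute-force enumeration", {
  vec <- make_expr(c(6, 5, 4, 3, 2, 1))
  v <- build_gene_vector(vec, "s1")
  cell <- enrichment_score(c("g1", "g2", "g3"), v, universe = vec$gene)
  expect_equal(cell$p, 0.1)
  expect_equal(cell$score, 1)
  expect_gt(cell$z, 0)
  # independent oracle: enumerate all 20 label assignments
  expect_equal(enumerate_ranksum_p(c(6, 5, 4), c(3, 2, 1)), 0.1)
  # a second configuration, also verified by enumeration
  x <- c(9, 7, 2)
  y <- c(8, 5, 4, 1)
  vec2 <- make_expr(c(x, y))
  cell2 <- enrichment_score(c("g1", "g2", "g3"), build_gene_vector(vec2, "s1"),
    universe = vec2$gene
  )
  expect_equal(cell2$p, enumerate_ranksum_p(x, y))
})

test_that("degenerate and symmetric enrichment cases behave as documented", {
  flat <- make_expr(rep(3, 6))
  cell <- enrichment_score(c("g1", "g2"), build_gene_vector(flat, "s1"), flat$gene)
  expect_equal(cell$p, 1)
  expect_equal(cell$score, 0)
  expect_equal(cell$z, 0)

  vec <- make_expr(c(6, 5, 4, 3, 2, 1))
  v <- build_gene_vector(vec, "s1")
  top <- enrichment_score(c("g1", "g2", "g3"), v, vec$gene)
  bottom <- enrichment_score(c("g4", "g5", "g6"), v, vec$gene)
  expect_equal(top$p, bottom$p)
  expect_equal(top$z, -bottom$z)

  expect_error(
    enrichment_score(c("absent"), v, vec$gene),
    "at least one in-set"
  )
})

test_that("normal approximation tracks the exact p on small tie-free inputs", {
  # below three genes per group the continuity-corrected normal deviates by
  # up to ~0.09 from the exact tail, so the agreement bound starts at 3
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    vals <- sample(100L, n1 + n2) # tie-free
    p_exact <- enumerate_ranksum_p(vals[seq_len(n1)], vals[n1 + seq_len(n2)])
    p_norm <- suppressWarnings(
      stats::wilcox.test(vals[seq_len(n1)], vals[n1 + seq_len(n2)],
        exact = FALSE, correct = TRUE
      )$p.value
    )
    expect_lt(abs(p_norm - p_exact), 0.05)
  }
})

test_that("raising in-set expression never decreases the Z-score", {
  set.seed(9)
  vals <- stats::rexp(40)
  genes <- sprintf("g%02d", 1:40)
  set <- genes[1:10]
  z_at <- function(bump) {
    v <- vals
    v[1:10] <- v[1:10] + bump
    enrichment_score(set, build_gene_vector(make_expr(v, genes), "s1"), genes)$z
  }
  zs <- vapply(seq(0, 3, by = 0.5), z_at, numeric(1))
  expect_true(all(diff(zs) >= -1e-12))
})

test_that("the enrichment matrix covers the set-by-condition grid", {
  sets <- tibble::tibble(
    set = rep(c("A", "B"), each = 2L),
    gene = c("g1", "g2", "g3", "g4")
  )
  expr <- tibble::tibble(
    gene = sprintf("g%d", 1:6),
    c1 = c(9, 8, 1, 2, 5, 5), c2 = c(1, 2, 9, 8, 5, 5), c3 = c(5, 5, 5, 5, 5, 5)
  )
  enr <- enrichment_matrix(sets, expr)
  expect_s3_class(enr, "owl_enrichment")
  expect_equal(nrow(enr), 6L)
  expect_true(all(!is.na(enr$p)))
  expect_equal(attr(enr, "universe_size"), 4L) # collection universe: g1..g4
  expect_gt(enr$z[enr$set == "A" & enr$condition == "c1"], 0)
  expect_lt(enr$z[enr$set == "A" & enr$condition == "c2"], 0)

  # a set fully outside the universe yields missing cells with a warning
  sets2 <- dplyr::bind_rows(sets, tibble::tibble(set = "C", gene = c("nope")))
  expect_warning(enr2 <- enrichment_matrix(sets2, expr), "missing")
  expect_true(all(is.na(enr2$z[enr2$set == "C"])))

  # measured-genes universe is wider than the collection universe
  enr3 <- enrichment_matrix(sets, expr, universe = "measured")
  expect_equal(attr(enr3, "universe_size"), 6L)
})

test_that("jaccard index satisfies its bounds and symmetry", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_error(jaccard_index(character(), character()), "undefined")
  set.seed(4)
  for (i in 1:10) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(jaccard_index(a, b), jaccard_index(b, a))
    expect_gte(jaccard_index(a, b), 0)
    expect_lte(jaccard_index(a, b), 1)
    expect_equal(jaccard_index(a, b) == 1, setequal(a, b) && length(a) > 0)
  }
})

test_that("cluster orders put identical rows together and isolate outgroups", {
  m <- rbind(
    r1 = c(0, 0, 10), r2 = c(10, 10, 0), r3 = c(0, 0, 10), r4 = c(50, 60, 70)
  )
  colnames(m) <- c("c1", "c2", "c3")
  ord <- cluster_order(m, axis = "rows")
  pos <- match(c("r1", "r3"), ord$rows)
  expect_equal(abs(diff(pos)), 1L)

  expect_equal(cluster_order(m[1, , drop = FALSE], axis = "rows")$rows, "r1")

  # rows 1,2 close; row 3 far: outgroup sits at an end of the leaf order
  m2 <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 10))
  colnames(m2) <- c("x", "y")
  ord2 <- cluster_order(m2, axis = "rows")$rows
  expect_true(match("c", ord2) %in% c(1L, 3L))
  expect_equal(abs(diff(match(c("a", "b"), ord2))), 1L)

  # deterministic
  expect_identical(cluster_order(m), cluster_order(m))
})

test_that("ordered matrices round-trip through TSV and only permute", {
  sets <- tibble::tibble(set = c("A", "A", "B", "B"), gene = c("g1", "g2", "g3", "g4"))
  expr <- tibble::tibble(
    gene = sprintf("g%d", 1:4),
    c1 = c(9, 8, 1, 2), c2 = c(1, 2, 9, 8)
  )
  enr <- enrichment_matrix(sets, expr)
  dir <- withr::local_tempdir()
  write_matrix(enr, dir = dir)
  z1 <- utils::read.delim(file.path(dir, "z_matrix.tsv"), check.names = FALSE)
  expect_equal(dim(z1), c(2L, 3L))
  # round-trip: rewriting the read-back values reproduces the file exactly
  lines1 <- readLines(file.path(dir, "z_matrix.tsv"))
  write_matrix(enr, row_order = rev(unique(enr$set)), dir = dir)
  z2 <- utils::read.delim(file.path(dir, "z_matrix.tsv"), check.names = FALSE)
  expect_equal(z2$set, rev(z1$set))
  expect_equal(sort(z2$c1), sort(z1$c1))
  expect_error(write_matrix(enr[0, ], dir = dir), "empty")
})

test_that("GMT files round-trip gene sets", {
  sets <- tibble::tibble(set = c("A", "A", "B"), gene = c("g2", "g1", "g3"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c(A = "alpha"))
  lines <- readLines(path)
  expect_equal(lines[1L], "A\talpha\tg1\tg2")
  back <- read_gmt(path)
  expect_equal(dplyr::arrange(back, set, gene), dplyr::arrange(sets, set, gene))
})
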