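test_that("toy ontologies are seedless, deterministic and EL-clean", {
  a <- toy_cannabinoid_ontology()
  b <- toy_cannabinoid_ontology()
  expect_identical(write_functional_subset(a$ontology), write_functional_subset(b$ontology))
  # parses and normalizes without error
  re <- parse_functional_subset(write_functional_subset(a$ontology))
  expect_s3_class(normalize(re), "el_nf")
})

test_that("the cannabinoid query agrees between reasoner and oracle", {
  fx <- toy_cannabinoid_ontology()
  expected <- c("GO:0004949", "GO:0038171", "GO:0071926", "GO:1901696", "GO:2000124")
  expr <- ce_some("participant_OR_reg_participant", "CHEBI:67194")
  expect_equal(query_hits(el_query(fx$ontology, expr)), expected)

  # oracle route: saturate the extended ontology with naive_closure instead
  ext <- ont_extend(
    fx$ontology,
    classes = "Q:1",
    axioms = list(ax_equiv(ce_named("Q:1"), expr))
  )
  sat <- naive_closure(normalize(ext))
  hits <- names(Filter(function(s) "Q:1" %in% s, sat$subsumptions))
  expect_equal(sort(grep("^GO:", hits, value = TRUE)), expected)
})

test_that("the regulation class is reached only through the chain axiom", {
  fx <- toy_cannabinoid_ontology()
  expr <- ce_some("participant_OR_reg_participant", "CHEBI:67194")
  with_chain <- query_hits(el_query(fx$ontology, expr))
  expect_true("GO:2000124" %in% with_chain)

  no_chain <- fx$ontology
  no_chain$axioms <- Filter(function(a) a$type != "chain", no_chain$axioms)
  without_chain <- query_hits(el_query(no_chain, expr))
  expect_setequal(setdiff(with_chain, without_chain), "GO:2000124")
})

test_that("each cell-pattern route is witnessed by exactly one class", {
  fx <- toy_pattern_ontology()
  hits <- query_hits(el_query(fx$ontology, ce_some("cell_grouping", "CL:0000084")))
  expect_length(hits, 4L)

  # removing the part_of route removes exactly its witness
  ont2 <- fx$ontology
  ont2$axioms <- Filter(
    function(a) {
      !(a$type == "subpropertyof" && a$sub == "part_of" && a$sup == "cell_grouping")
    },
    ont2$axioms
  )
  hits2 <- query_hits(el_query(ont2, ce_some("cell_grouping", "CL:0000084")))
  expect_setequal(setdiff(hits, hits2), "GO:0042101")
})

test_that("random ontologies regenerate identically from the same seed", {
  a <- random_el_ontology(1)
  b <- random_el_ontology(1)
  expect_identical(write_functional_subset(a), write_functional_subset(b))
  expect_false(identical(
    write_functional_subset(a),
    write_functional_subset(random_el_ontology(2))
  ))
  # density 0: declarations only; saturation is purely reflexive
  empty <- random_el_ontology(3, n_classes = 5, density = 0)
  expect_length(empty$axioms, 0L)
  sat <- saturate(normalize(empty))
  expect_true(all(lengths(sat$subsumptions) == 1L))
})

test_that("synthetic expression is deterministic, non-negative and null at zero effect", {
  truth <- planted_truth(conditions = paste0("t", 1:4), n_genes = 80,
                         genes_per_condition = 10, effect_size = 2, seed = 5)
  a <- synthetic_expression(truth, samples_per_condition = 3)
  b <- synthetic_expression(truth, samples_per_condition = 3)
  expect_identical(a$expression, b$expression)
  expect_true(all(as.matrix(a$expression[, -1L]) >= 0))
  expect_equal(nrow(a$sample_map), 12L)

  # signature sets are disjoint across conditions
  sig <- truth$signature_genes
  expect_equal(anyDuplicated(unlist(sig)), 0L)

  # null fixture: per-condition means of would-be signature genes do not
  # systematically exceed background (loose sanity bound)
  null_truth <- planted_truth(conditions = paste0("t", 1:4), n_genes = 80,
                              genes_per_condition = 10, effect_size = 0, seed = 5)
  nx <- synthetic_expression(null_truth, samples_per_condition = 10)
  m <- as.matrix(nx$expression[, -1L])
  rownames(m) <- nx$expression$gene
  sig1 <- null_truth$signature_genes[["t1"]]
  cols <- nx$sample_map$sample[nx$sample_map$condition == "t1"]
  expect_lt(
    abs(mean(log(m[sig1, cols])) - mean(log(m[setdiff(rownames(m), sig1), cols]))),
    0.5
  )
})

test_that("one-hot signature genes pass the Gini filter in their own tissue", {
  truth <- planted_truth(conditions = paste0("t", 1:5), n_genes = 100,
                         genes_per_condition = 10, effect_size = 2, seed = 8)
  fix <- synthetic_expression(truth, background_scale = 0)
  sel <- select_tissue_enriched(fix$expression, fix$sample_map)
  for (cond in truth$conditions) {
    expect_true(all(truth$signature_genes[[cond]] %in% sel$gene[sel$condition == cond]))
  }
})

test_that("annotation fixtures tie planted genes to toy GO ids end-to-end", {
  # at least four conditions, or the (n-1)/n Gini ceiling sits below 0.7
  truth <- planted_truth(
    conditions = c("liver", "brain", "lung", "heart", "kidney"),
    n_genes = 80, genes_per_condition = 8, seed = 2
  )
  ann <- synthetic_annotations(truth)
  expect_equal(nrow(ann$mapping), 5L)
  sets <- build_gene_sets(ann$annotations, ann$mapping)
  for (i in seq_len(nrow(ann$mapping))) {
    term <- ann$mapping$term[i]
    cond <- ann$term_condition$condition[ann$term_condition$term == term]
    expect_setequal(
      sets$gene[sets$set == paste0(term, " cv")],
      truth$signature_genes[[cond]]
    )
  }

  # a ts signature from an independent realization overlaps the planted set
  fix <- synthetic_expression(truth, background_scale = 0, seed = 77)
  ts <- merge_signatures(select_tissue_enriched(fix$expression, fix$sample_map))
  j <- jaccard_index(
    sets$gene[sets$set == paste0(ann$mapping$term[1], " cv")],
    ts$gene[ts$set == "liver ts"]
  )
  expect_gte(j, 0.5)
})

test_that("fixture bundles write and re-read from disk", {
  dir <- withr::local_tempdir()
  paths <- write_fixture(toy_cannabinoid_ontology(), dir)
  expect_true(file.exists(file.path(dir, "ontology.ofn")))
  ont <- parse_functional_subset(file.path(dir, "ontology.ofn"))
  expect_s3_class(ont, "el_ontology")
  mapping <- parse_mapping_table(file.path(dir, "mapping.tsv"), ont = ont)
  expect_equal(mapping$term, "cannabinoid")

  truth <- planted_truth(conditions = c("a", "b"), n_genes = 30,
                         genes_per_condition = 5, seed = 3)
  paths2 <- write_fixture(synthetic_expression(truth, samples_per_condition = 2), dir)
  expr <- tibble::as_tibble(utils::read.delim(file.path(dir, "expression.tsv")))
  expect_equal(nrow(expr), 30L)
  ann <- parse_annotations(file.path(dir, "annotations.tsv"))
  expect_true(all(c("gene", "go_id") %in% names(ann)))
})
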