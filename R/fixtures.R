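# Deterministic synthetic fixtures. The toy ontologies reuse real GO/ChEBI
# identifiers for traceability, but carry no claim of fidelity to the real
# ontologies: they are minimal axiom sets exercising each reasoning route.
# Expression fixtures plant known tissue signatures so that recovery can be
# measured against ground truth.

#' Toy cannabinoid ontology (worked mapping example)
#'
#' A minimal ontology in which the query
#' `participant_OR_reg_participant some cannabinoid` returns exactly five GO
#' classes: a signaling pathway and its endocannabinoid subtype (direct and
#' inherited participation), a regulation class reachable only through the
#' `regulates o has_participant` chain, a receptor activity and a
#' biosynthetic process. Ships with a mapping table for the vocabulary term
#' "cannabinoid" and a manual mapping listing two of the five ids, so the
#' automated-vs-manual comparison finds three additional classes.
#'
#' @return list with `ontology` (an [el_ontology()] including the preset
#'   grouping axioms), `mapping` (tibble: term, property, filler),
#'   `manual` (tibble: term, go_id).
#' @export
toy_cannabinoid_ontology <- function() {
  classes <- tibble::tibble(
    id = c(
      "CHEBI:67194", "CHEBI:67197",
      "GO:0038171", "GO:0071926", "GO:2000124", "GO:0004949", "GO:1901696"
    ),
    label = c(
      "cannabinoid", "endocannabinoid",
      "cannabinoid signaling pathway",
      "endocannabinoid signaling pathway",
      "regulation of endocannabinoid signaling pathway",
      "cannabinoid receptor activity",
      "cannabinoid biosynthetic process"
    )
  )
  axioms <- list(
    ax_sub("CHEBI:67197", "CHEBI:67194"),
    ax_sub("GO:0038171", ce_some("has_participant", "CHEBI:67194")),
    ax_sub("GO:0071926", ce_and("GO:0038171", ce_some("has_participant", "CHEBI:67197"))),
    ax_sub("GO:2000124", ce_some("regulates", "GO:0071926")),
    ax_sub("GO:0004949", ce_some("has_participant", "CHEBI:67194")),
    ax_sub("GO:1901696", ce_some("has_participant", "CHEBI:67194"))
  )
  ont <- el_ontology(classes, character(), list(), check = FALSE)
  ont <- add_grouping_axioms(ont)
  ont <- ont_extend(ont, axioms = axioms)
  list(
    ontology = ont,
    mapping = tibble::tibble(
      term = "cannabinoid",
      property = "participant_OR_reg_participant",
      filler = "CHEBI:67194"
    ),
    manual = tibble::tibble(
      term = "cannabinoid",
      go_id = c("GO:2000124", "GO:0038171")
    )
  )
}

#' Toy cell/anatomy pattern ontology
#'
#' Exercises the remaining preset grouping patterns. For the cell pattern
#' (filler `CL:0000084`, "T cell") one GO witness class is reachable through
#' each of the four routes of `cell_grouping`: part-of, participation,
#' occurs-in and results-in-development-of. For the reflexive structure
#' pattern (filler `GO:0045202`, "synapse") the query returns the synapse
#' class itself, its subclass, one part, one organization process and one
#' participating process.
#'
#' @return list with `ontology`, `mapping` (two rows: terms `T_cells` and
#'   `Synapse`), `manual` (empty).
#' @export
toy_pattern_ontology <- function() {
  classes <- tibble::tibble(
    id = c(
      "CL:0000084",
      "GO:0042101", "GO:0042110", "GO:0050863", "GO:0030217",
      "GO:0045202", "GO:0060076", "GO:0045211", "GO:0050808", "GO:0099536"
    ),
    label = c(
      "T cell",
      "T cell receptor complex", "T cell activation",
      "regulation of T cell activation occurring in T cell",
      "T cell differentiation",
      "synapse", "excitatory synapse", "postsynaptic membrane",
      "synapse organization", "synaptic signaling"
    )
  )
  axioms <- list(
    # cell pattern: one witness per route
    ax_sub("GO:0042101", ce_some("part_of", "CL:0000084")),
    ax_sub("GO:0042110", ce_some("has_participant", "CL:0000084")),
    ax_sub("GO:0050863", ce_some("occurs_in", "CL:0000084")),
    ax_sub("GO:0030217", ce_some("results_in_development_of", "CL:0000084")),
    # structure pattern: subclass, part, organization, participation
    ax_sub("GO:0060076", "GO:0045202"),
    ax_sub("GO:0045211", ce_some("part_of", "GO:0045202")),
    ax_sub("GO:0050808", ce_some("results_in_organization_of", "GO:0045202")),
    ax_sub("GO:0099536", ce_some("has_participant", "GO:0045202"))
  )
  ont <- el_ontology(classes, character(), list(), check = FALSE)
  ont <- add_grouping_axioms(ont)
  ont <- ont_extend(ont, axioms = axioms)
  list(
    ontology = ont,
    mapping = tibble::tibble(
      term = c("T_cells", "Synapse"),
      property = c("cell_grouping", "structure_grouping"),
      filler = c("CL:0000084", "GO:0045202")
    ),
    manual = tibble::tibble(term = character(), go_id = character())
  )
}

#' Random EL ontology generator
#'
#' Seeded generator covering every normal-form axiom kind plus property
#' hierarchy, chains, transitivity and reflexivity; used for the
#' worklist-vs-brute-force oracle equivalence property.
#'
#' @param seed integer seed.
#' @param n_classes number of classes (kept small; the oracle is dense).
#' @param n_props number of properties.
#' @param density expected number of axioms per class.
#' @return an [el_ontology()].
#' @export
random_el_ontology <- function(seed, n_classes = 12, n_props = 3, density = 1.5) {
  stopifnot(n_classes >= 2, n_props >= 1, density >= 0)
  cls <- sprintf("T:%03d", seq_len(n_classes))
  prp <- sprintf("r%d", seq_len(n_props))
  withr_seed(seed, {
    props <- tibble::tibble(
      id = prp,
      label = NA_character_,
      transitive = stats::runif(n_props) < 0.3,
      reflexive = stats::runif(n_props) < 0.2
    )
    n_ax <- stats::rpois(1, density * n_classes)
    axioms <- vector("list", n_ax)
    for (i in seq_len(n_ax)) {
      kind <- sample(7L, 1L)
      a <- sample(cls, 3L, replace = TRUE)
      r <- sample(prp, 2L, replace = TRUE)
      axioms[[i]] <- switch(kind,
        ax_sub(a[1L], a[2L]), # NF1
        ax_sub(ce_and(a[1L], a[2L]), a[3L]), # NF2 (GCI)
        ax_sub(a[1L], ce_some(r[1L], a[2L])), # NF3
        ax_sub(ce_some(r[1L], a[1L]), a[2L]), # NF4
        ax_equiv(a[1L], ce_and(a[2L], ce_some(r[1L], a[3L]))), # complex equivalence
        ax_subprop(r[1L], r[2L]),
        ax_chain(r[1L], r[2L], sample(prp, 1L))
      )
    }
    # drop degenerate conjunctions ce_and(A, A) that collapsed to one conjunct
    el_ontology(classes = cls, properties = props, axioms = axioms)
  })
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Planted ground truth for synthetic expression data
#'
#' Assigns disjoint signature gene sets to conditions and fixes the effect
#' size (upward shift of signature genes in their own condition, in units of
#' the log-scale noise standard deviation).
#'
#' @param conditions character vector of condition (tissue) names.
#' @param n_genes total number of genes (`g0001`, `g0002`, ...).
#' @param genes_per_condition signature size per condition.
#' @param effect_size log-scale shift in noise standard deviations.
#' @param seed integer seed controlling the signature assignment.
#' @return object of class `planted_truth`: `signature_genes` (named list),
#'   `genes`, `conditions`, `effect_size`, `seed`.
#' @export
planted_truth <- function(conditions = paste0("tissue", 1:5), n_genes = 300,
                          genes_per_condition = 20, effect_size = 2, seed = 1) {
  stopifnot(
    effect_size >= 0,
    length(conditions) * genes_per_condition <= n_genes
  )
  genes <- sprintf("g%04d", seq_len(n_genes))
  sig <- withr_seed(seed, {
    picked <- sample(genes, length(conditions) * genes_per_condition)
    split(picked, rep(conditions, each = genes_per_condition))
  })
  structure(
    list(
      signature_genes = sig[conditions], genes = genes,
      conditions = conditions, effect_size = effect_size, seed = seed
    ),
    class = "planted_truth"
  )
}

#' Synthetic expression matrix with planted signatures
#'
#' Baseline expression is log-normal (RPKM-like positivity and skew);
#' signature genes are shifted up by `effect_size` noise standard deviations
#' (on the log scale) in every sample of their own condition. With
#' `effect_size = 0` the fixture is a pure null. `background_scale`
#' multiplies signature genes' expression *outside* their own condition:
#' the default 1 leaves the baseline untouched (enrichment-style signal),
#' while 0 makes signature genes one-hot — expressed only in their own
#' tissue, the regime that Gini-index selection of tissue-restricted genes
#' targets.
#'
#' @param truth a [planted_truth()].
#' @param samples_per_condition samples per condition.
#' @param meanlog,sdlog log-normal baseline parameters.
#' @param background_scale multiplier for signature genes outside their own
#'   condition, in `[0, 1]`.
#' @param seed integer seed for the noise (independent of the signature
#'   assignment seed held in `truth`).
#' @return list with `expression` (tibble: `gene` column plus one column per
#'   sample), `sample_map` (tibble: sample, condition) and `truth`.
#' @export
synthetic_expression <- function(truth, samples_per_condition = 4,
                                 meanlog = 1, sdlog = 1,
                                 background_scale = 1, seed = truth$seed) {
  stopifnot(inherits(truth, "planted_truth"))
  conds <- truth$conditions
  samples <- paste0(
    rep(conds, each = samples_per_condition), "_s",
    rep(seq_len(samples_per_condition), length(conds))
  )
  cond_of <- rep(conds, each = samples_per_condition)
  vals <- withr_seed(seed, {
    m <- matrix(
      stats::rnorm(length(truth$genes) * length(samples), meanlog, sdlog),
      nrow = length(truth$genes),
      dimnames = list(truth$genes, samples)
    )
    m <- exp(m)
    all_sig <- unlist(truth$signature_genes, use.names = FALSE)
    for (cond in conds) {
      sig <- truth$signature_genes[[cond]]
      m[sig, cond_of == cond] <- m[sig, cond_of == cond] *
        exp(truth$effect_size * sdlog)
      other_sig <- setdiff(all_sig, sig)
      m[other_sig, cond_of == cond] <- m[other_sig, cond_of == cond] * background_scale
    }
    m
  })
  list(
    expression = dplyr::bind_cols(
      tibble::tibble(gene = truth$genes),
      tibble::as_tibble(vals)
    ),
    sample_map = tibble::tibble(sample = samples, condition = cond_of),
    truth = truth
  )
}

#' Synthetic annotations tied to planted signatures
#'
#' Gives every condition a toy GO id and annotates its signature genes to
#' it; non-signature genes are annotated to a distractor id. Together with
#' the per-condition mapping table this lets controlled-vocabulary gene
#' sets be built end-to-end and compared against planted truth.
#'
#' @param truth a [planted_truth()].
#' @return list with `annotations` (tibble: gene, go_id), `mapping`
#'   (tibble: term, go_id — one toy GO id per condition) and
#'   `term_condition` (tibble: term, condition).
#' @export
synthetic_annotations <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  conds <- truth$conditions
  go_ids <- sprintf("GO:91%05d", seq_along(conds))
  terms <- paste0(conds, "_term")
  ann <- purrr::map2_dfr(conds, go_ids, function(cond, go) {
    tibble::tibble(gene = truth$signature_genes[[cond]], go_id = go)
  })
  rest <- setdiff(truth$genes, ann$gene)
  ann <- dplyr::bind_rows(
    ann,
    tibble::tibble(gene = rest, go_id = "GO:9199999")
  )
  list(
    annotations = ann[order(ann$gene), ],
    mapping = tibble::tibble(term = terms, go_id = go_ids),
    term_condition = tibble::tibble(term = terms, condition = conds)
  )
}

#' Write a fixture bundle to a directory
#'
#' Serializes a toy ontology fixture (functional-syntax subset plus mapping
#' and manual TSVs) or an expression fixture (expression, sample map,
#' annotation and mapping TSVs) for use from the command line.
#'
#' @param fixture result of [toy_cannabinoid_ontology()],
#'   [toy_pattern_ontology()] or [synthetic_expression()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(fixture$ontology)) {
    p <- file.path(dir, "ontology.ofn")
    write_functional_subset(fixture$ontology, p)
    paths <- c(paths, p)
    w(fixture$mapping, "mapping.tsv")
    w(fixture$manual, "manual.tsv")
  }
  if (!is.null(fixture$expression)) {
    w(fixture$expression, "expression.tsv")
    w(fixture$sample_map, "sample_map.tsv")
    ann <- synthetic_annotations(fixture$truth)
    w(ann$annotations, "annotations.tsv")
    w(ann$mapping, "term_go.tsv")
  }
  invisible(paths)
}
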