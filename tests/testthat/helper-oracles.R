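# Shared helpers: independent oracles and small builders used across tests.

# exact saturation equality
expect_same_saturation <- function(a, b) {
  expect_identical(a$subsumptions, b$subsumptions)
  expect_identical(a$links, b$links)
}

# Brute-force two-sided rank-sum p by enumerating every assignment of group
# labels to the observed values (tie-free case). Independent of wilcox.test.
enumerate_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  r <- rank(vals)
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (length(vals) + 1) / 2)
  picks <- utils::combn(length(vals), n1)
  stats <- apply(picks, 2L, function(idx) {
    abs(sum(r[idx]) - n1 * (length(vals) + 1) / 2)
  })
  mean(stats >= obs - 1e-12)
}

# subsumption pairs of a saturation as a sorted "sub->sup" character vector
sub_pairs <- function(sat, classes = NULL) {
  out <- unlist(
    lapply(names(sat$subsumptions), function(c) {
      paste0(c, "->", sat$subsumptions[[c]])
    }),
    use.names = FALSE
  )
  if (!is.null(classes)) {
    keep <- vapply(
      strsplit(out, "->", fixed = TRUE),
      function(p) all(p %in% classes), logical(1)
    )
    out <- out[keep]
  }
  sort(out)
}

# tiny ontology from axioms, declaring everything mentioned
tiny_ontology <- function(axioms, transitive = character(),
                          reflexive = character(), extra_classes = character()) {
  cls <- unique(c(
    unlist(lapply(axioms, owlsets:::axiom_class_ids), use.names = FALSE),
    extra_classes
  ))
  prp <- unique(c(
    unlist(lapply(axioms, owlsets:::axiom_prop_ids), use.names = FALSE),
    transitive, reflexive
  ))
  el_ontology(
    classes = cls,
    properties = tibble::tibble(
      id = prp,
      transitive = prp %in% transitive,
      reflexive = prp %in% reflexive
    ),
    axioms = axioms
  )
}
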