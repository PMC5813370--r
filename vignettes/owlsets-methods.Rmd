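---
title: "Methods: EL reasoning, grouping properties and rank-based enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EL reasoning, grouping properties and rank-based enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlsets)
```

## The problem

Enrichment analyses need gene sets, and the Gene Ontology's graph structure
only yields one family of them: a term together with its descendants. Many
biologically natural groupings cut across that hierarchy — "everything
related to a T cell", "every process in which a cannabinoid participates or
that regulates such a process" — and are traditionally curated by hand as a
flat controlled vocabulary whose terms each point at a list of GO ids.
`owlsets` replaces that manual list with a *dynamic* mapping: each
vocabulary term is an OWL 2 EL class expression, and the term's GO set is
whatever the reasoner entails today, so the mapping tracks the ontology as
it evolves.

## EL reasoning

### Why the EL profile

Mapping queries are restricted to OWL 2 EL: named classes, conjunction and
existential restriction, plus property hierarchies, (binary) property
chains, transitivity and reflexivity. Classification in this profile is
polynomial, which is what makes reasoning over the full GO with its
CL/Uberon/ChEBI imports routinely fast; the price is the loss of
disjunction and inverse properties. Inverse property axioms, where present
in an input, are not representable here and the parsers reject the
constructs that name them; `DisjointClasses` is parsed but ignored with a
warning, since EL uses disjointness only to detect unsatisfiable classes
and the mapping workflow has no use for that signal.

### Normalization

Every class axiom is decomposed into the four EL normal forms over named
classes (`A ⊑ B`, `A1 ⊓ A2 ⊑ B`, `A ⊑ ∃R.B`, `∃R.A ⊑ B`), introducing
fresh classes under the reserved prefix `X:` for complex subexpressions.
`EquivalentClasses` splits into mutual `SubClassOf`; a transitive role `R`
is compiled to the chain `R ∘ R ⊑ R` so the rule engine needs a single
composed-role rule. Fresh names are assigned by a counter in input order,
so the same ontology always normalizes — and therefore saturates — to the
same result, and every downstream TSV is diffable.

### Saturation, twice

`saturate()` computes the least fixpoint of the standard completion rules
(initialisation `C ⊑ C`; conjunction and existential propagation; role
hierarchy; role composition; reflexivity) with a worklist and indexes
keyed on class and on (property, class). `naive_closure()` recomputes the
same fixpoint by brute force: dense logical matrices and repeated passes
over every rule until nothing changes, with no worklist and no indexing.
The two implementations share nothing but the rule definitions, so exact
equality of their outputs on seeded random ontologies (every axiom kind,
chains, transitivity, reflexivity; up to 25 classes and 4 properties) is a
meaningful correctness check rather than a tautology. The reflexivity rule
is applied eagerly to every declared class; that is the known hot spot if
the reasoner were ever pointed at very large ontologies, and it is a
deliberate trade of speed for a simpler correctness argument.

### Queries

A query adds a fresh class `Q:n` with `EquivalentClasses(Q:n, expr)`,
saturates, and reads off equivalents (`A ⊑ Q` and `Q ⊑ A`) and descendants
(`A ⊑ Q` only). Results are filtered to requested CURIE prefixes (GO by
default) and to non-obsolete classes; obsolete classes that would have
matched are kept in a side table because the mapping workflow's results
tables carry an "is obsolete" column. Obsolete classes still *participate*
in reasoning — filtering happens at result construction, not before — so a
live class reachable through an obsolete one is not lost. A whole mapping
table is answered in one batch over a single shared saturation; a test
confirms batching never cross-contaminates results.

## Grouping properties: disjunction by other means

EL has no `OR`, but a super-property with several subproperties answers a
query through any of its routes, which is an exact union for queries of
the shape `g some F`. A grouping property is therefore data: a name, a set
of subproperties, a set of binary chains (each materialized as a named
intermediate, e.g. `regulates_o_has_participant`, with
`regulates ∘ has_participant ⊑ regulates_o_has_participant ⊑ g`), a
reflexivity flag, and a description template. Reflexivity makes the filler
class itself (and its subclasses) answer the query — the "a synapse OR
part of a synapse" pattern. The shipped presets cover the four documented
patterns (participation-or-regulation, occurs-in-or-participation, the
reflexive structure pattern, the four-route cell pattern); anything else
is one JSON stanza in a config file, not code. `regulates` is given
`positively_regulates` and `negatively_regulates` as subproperties,
mirroring GO's relation hierarchy, so direction-specific regulation
classes are captured by the chain route.

The property hierarchy listing this design follows is directionally
ambiguous in places; the reading implemented here —
`has_participant ⊑ participant_OR_reg_participant` and
`regulates_o_has_participant ⊑ participant_OR_reg_participant` — is the
only one consistent with the worked cannabinoid example, whose query must
return both direct participation classes and the regulation class reached
through the chain.

Description templates contain a `{filler}` placeholder one or more times;
`describe_query()` substitutes the filler's label everywhere it appears.
English articles live in the template, which reproduces the cannabinoid
and synapse descriptions word for word; labels that need a different
determiner ("some substance with neurotransmitter biological role") come
out with the template's article instead — a cosmetic limitation accepted
in exchange for one-slot simplicity.

## The mapping pipeline

The workflow is three TSVs in (term/property/filler mapping, optional
manual term→GO pairs, optional blacklist pairs) and four TSV families out:
per-term indicator tables (`GO name, GO ID, manual, auto, checked, black
listed, is obsolete`), a combined mapping of surviving (term, GO id) pairs
with provenance, a per-term summary of automated-only and manual-only
counts, and the list of unmapped terms. Review happens on files: a
blacklist row removes a pair from the combined table unconditionally
(asserted on every emit), and manual ids unknown to the ontology are
flagged obsolete rather than treated as errors, because vocabulary
curation lags ontology releases. Manual-only pairs enter the combined
table only on request (`keep_manual_only`), with their provenance kept
distinct from automated pairs rather than silently merged.

## Over-representation analysis

### Gene sets

A term's gene set is the union of genes *directly* annotated to its mapped
GO ids. No annotation propagation is applied: the DL query already
returned the term's descendant classes, so propagation would double-count
structure. Annotation-derived sets get the suffix `" cv"`, tissue
signatures `" ts"`. GAF qualifiers containing `NOT` are dropped; evidence
codes are not filtered (no flag in the data argued for a default
exclusion, and the choice is exposed to the caller by pre-filtering the
annotation table).

### Tissue signatures

Per gene and dataset, the Gini coefficient
`G = Σᵢⱼ |vᵢ − vⱼ| / (2 n² v̄)` is computed over per-condition mean
expression; genes with `G > 0.7` (strictly) are assigned to their argmax
condition, ties to the first condition in column order with a warning, and
per-dataset lists merge by union. The threshold is a property of near
tissue-exclusive expression: with `n` conditions the maximum attainable
`G` is `(n − 1)/n`, so 0.7 is reachable only from four conditions up, and
a gene expressed at a uniform baseline everywhere needs an own-tissue
excess of roughly 36-fold (5 conditions) to cross it. This is why the
synthetic generator has a distinct tissue-restricted regime (below) rather
than expecting an additive shift to produce signatures.

### Scoring

For each condition, genes are ranked by mean expression across that
condition's samples (mid-ranks for ties, rank 1 highest). A gene set is
scored against the rest of the universe by a two-sided Wilcoxon rank-sum
test: exact when the smaller group has at most 8 genes and there are no
ties, otherwise the normal approximation with tie-corrected variance and
continuity correction. The enrichment score is `−log₁₀ p`; direction is
carried by the signed, continuity-corrected rank-sum deviate `z`, positive
when the set sits high. Both choices — two-sided test, rank-sum deviate as
the Z-score — are defaults where the method description was silent; the
two-sidedness matches heat maps that colour both over- and
under-representation. The universe defaults to the union of genes over
the gene-set collection ("entire geneset collection as universe"), with
all measured genes available behind a flag. No multiple-testing correction
is applied across the matrix: cells report raw `−log₁₀ p` and `z`.

The exact and approximate p-values agree to better than 0.05 for tie-free
groups of three or more; at group size two the continuity-corrected
normal tail is off by up to ~0.09 from the exact value, which is an
arithmetic fact about the approximation, so the agreement property is
asserted from size three upward.

### Presentation

Missing cells (a set with no gene in a condition's universe) are recorded
as `NA` with a warning and imputed as 0 — the null-neutral value — only
for clustering. Leaf orders come from agglomerative hierarchical
clustering on euclidean distance with average linkage (single and
complete linkage are options); `autoplot()` draws the familiar
red/white/blue Z heat map in clustered order, and `write_matrix()` emits
the ordered Z and score matrices in fixed six-decimal format so files are
byte-stable across runs.

## Synthetic data: what it emulates and what it does not

`planted_truth()` fixes disjoint signature gene sets per condition;
`synthetic_expression()` draws log-normal baseline noise (meanlog 1,
sdlog 1 — positive, right-skewed, RPKM-like) and multiplies signature
genes in their own condition by `exp(effect × sdlog)`. Defaults are 5
conditions, 300 genes, 20 signature genes per condition, 4 samples per
condition and a 2-standard-deviation effect — a small but honestly noisy
enrichment problem. `background_scale = 0` switches signature genes to
the one-hot, tissue-restricted regime that Gini selection targets.
`synthetic_annotations()` closes the loop by annotating signature genes
to one toy GO id per condition, so controlled-vocabulary sets can be
built end-to-end and compared (e.g. by Jaccard index) against signatures
recovered from an independent expression realization.

What passing tests on these fixtures shows: the reasoner's entailments
are exactly the completion-rule fixpoint; grouping queries equal their
route unions; the pipeline's bookkeeping (indicator columns, blacklist,
obsolete handling) is correct; the scorer is calibrated under a true null
and recovers planted signal of realistic effect size in the planted
condition. What it does not show: robustness to correlated genes,
batch structure, compositional normalization artefacts, annotation bias,
or the overlapping gene-set structure of a real GO release — real
expression atlases have all of these and the fixtures deliberately have
none.

## Problem sizes and numerical choices

Randomized properties run at the scale the brute-force oracle is dense
enough to check exactly: 500 seeded ontologies of up to 25 classes and 4
properties for reasoner equivalence, 1000 random size-50 sets on a
2000-gene shuffled vector for null calibration (fraction of p < 0.05
asserted within 0.05 ± 0.02), and 100 seeded replicates for signal
recovery (maximal z in the planted condition, ≥ 95% required, for both
`cv` and `ts` sets). p-values are floored at the smallest positive
double before taking `−log₁₀`; degenerate inputs (all-equal expression)
short-circuit to `p = 1, z = 0`; all-zero genes are excluded from Gini
with an error at the single-vector level and silently skipped at the
matrix level, where exclusion is the documented contract.

## Known limitations

* Only binary property chains are supported (the patterns in scope need
  no more); n-ary chains would require a pre-binarization pass.
* The reasoner tracks no unsatisfiability, nominals, datatypes or
  inverses, and offers no explanations for entailments.
* Description generation is one template slot; grammatical agreement
  beyond the template's fixed articles is out of scope.
* The eager reflexivity rule makes saturation cost scale with
  (classes × reflexive properties); acceptable here, the first thing to
  make lazy on full-GO workloads.
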