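test_that("CURIE normalization handles IRIs, underscores and symbolic names", {
  expect_equal(curie("GO_0038171"), "GO:0038171")
  expect_equal(curie("GO:0038171"), "GO:0038171")
  expect_equal(
    curie("http://purl.obolibrary.org/obo/CHEBI_67194"),
    "CHEBI:67194"
  )
  expect_equal(curie("has_participant"), "has_participant")
  expect_equal(curie_prefix(c("GO:1", "part_of")), c("GO", ""))
  expect_identical(curie_prefix(character()), character())
})

test_that("conjunctions flatten, canonicalize and deduplicate", {
  a <- ce_and("GO:2", ce_and("GO:1", ce_some("r", "GO:3")))
  b <- ce_and(ce_some("r", "GO:3"), "GO:1", "GO:2")
  expect_equal(expr_key(a), expr_key(b))
  expect_length(a$args, 3L)
  # duplicate conjuncts collapse, possibly to a bare named class
  expect_equal(ce_and("GO:1", "GO:1")$kind, "named")
})

test_that("functional-syntax subset parses declarations, axioms and flags", {
  ont <- parse_functional_subset(c(
    "Declaration(Class(:A))",
    "Declaration(Class(:B))",
    "Declaration(Class(GO:0001))",
    "Declaration(ObjectProperty(:r))",
    "Declaration(ObjectProperty(regulates))",
    "Declaration(ObjectProperty(has_participant))",
    "Declaration(ObjectProperty(regulates_o_has_participant))",
    "SubClassOf(:A :B)",
    "SubClassOf(:A ObjectSomeValuesFrom(:r GO:0001))",
    "EquivalentClasses(GO:0001 ObjectIntersectionOf(:B ObjectSomeValuesFrom(:r :A)))",
    "SubObjectPropertyOf(ObjectPropertyChain(regulates has_participant) regulates_o_has_participant)",
    "TransitiveObjectProperty(:r)",
    "ReflexiveObjectProperty(regulates)",
    'AnnotationAssertion(rdfs:label :A "alpha")'
  ))
  expect_setequal(ont$classes$id, c("A", "B", "GO:0001"))
  expect_equal(ont$classes$label[ont$classes$id == "A"], "alpha")
  expect_true(ont$properties$transitive[ont$properties$id == "r"])
  expect_true(ont$properties$reflexive[ont$properties$id == "regulates"])
  types <- vapply(ont$axioms, `[[`, character(1), "type")
  expect_equal(sum(types == "chain"), 1L)
  chain <- ont$axioms[[which(types == "chain")]]
  expect_equal(
    c(chain$first, chain$second, chain$sup),
    c("regulates", "has_participant", "regulates_o_has_participant")
  )
})

test_that("non-EL constructs and broken syntax are rejected with clear errors", {
  expect_error(
    parse_functional_subset(c(
      "Declaration(Class(:A))", "Declaration(Class(:B))", "Declaration(Class(:C))",
      "SubClassOf(:A ObjectUnionOf(:B :C))"
    )),
    "profile violation.*ObjectUnionOf"
  )
  expect_error(
    parse_functional_subset("InverseObjectProperties(:r :s)"),
    "profile violation"
  )
  expect_error(
    parse_functional_subset(c("Declaration(Class(:A))", "SubClassOf(:A :B")),
    "line"
  )
})

test_that("deprecated classes and DisjointClasses are handled as annotations", {
  expect_warning(
    ont <- parse_functional_subset(c(
      "Declaration(Class(GO:1))",
      "Declaration(Class(GO:2))",
      'AnnotationAssertion(owl:deprecated GO:1 "true")',
      "DisjointClasses(GO:1 GO:2)"
    )),
    "DisjointClasses"
  )
  expect_true(ont$classes$obsolete[ont$classes$id == "GO:1"])
  expect_false(ont$classes$obsolete[ont$classes$id == "GO:2"])
  expect_length(ont$axioms, 0L)
})

test_that("functional-syntax serialization round-trips the axiom multiset", {
  for (seed in 1:5) {
    ont <- random_el_ontology(seed, n_classes = 10, n_props = 3, density = 1.5)
    re <- parse_functional_subset(write_functional_subset(ont))
    expect_identical(
      sort(vapply(ont$axioms, owlsets:::axiom_key, character(1))),
      sort(vapply(re$axioms, owlsets:::axiom_key, character(1)))
    )
    expect_setequal(re$classes$id, ont$classes$id)
    expect_equal(
      re$properties[order(re$properties$id), ],
      ont$properties[order(ont$properties$id), ]
    )
  }
})

test_that("obographs documents parse to classes, edges and logical definitions", {
  doc <- list(
    nodes = list(
      list(id = "http://purl.obolibrary.org/obo/GO_0038171", lbl = "csp", type = "CLASS"),
      list(id = "GO_0071926", lbl = "ecsp", type = "CLASS"),
      list(id = "CHEBI_67194", lbl = "cannabinoid", type = "CLASS"),
      list(
        id = "GO_0000001", lbl = "old",
        meta = list(deprecated = TRUE), type = "CLASS"
      ),
      list(id = "http://purl.obolibrary.org/obo/RO_0000057", lbl = "has participant", type = "PROPERTY")
    ),
    edges = list(
      list(sub = "GO_0071926", pred = "is_a", obj = "GO_0038171"),
      list(sub = "GO_0038171", pred = "RO_0000057", obj = "CHEBI_67194")
    ),
    logicalDefinitionAxioms = list(
      list(
        definedClassId = "GO_0071926",
        genusIds = list("GO_0038171"),
        restrictions = list(list(propertyId = "RO_0000057", fillerId = "CHEBI_67194"))
      )
    ),
    propertyChainAxioms = list(
      list(
        predicateId = "RO_0002211",
        chainPredicateIds = list("RO_0002211", "RO_0000057")
      )
    )
  )
  ont <- parse_obograph(doc)
  expect_setequal(
    ont$classes$id,
    c("GO:0038171", "GO:0071926", "CHEBI:67194", "GO:0000001")
  )
  expect_true(ont$classes$obsolete[ont$classes$id == "GO:0000001"])
  keys <- vapply(ont$axioms, owlsets:::axiom_key, character(1))
  expect_true("SubClassOf(GO:0071926 GO:0038171)" %in% keys)
  expect_true("SubClassOf(GO:0038171 Some(RO:0000057 CHEBI:67194))" %in% keys)
  expect_true(
    "EquivalentClasses(And(GO:0038171 Some(RO:0000057 CHEBI:67194)) GO:0071926)" %in% keys
  )
  expect_true(
    "SubObjectPropertyOf(ObjectPropertyChain(RO:0002211 RO:0000057) RO:0002211)" %in% keys
  )
})

test_that("obographs referential and structural errors are reported", {
  expect_error(
    parse_obograph(list(nodes = list(list(lbl = "x")))),
    "node without an id"
  )
  expect_error(
    parse_obograph(list(
      nodes = list(list(id = "GO_1")),
      edges = list(list(sub = "GO_1", pred = "is_a", obj = "GO_2"))
    )),
    "undeclared node GO:2"
  )
})

test_that("merge takes unions, resolves labels first-wins, rejects flag conflicts", {
  o1 <- tiny_ontology(list(ax_sub("A", "B")))
  o2 <- tiny_ontology(list(ax_sub("B", "C")))
  m <- merge_ontologies(list(o1, o2))
  sat <- saturate(normalize(m))
  expect_true("C" %in% sat$subsumptions[["A"]])

  # identity case
  empty <- el_ontology()
  expect_equal(merge_ontologies(list(o1, empty))$axioms, o1$axioms)

  # commutative/associative up to canonical ordering
  o3 <- tiny_ontology(list(ax_sub("C", ce_some("r", "A"))))
  key_of <- function(o) sort(vapply(o$axioms, owlsets:::axiom_key, character(1)))
  expect_equal(
    key_of(merge_ontologies(list(o1, merge_ontologies(list(o2, o3))))),
    key_of(merge_ontologies(list(merge_ontologies(list(o1, o2)), o3)))
  )
  expect_equal(
    key_of(merge_ontologies(list(o3, o1))),
    key_of(merge_ontologies(list(o1, o3)))
  )

  # conflicting reflexive flag is an error
  p1 <- el_ontology(properties = tibble::tibble(id = "g", reflexive = TRUE))
  p2 <- el_ontology(properties = tibble::tibble(id = "g", reflexive = FALSE))
  expect_error(merge_ontologies(list(p1, p2)), "conflicting")

  # conflicting labels warn, first occurrence wins
  l1 <- el_ontology(classes = tibble::tibble(id = "GO:1", label = "first"))
  l2 <- el_ontology(classes = tibble::tibble(id = "GO:1", label = "second"))
  expect_warning(lm <- merge_ontologies(list(l1, l2)), "label")
  expect_equal(lm$classes$label, "first")
})

test_that("normalization produces the four normal forms with fresh names", {
  # already normal
  nx <- normalize(tiny_ontology(list(ax_sub("A", "B"))))
  expect_equal(nrow(nx$nf1), 1L)
  expect_equal(nrow(nx$nf2) + nrow(nx$nf3) + nrow(nx$nf4), 0L)
  expect_length(nx$fresh, 0L)

  # complex equivalence: one fresh name, entailments preserved
  ont <- tiny_ontology(list(
    ax_equiv("A", ce_and("B", ce_some("R", "C")))
  ))
  nx <- normalize(ont)
  expect_length(nx$fresh, 1L)
  expect_true(startsWith(nx$fresh[1L], "X:"))
  sat <- saturate(nx)
  expect_true(all(c("A", "B") %in% sat$subsumptions[["A"]]))
  expect_true(any(
    sat$links$src == "A" & sat$links$property == "R" & sat$links$tgt == "C"
  ))

  # GCI: an NF4 entry for the restriction plus an NF2 entry combining it
  gci <- tiny_ontology(list(
    ax_sub(ce_and("B", ce_some("R", "A")), "C")
  ))
  nxg <- normalize(gci)
  expect_equal(nrow(nxg$nf4), 1L)
  expect_equal(nrow(nxg$nf2), 1L)
  expect_true(nxg$nf4$sup %in% nxg$fresh)
  expect_true(nxg$nf4$sup %in% c(nxg$nf2$a1, nxg$nf2$a2))
  expect_equal(nxg$nf2$sup, "C")
})

test_that("normalization is deterministic and preserves entailments vs complexified twins", {
  # Build pairs (flat, complex) that are semantically equivalent by
  # construction and check the saturations agree over original classes.
  for (seed in 1:20) {
    base <- random_el_ontology(seed, n_classes = 8, n_props = 2, density = 1.2)
    # complexified twin: replace each pair of NF1/NF3 axioms about a common
    # subclass by a single conjunction axiom
    axs <- base$axioms
    subs <- vapply(axs, function(a) {
      if (a$type == "subclassof" && a$sub$kind == "named") a$sub$id else NA_character_
    }, character(1))
    dup <- names(which(table(subs[!is.na(subs)]) >= 2L))
    if (length(dup)) {
      tgt <- dup[1L]
      idx <- which(subs == tgt)[1:2]
      merged <- ax_sub(
        axs[[idx[1L]]]$sub,
        ce_and(axs[[idx[1L]]]$sup, axs[[idx[2L]]]$sup)
      )
      axs2 <- c(axs[-idx], list(merged))
      twin <- el_ontology(base$classes, base$properties, axs2)
      s1 <- saturate(normalize(base))
      s2 <- saturate(normalize(twin))
      expect_identical(
        sub_pairs(s1, base$classes$id),
        sub_pairs(s2, base$classes$id)
      )
    }
    # determinism: same input, same normalization
    expect_identical(normalize(base), normalize(base))
  }
})
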