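#' Normalize an identifier to CURIE form
#'
#' Ontology identifiers arrive in several spellings: full OBO-style IRIs
#' (`http://purl.obolibrary.org/obo/GO_0038171`), underscore CURIEs
#' (`GO_0038171`) and colon CURIEs (`GO:0038171`). All are normalized to the
#' colon form; identifiers that match none of these patterns (symbolic
#' property names such as `has_participant`) are returned unchanged.
#'
#' @param id character vector of identifiers.
#' @return character vector of normalized identifiers.
#' @examples
#' curie(c("GO_0038171", "http://purl.obolibrary.org/obo/CHEBI_67194"))
#' @export
curie <- function(id) {
  id <- as.character(id)
  iri <- grepl("^https?://", id)
  id[iri] <- sub("^.*[/#]", "", id[iri])
  # OBO local ids are PREFIX_LOCAL; only rewrite the first underscore of that
  # shape so symbolic names like `has_participant` survive untouched
  obo <- !grepl(":", id, fixed = TRUE) &
    grepl("^[A-Za-z][A-Za-z0-9.-]*_[A-Za-z0-9][A-Za-z0-9_.-]*$", id) &
    grepl("^[A-Z]", id)
  id[obo] <- sub("_", ":", id[obo])
  id
}

#' Extract the CURIE prefix (namespace) of identifiers
#' @param id character vector of CURIEs.
#' @return character vector of prefixes; `""` where no colon is present.
#' @export
curie_prefix <- function(id) {
  out <- sub(":.*$", "", id)
  out[!grepl(":", id, fixed = TRUE)] <- ""
  out
}

# ---- EL class expressions -------------------------------------------------
# An expression is a plain list tagged with class "el_expr":
#   named: list(kind = "named", id)
#   and:   list(kind = "and", args = list of el_expr), length >= 2, flattened,
#          canonically ordered by expression key
#   some:  list(kind = "some", property, filler = el_expr)
# The EL profile admits exactly these three constructors: no union, negation,
# universal restriction or inverse appears anywhere.

new_expr <- function(x) structure(x, class = "el_expr")

#' EL class expression constructors
#'
#' `ce_named()` wraps a named class, `ce_and()` builds a conjunction (nested
#' conjunctions are flattened and conjuncts ordered canonically), and
#' `ce_some()` builds an existential restriction. Together they span the OWL 2
#' EL class-expression language used for mapping queries.
#'
#' @param id class identifier (normalized with [curie()]).
#' @param ... for `ce_and()`, two or more expressions (bare identifiers are
#'   promoted with `ce_named()`).
#' @param property property identifier.
#' @param filler filler expression or bare class identifier.
#' @return an object of class `el_expr`.
#' @examples
#' ce_some("has_participant", "CHEBI:67194")
#' ce_and("GO:0038171", ce_some("has_participant", "CHEBI:67194"))
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  new_expr(list(kind = "named", id = curie(id)))
}

#' @rdname ce_named
#' @export
ce_and <- function(...) {
  args <- lapply(list(...), as_expr)
  flat <- list()
  for (a in args) {
    if (a$kind == "and") flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  keys <- vapply(flat, expr_key, character(1))
  flat <- flat[order(keys)][!duplicated(sort(keys))]
  if (length(flat) == 1L) return(flat[[1L]])
  if (length(flat) < 2L) stop("ce_and() needs at least two conjuncts", call. = FALSE)
  new_expr(list(kind = "and", args = flat))
}

#' @rdname ce_named
#' @export
ce_some <- function(property, filler) {
  stopifnot(is.character(property), length(property) == 1L)
  new_expr(list(kind = "some", property = curie(property), filler = as_expr(filler)))
}

as_expr <- function(x) {
  if (inherits(x, "el_expr")) return(x)
  if (is.character(x) && length(x) == 1L) return(ce_named(x))
  stop("not an EL class expression: ", deparse(substitute(x)), call. = FALSE)
}

#' Canonical string key of an EL expression
#'
#' Used for deduplication and deterministic ordering of axioms; two
#' structurally equal expressions always share a key.
#'
#' @param e an `el_expr`.
#' @return length-one character.
#' @export
expr_key <- function(e) {
  switch(e$kind,
    named = e$id,
    some = paste0("Some(", e$property, " ", expr_key(e$filler), ")"),
    and = paste0(
      "And(",
      paste(sort(vapply(e$args, expr_key, character(1))), collapse = " "), ")"
    ),
    stop("unknown expression kind: ", e$kind)
  )
}

#' @export
print.el_expr <- function(x, ...) {
  cat("<el_expr> ", expr_key(x), "\n", sep = "")
  invisible(x)
}

# All named class ids appearing in an expression
expr_class_ids <- function(e) {
  switch(e$kind,
    named = e$id,
    some = expr_class_ids(e$filler),
    and = unlist(lapply(e$args, expr_class_ids), use.names = FALSE)
  )
}

# All property ids appearing in an expression
expr_prop_ids <- function(e) {
  switch(e$kind,
    named = character(),
    some = c(e$property, expr_prop_ids(e$filler)),
    and = unlist(lapply(e$args, expr_prop_ids), use.names = FALSE)
  )
}

# ---- Axioms ---------------------------------------------------------------
# list(type = "subclassof",  sub = el_expr, sup = el_expr)
# list(type = "equivalent",  exprs = list of el_expr, length >= 2)
# list(type = "subpropertyof", sub = id, sup = id)
# list(type = "chain", first = id, second = id, sup = id)

new_axiom <- function(x) structure(x, class = "el_axiom")

#' Axiom constructors
#'
#' The axiom kinds supported are exactly those needed for EL reasoning over
#' GO-style ontologies: `ax_sub()` for SubClassOf (GCIs — complex left sides —
#' are permitted), `ax_equiv()` for EquivalentClasses, `ax_subprop()` for
#' SubObjectPropertyOf and `ax_chain()` for a binary property chain
#' `first o second -> sup`.
#'
#' @param sub,sup class expressions (for `ax_sub`) or property ids (for
#'   `ax_subprop`, `ax_chain`).
#' @param ... two or more class expressions for `ax_equiv()`.
#' @param first,second property ids composed by the chain.
#' @return an object of class `el_axiom`.
#' @export
ax_sub <- function(sub, sup) {
  new_axiom(list(type = "subclassof", sub = as_expr(sub), sup = as_expr(sup)))
}

#' @rdname ax_sub
#' @export
ax_equiv <- function(...) {
  exprs <- lapply(list(...), as_expr)
  if (length(exprs) < 2L) stop("ax_equiv() needs at least two expressions", call. = FALSE)
  new_axiom(list(type = "equivalent", exprs = exprs))
}

#' @rdname ax_sub
#' @export
ax_subprop <- function(sub, sup) {
  new_axiom(list(type = "subpropertyof", sub = curie(sub), sup = curie(sup)))
}

#' @rdname ax_sub
#' @export
ax_chain <- function(first, second, sup) {
  new_axiom(list(
    type = "chain",
    first = curie(first), second = curie(second), sup = curie(sup)
  ))
}

axiom_key <- function(ax) {
  switch(ax$type,
    subclassof = paste0("SubClassOf(", expr_key(ax$sub), " ", expr_key(ax$sup), ")"),
    equivalent = paste0(
      "EquivalentClasses(",
      paste(sort(vapply(ax$exprs, expr_key, character(1))), collapse = " "), ")"
    ),
    subpropertyof = paste0("SubObjectPropertyOf(", ax$sub, " ", ax$sup, ")"),
    chain = paste0(
      "SubObjectPropertyOf(ObjectPropertyChain(", ax$first, " ", ax$second,
      ") ", ax$sup, ")"
    ),
    stop("unknown axiom type: ", ax$type)
  )
}

#' @export
print.el_axiom <- function(x, ...) {
  cat("<el_axiom> ", axiom_key(x), "\n", sep = "")
  invisible(x)
}

axiom_class_ids <- function(ax) {
  switch(ax$type,
    subclassof = c(expr_class_ids(ax$sub), expr_class_ids(ax$sup)),
    equivalent = unlist(lapply(ax$exprs, expr_class_ids), use.names = FALSE),
    character()
  )
}

axiom_prop_ids <- function(ax) {
  switch(ax$type,
    subclassof = c(expr_prop_ids(ax$sub), expr_prop_ids(ax$sup)),
    equivalent = unlist(lapply(ax$exprs, expr_prop_ids), use.names = FALSE),
    subpropertyof = c(ax$sub, ax$sup),
    chain = c(ax$first, ax$second, ax$sup)
  )
}
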