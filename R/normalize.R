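# EL normalization: every class axiom is decomposed into the four normal
# forms over named classes,
#   NF1  A ⊑ B
#   NF2  A1 ⊓ A2 ⊑ B
#   NF3  A ⊑ ∃R.B
#   NF4  ∃R.A ⊑ B
# introducing fresh named classes (reserved prefix "X:") for complex
# subexpressions. EquivalentClasses splits into mutual SubClassOf;
# transitivity of R is compiled to the chain R o R ⊑ R so that the rule
# engine needs a single composed-role rule. Fresh-name assignment is
# deterministic in input order: the same ontology always normalizes to the
# same result.

FRESH_PREFIX <- "X"

#' Normalize an ontology to EL normal forms
#'
#' @param ont an [el_ontology()].
#' @return an object of class `el_nf`: tibbles `nf1` (sub, sup), `nf2`
#'   (a1, a2, sup), `nf3` (sub, role, filler), `nf4` (role, filler, sup),
#'   `subprops` (sub, sup), `chains` (r1, r2, sup); character vectors
#'   `reflexive` (reflexive property ids), `classes` (all named classes,
#'   original plus fresh), `original` and `fresh`.
#' @export
normalize <- function(ont) {
  stopifnot(inherits(ont, "el_ontology"))
  if (any(curie_prefix(ont$classes$id) == FRESH_PREFIX)) {
    stop("input ontology uses the reserved fresh-class prefix '", FRESH_PREFIX, ":'",
      call. = FALSE
    )
  }
  st <- new.env(parent = emptyenv())
  st$counter <- 0L
  st$fresh <- character()
  st$nf1 <- list()
  st$nf2 <- list()
  st$nf3 <- list()
  st$nf4 <- list()

  for (ax in ont$axioms) {
    switch(ax$type,
      subclassof = nf_subclass(st, ax$sub, ax$sup),
      equivalent = {
        # mutual SubClassOf against the first expression
        e1 <- ax$exprs[[1L]]
        for (e in ax$exprs[-1L]) {
          nf_subclass(st, e1, e)
          nf_subclass(st, e, e1)
        }
      },
      NULL
    )
  }

  subprops <- do.call(
    rbind,
    c(
      list(data.frame(sub = character(), sup = character())),
      lapply(
        Filter(function(a) a$type == "subpropertyof", ont$axioms),
        function(a) data.frame(sub = a$sub, sup = a$sup)
      )
    )
  )
  chains <- do.call(
    rbind,
    c(
      list(data.frame(r1 = character(), r2 = character(), sup = character())),
      lapply(
        Filter(function(a) a$type == "chain", ont$axioms),
        function(a) data.frame(r1 = a$first, r2 = a$second, sup = a$sup)
      )
    )
  )
  # transitivity as a self-chain
  tr <- ont$properties$id[ont$properties$transitive]
  if (length(tr)) {
    chains <- rbind(chains, data.frame(r1 = tr, r2 = tr, sup = tr))
  }

  structure(
    list(
      nf1 = bind_nf(st$nf1, c("sub", "sup")),
      nf2 = bind_nf(st$nf2, c("a1", "a2", "sup")),
      nf3 = bind_nf(st$nf3, c("sub", "role", "filler")),
      nf4 = bind_nf(st$nf4, c("role", "filler", "sup")),
      subprops = tibble::as_tibble(unique(subprops)),
      chains = tibble::as_tibble(unique(chains)),
      reflexive = ont$properties$id[ont$properties$reflexive],
      classes = c(ont$classes$id, st$fresh),
      original = ont$classes$id,
      fresh = st$fresh
    ),
    class = "el_nf"
  )
}

bind_nf <- function(rows, cols) {
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(replicate(length(cols), character(), simplify = FALSE), cols))
    return(tibble::as_tibble(out))
  }
  out <- unique(do.call(rbind, rows))
  names(out) <- cols
  tibble::as_tibble(out)
}

nf_fresh <- function(st) {
  st$counter <- st$counter + 1L
  id <- paste0(FRESH_PREFIX, ":", st$counter)
  st$fresh <- c(st$fresh, id)
  id
}

emit <- function(st, slot, row) {
  st[[slot]] <- c(st[[slot]], list(as.data.frame(as.list(row), stringsAsFactors = FALSE)))
}

# Name for an expression used on the LEFT of ⊑: returns a named class A with
# the emitted axioms entailing  expr ⊑ A.
nf_name_sub <- function(st, e) {
  switch(e$kind,
    named = e$id,
    some = {
      a <- nf_name_sub(st, e$filler)
      f <- nf_fresh(st)
      emit(st, "nf4", c(role = e$property, filler = a, sup = f))
      f
    },
    and = {
      parts <- vapply(e$args, function(x) nf_name_sub(st, x), character(1))
      acc <- parts[1L]
      for (i in seq_along(parts)[-1L]) {
        f <- nf_fresh(st)
        emit(st, "nf2", c(a1 = acc, a2 = parts[i], sup = f))
        acc <- f
      }
      acc
    }
  )
}

# Emit axioms entailing  A ⊑ expr  for a named class A.
nf_expand_sup <- function(st, a, e) {
  switch(e$kind,
    named = emit(st, "nf1", c(sub = a, sup = e$id)),
    and = for (x in e$args) nf_expand_sup(st, a, x),
    some = {
      if (e$filler$kind == "named") {
        emit(st, "nf3", c(sub = a, role = e$property, filler = e$filler$id))
      } else {
        b <- nf_fresh(st)
        emit(st, "nf3", c(sub = a, role = e$property, filler = b))
        nf_expand_sup(st, b, e$filler)
      }
    }
  )
}

nf_subclass <- function(st, sub, sup) {
  if (sub$kind == "named") {
    nf_expand_sup(st, sub$id, sup)
    return(invisible())
  }
  # target name for the right-hand side
  target <- if (sup$kind == "named") {
    sup$id
  } else {
    f <- nf_fresh(st)
    nf_expand_sup(st, f, sup)
    f
  }
  if (sub$kind == "some") {
    a <- nf_name_sub(st, sub$filler)
    emit(st, "nf4", c(role = sub$property, filler = a, sup = target))
  } else { # conjunction (GCI): fold conjunct names into NF2 entries
    parts <- vapply(sub$args, function(x) nf_name_sub(st, x), character(1))
    acc <- parts[1L]
    if (length(parts) == 2L) {
      emit(st, "nf2", c(a1 = parts[1L], a2 = parts[2L], sup = target))
    } else {
      for (i in 2L:(length(parts) - 1L)) {
        f <- nf_fresh(st)
        emit(st, "nf2", c(a1 = acc, a2 = parts[i], sup = f))
        acc <- f
      }
      emit(st, "nf2", c(a1 = acc, a2 = parts[length(parts)], sup = target))
    }
  }
  invisible()
}

#' @export
print.el_nf <- function(x, ...) {
  cat(
    "<el_nf> NF1:", nrow(x$nf1), " NF2:", nrow(x$nf2),
    " NF3:", nrow(x$nf3), " NF4:", nrow(x$nf4),
    " subprops:", nrow(x$subprops), " chains:", nrow(x$chains),
    " classes:", length(x$classes),
    " (", length(x$fresh), " fresh)\n",
    sep = ""
  )
  invisible(x)
}
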