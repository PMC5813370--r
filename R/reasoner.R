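# Completion-rule saturation for normalized EL axioms. Two implementations
# share the rule set:
#   * saturate():      indexed worklist algorithm (the production path)
#   * naive_closure(): brute-force fixpoint over dense matrices, repeated
#                      whole-ruleset passes until nothing changes (the test
#                      oracle; no worklist, no axiom indexing)
# Rules (least fixpoint):
#   init  C ⊑ C for every class C
#   R1    C ⊑ A, (A ⊑ B)        ⇒ C ⊑ B
#   R2    C ⊑ A1, C ⊑ A2, (A1 ⊓ A2 ⊑ B) ⇒ C ⊑ B
#   R3    C ⊑ A, (A ⊑ ∃R.B)     ⇒ link(C,R,B)
#   R4    link(C,R,D), D ⊑ A, (∃R.A ⊑ B) ⇒ C ⊑ B
#   R5    link(C,R,D), R ⊑ S     ⇒ link(C,S,D)
#   R6    link(C,R1,D), link(D,R2,E), (R1 o R2 ⊑ S) ⇒ link(C,S,E)
#   R7    reflexive R            ⇒ link(C,R,C) for every class C

SEP <- "\r"

#' Saturate normalized EL axioms (worklist algorithm)
#'
#' Computes the least fixpoint of the EL completion rules with a worklist
#' and axiom indexes keyed on class and on (property, class), the standard
#' strategy for scaling to full GO.
#'
#' @param nx an `el_nf` object from [normalize()].
#' @return an object of class `el_saturation`: `subsumptions` is a named
#'   list mapping each class to the sorted character vector of its
#'   subsumers (always including itself), `links` a tibble
#'   (src, property, tgt) closed under the role rules.
#' @export
saturate <- function(nx) {
  stopifnot(inherits(nx, "el_nf"))
  classes <- nx$classes

  nf1_by_sub <- split(nx$nf1$sup, nx$nf1$sub)
  nf2_by_a <- split(
    rbind(
      data.frame(a = nx$nf2$a1, other = nx$nf2$a2, sup = nx$nf2$sup),
      data.frame(a = nx$nf2$a2, other = nx$nf2$a1, sup = nx$nf2$sup)
    ),
    rep(c(nx$nf2$a1, nx$nf2$a2), 1)
  )
  nf3_by_sub <- split(nx$nf3[, c("role", "filler")], nx$nf3$sub)
  nf4_by_role <- split(nx$nf4[, c("filler", "sup")], nx$nf4$role)
  subprop_by_sub <- split(nx$subprops$sup, nx$subprops$sub)
  chain_by_r1 <- split(nx$chains[, c("r2", "sup")], nx$chains$r1)
  chain_by_r2 <- split(nx$chains[, c("r1", "sup")], nx$chains$r2)

  seen_sub <- new.env(hash = TRUE, parent = emptyenv())
  seen_link <- new.env(hash = TRUE, parent = emptyenv())
  sup_of <- new.env(hash = TRUE, parent = emptyenv()) # C -> supers
  link_fwd <- new.env(hash = TRUE, parent = emptyenv()) # (R,C) -> targets
  link_bwd <- new.env(hash = TRUE, parent = emptyenv()) # (R,D) -> sources
  out_links <- list()

  queue <- vector("list", 256L)
  qhead <- 0L

  push <- function(item) {
    qhead <<- qhead + 1L
    if (qhead > length(queue)) length(queue) <<- 2L * qhead
    queue[[qhead]] <<- item
  }
  add_sub <- function(c, a) {
    k <- paste0(c, SEP, a)
    if (!is.null(seen_sub[[k]])) return(invisible())
    seen_sub[[k]] <- TRUE
    sup_of[[c]] <- c(sup_of[[c]], a)
    push(list(t = 1L, c = c, a = a))
  }
  add_link <- function(c, r, d) {
    k <- paste0(c, SEP, r, SEP, d)
    if (!is.null(seen_link[[k]])) return(invisible())
    seen_link[[k]] <- TRUE
    fk <- paste0(r, SEP, c)
    bk <- paste0(r, SEP, d)
    link_fwd[[fk]] <- c(link_fwd[[fk]], d)
    link_bwd[[bk]] <- c(link_bwd[[bk]], c)
    out_links[[length(out_links) + 1L]] <<- c(c, r, d)
    push(list(t = 2L, c = c, r = r, d = d))
  }
  has_sub <- function(c, a) !is.null(seen_sub[[paste0(c, SEP, a)]])

  for (c in classes) add_sub(c, c)
  for (r in nx$reflexive) for (c in classes) add_link(c, r, c)

  while (qhead > 0L) {
    item <- queue[[qhead]]
    qhead <- qhead - 1L
    if (item$t == 1L) { # new subsumption C ⊑ A
      c <- item$c
      a <- item$a
      for (b in nf1_by_sub[[a]]) add_sub(c, b) # R1
      rows <- nf2_by_a[[a]] # R2
      if (!is.null(rows)) {
        for (i in seq_len(nrow(rows))) {
          if (has_sub(c, rows$other[i])) add_sub(c, rows$sup[i])
        }
      }
      rows <- nf3_by_sub[[a]] # R3
      if (!is.null(rows)) {
        for (i in seq_len(nrow(rows))) add_link(c, rows$role[i], rows$filler[i])
      }
      # R4 triggered by D ⊑ A: find links ending at D = c
      for (r in names(nf4_by_role)) {
        rows <- nf4_by_role[[r]]
        hit <- rows$sup[rows$filler == a]
        if (length(hit)) {
          srcs <- link_bwd[[paste0(r, SEP, c)]]
          for (s in srcs) for (b in hit) add_sub(s, b)
        }
      }
    } else { # new link (C, R, D)
      c <- item$c
      r <- item$r
      d <- item$d
      rows <- nf4_by_role[[r]] # R4 triggered by the link
      if (!is.null(rows)) {
        for (i in seq_len(nrow(rows))) {
          if (has_sub(d, rows$filler[i])) add_sub(c, rows$sup[i])
        }
      }
      for (s in subprop_by_sub[[r]]) add_link(c, s, d) # R5
      rows <- chain_by_r1[[r]] # R6, link as first component
      if (!is.null(rows)) {
        for (i in seq_len(nrow(rows))) {
          for (e in link_fwd[[paste0(rows$r2[i], SEP, d)]]) {
            add_link(c, rows$sup[i], e)
          }
        }
      }
      rows <- chain_by_r2[[r]] # R6, link as second component
      if (!is.null(rows)) {
        for (i in seq_len(nrow(rows))) {
          for (b in link_bwd[[paste0(rows$r1[i], SEP, c)]]) {
            add_link(b, rows$sup[i], d)
          }
        }
      }
    }
  }

  subs <- stats::setNames(
    lapply(classes, function(c) sort(sup_of[[c]])),
    classes
  )
  links <- if (length(out_links)) {
    m <- do.call(rbind, out_links)
    tibble::tibble(src = m[, 1L], property = m[, 2L], tgt = m[, 3L]) |>
      dplyr::arrange(.data$src, .data$property, .data$tgt)
  } else {
    tibble::tibble(src = character(), property = character(), tgt = character())
  }
  structure(list(subsumptions = subs, links = links), class = "el_saturation")
}

#' Brute-force fixpoint oracle
#'
#' Independent re-computation of the saturation by repeated passes of every
#' completion rule over dense logical matrices until nothing changes. No
#' worklist, no axiom indexing; intended for small inputs (tens of classes)
#' and used to cross-check [saturate()].
#'
#' @param nx an `el_nf` object from [normalize()].
#' @return an `el_saturation`, identical to the one [saturate()] produces.
#' @export
naive_closure <- function(nx) {
  stopifnot(inherits(nx, "el_nf"))
  cls <- nx$classes
  n <- length(cls)
  props <- unique(c(
    nx$nf3$role, nx$nf4$role, nx$subprops$sub, nx$subprops$sup,
    nx$chains$r1, nx$chains$r2, nx$chains$sup, nx$reflexive
  ))
  S <- matrix(FALSE, n, n, dimnames = list(cls, cls)) # S[C, A] <=> C ⊑ A
  diag(S) <- TRUE
  L <- stats::setNames(
    lapply(props, function(p) {
      m <- matrix(FALSE, n, n, dimnames = list(cls, cls))
      if (p %in% nx$reflexive) diag(m) <- TRUE
      m
    }),
    props
  )

  repeat {
    changed <- FALSE
    snap <- function(new, old) any(new != old)
    for (i in seq_len(nrow(nx$nf1))) { # R1
      new <- S[, nx$nf1$sup[i]] | S[, nx$nf1$sub[i]]
      if (snap(new, S[, nx$nf1$sup[i]])) changed <- TRUE
      S[, nx$nf1$sup[i]] <- new
    }
    for (i in seq_len(nrow(nx$nf2))) { # R2
      new <- S[, nx$nf2$sup[i]] | (S[, nx$nf2$a1[i]] & S[, nx$nf2$a2[i]])
      if (snap(new, S[, nx$nf2$sup[i]])) changed <- TRUE
      S[, nx$nf2$sup[i]] <- new
    }
    for (i in seq_len(nrow(nx$nf3))) { # R3
      r <- nx$nf3$role[i]
      new <- L[[r]][, nx$nf3$filler[i]] | S[, nx$nf3$sub[i]]
      if (snap(new, L[[r]][, nx$nf3$filler[i]])) changed <- TRUE
      L[[r]][, nx$nf3$filler[i]] <- new
    }
    for (i in seq_len(nrow(nx$nf4))) { # R4
      r <- nx$nf4$role[i]
      reach <- (L[[r]] %*% S[, nx$nf4$filler[i], drop = FALSE]) > 0
      new <- S[, nx$nf4$sup[i]] | reach[, 1L]
      if (snap(new, S[, nx$nf4$sup[i]])) changed <- TRUE
      S[, nx$nf4$sup[i]] <- new
    }
    for (i in seq_len(nrow(nx$subprops))) { # R5
      s <- nx$subprops$sup[i]
      new <- L[[s]] | L[[nx$subprops$sub[i]]]
      if (snap(new, L[[s]])) changed <- TRUE
      L[[s]] <- new
    }
    for (i in seq_len(nrow(nx$chains))) { # R6
      s <- nx$chains$sup[i]
      comp <- (L[[nx$chains$r1[i]]] %*% L[[nx$chains$r2[i]]]) > 0
      new <- L[[s]] | comp
      if (snap(new, L[[s]])) changed <- TRUE
      L[[s]] <- new
    }
    if (!changed) break
  }

  subs <- stats::setNames(
    lapply(cls, function(c) sort(cls[S[c, ]])),
    cls
  )
  link_rows <- list()
  for (p in sort(props)) {
    idx <- which(L[[p]], arr.ind = TRUE)
    if (nrow(idx)) {
      link_rows[[p]] <- tibble::tibble(
        src = cls[idx[, 1L]], property = p, tgt = cls[idx[, 2L]]
      )
    }
  }
  links <- if (length(link_rows)) {
    dplyr::bind_rows(link_rows) |>
      dplyr::arrange(.data$src, .data$property, .data$tgt)
  } else {
    tibble::tibble(src = character(), property = character(), tgt = character())
  }
  structure(list(subsumptions = subs, links = links), class = "el_saturation")
}

#' @export
print.el_saturation <- function(x, ...) {
  cat(
    "<el_saturation> ", length(x$subsumptions), " classes, ",
    sum(lengths(x$subsumptions)), " subsumptions, ",
    nrow(x$links), " links\n",
    sep = ""
  )
  invisible(x)
}

#' Classify a saturation into a taxonomy
#'
#' Groups mutually subsuming classes into equivalence groups and computes
#' direct (transitively reduced) subsumption edges between groups.
#'
#' @param sat an `el_saturation`.
#' @param classes classes to include; defaults to all non-fresh classes in
#'   the saturation.
#' @return a list with `groups` (list of character vectors, each sorted; the
#'   first element is the representative) and `edges` (tibble from, to of
#'   group representatives).
#' @export
classify <- function(sat, classes = NULL) {
  stopifnot(inherits(sat, "el_saturation"))
  all_cls <- names(sat$subsumptions)
  if (is.null(classes)) {
    classes <- all_cls[curie_prefix(all_cls) != FRESH_PREFIX]
  }
  sup <- lapply(sat$subsumptions[classes], intersect, classes)

  rep_of <- character(0)
  groups <- list()
  for (c in sort(classes)) {
    eq <- sort(Filter(function(a) c %in% sup[[a]], sup[[c]]))
    key <- eq[1L]
    if (is.null(groups[[key]])) groups[[key]] <- eq
    rep_of[c] <- key
  }
  reps <- names(groups)

  # strict subsumption between representatives
  edges <- list()
  for (a in reps) {
    strict <- setdiff(unique(rep_of[intersect(sup[[a]], names(rep_of))]), a)
    for (b in strict) {
      # direct iff no intermediate representative strictly between
      inter <- setdiff(strict, b)
      direct <- !any(vapply(
        inter,
        function(m) b %in% rep_of[intersect(sup[[m]], names(rep_of))],
        logical(1)
      ))
      if (direct) edges[[length(edges) + 1L]] <- c(a, b)
    }
  }
  edges <- if (length(edges)) {
    m <- do.call(rbind, edges)
    tibble::tibble(from = m[, 1L], to = m[, 2L]) |>
      dplyr::arrange(.data$from, .data$to)
  } else {
    tibble::tibble(from = character(), to = character())
  }
  list(groups = unname(groups), edges = edges)
}
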