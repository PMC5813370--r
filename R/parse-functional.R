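# Parser and writer for a small OWL functional-syntax subset: the axiom
# kinds that occur in an EL-profile GO release (class/property declarations,
# SubClassOf, EquivalentClasses, intersections, existential restrictions,
# property hierarchy and chains, transitivity, reflexivity) plus rdfs:label
# and owl:deprecated annotations. Anything else is rejected, either as a
# profile violation (named DL constructs) or a parse error.

FS_PROFILE_VIOLATIONS <- c(
  "ObjectUnionOf", "ObjectComplementOf", "ObjectAllValuesFrom",
  "ObjectInverseOf", "InverseObjectProperties", "ObjectOneOf",
  "ObjectMaxCardinality", "ObjectMinCardinality", "ObjectExactCardinality",
  "DisjointUnion", "DataAllValuesFrom", "ObjectHasValue"
)

#' Parse an OWL functional-syntax subset
#'
#' Reads hand-written EL fixtures. Supported constructs:
#' `Declaration(Class(..))`, `Declaration(ObjectProperty(..))`,
#' `SubClassOf`, `EquivalentClasses`, `ObjectIntersectionOf`,
#' `ObjectSomeValuesFrom`, `SubObjectPropertyOf` (including
#' `ObjectPropertyChain` of length two), `TransitiveObjectProperty`,
#' `ReflexiveObjectProperty`, and `AnnotationAssertion` with `rdfs:label`
#' or `owl:deprecated`. `DisjointClasses` is accepted but ignored with a
#' warning (EL uses it only for unsatisfiability, which this reasoner does
#' not track); `InverseObjectProperties` likewise. Named non-EL constructs
#' such as `ObjectUnionOf` raise a profile-violation error.
#'
#' @param text a length-one string, or a character vector of lines, or a
#'   file path (detected when the string names an existing file).
#' @return an [el_ontology()].
#' @export
parse_functional_subset <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  text <- paste(text, collapse = "\n")
  toks <- fs_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks$token
  st$lines <- toks$line
  st$pos <- 1L

  classes <- list()
  props <- list()
  axioms <- list()
  labels <- list()
  deprecated <- character()
  trans <- character()
  refl <- character()
  n_disjoint <- 0L
  n_inverse <- 0L

  while (st$pos <= length(st$toks)) {
    head <- fs_peek(st)
    if (head %in% FS_PROFILE_VIOLATIONS) {
      stop("OWL 2 EL profile violation: construct ", head, " is not supported",
        call. = FALSE
      )
    }
    if (head == "Prefix") { # tolerated wrapper; contents ignored
      fs_next(st)
      if (fs_peek(st) == "(") fs_skip_group(st)
      next
    }
    if (head == "Ontology") { # tolerated wrapper; keep parsing its contents
      fs_next(st)
      if (fs_peek(st) == "(") {
        fs_next(st)
        while (st$pos <= length(st$toks) && grepl("^<", fs_peek(st))) fs_next(st)
      }
      next
    }
    if (head == ")") { # closing of a tolerated Ontology( wrapper
      fs_next(st)
      next
    }
    form <- fs_read_form(st)
    kw <- form$head
    if (kw %in% FS_PROFILE_VIOLATIONS) {
      stop("OWL 2 EL profile violation: construct ", kw, " is not supported",
        call. = FALSE
      )
    }
    switch(kw,
      "Declaration" = {
        inner <- form$args[[1L]]
        id <- curie(fs_entity(inner$args[[1L]]))
        if (inner$head == "Class") classes[[id]] <- TRUE
        else if (inner$head == "ObjectProperty") props[[id]] <- TRUE
        else stop("unsupported declaration kind: ", inner$head, call. = FALSE)
      },
      "SubClassOf" = {
        axioms <- c(axioms, list(ax_sub(fs_expr(form$args[[1L]]), fs_expr(form$args[[2L]]))))
      },
      "EquivalentClasses" = {
        exprs <- lapply(form$args, fs_expr)
        axioms <- c(axioms, list(do.call(ax_equiv, exprs)))
      },
      "SubObjectPropertyOf" = {
        a1 <- form$args[[1L]]
        if (is.list(a1) && identical(a1$head, "ObjectPropertyChain")) {
          chain <- vapply(a1$args, fs_entity, character(1))
          if (length(chain) != 2L) {
            stop("only binary property chains are supported", call. = FALSE)
          }
          axioms <- c(axioms, list(ax_chain(chain[1L], chain[2L], fs_entity(form$args[[2L]]))))
        } else {
          axioms <- c(axioms, list(ax_subprop(fs_entity(a1), fs_entity(form$args[[2L]]))))
        }
      },
      "TransitiveObjectProperty" = {
        trans <- c(trans, curie(fs_entity(form$args[[1L]])))
      },
      "ReflexiveObjectProperty" = {
        refl <- c(refl, curie(fs_entity(form$args[[1L]])))
      },
      "AnnotationAssertion" = {
        prop <- fs_entity(form$args[[1L]])
        subj <- curie(fs_entity(form$args[[2L]]))
        val <- form$args[[3L]]
        val <- if (is.list(val)) fs_entity(val) else val
        if (prop %in% c("rdfs:label", "label")) {
          labels[[subj]] <- fs_unquote(val)
        } else if (prop %in% c("owl:deprecated", "deprecated")) {
          if (tolower(fs_unquote(val)) %in% c("true", "1")) {
            deprecated <- c(deprecated, subj)
          }
        } # other annotations ignored
      },
      "DisjointClasses" = {
        n_disjoint <- n_disjoint + 1L
      },
      stop("unsupported construct: ", kw, call. = FALSE)
    )
  }
  if (n_disjoint > 0L) {
    warning(n_disjoint, " DisjointClasses axiom(s) ignored (not used for EL subsumption)",
      call. = FALSE
    )
  }

  cls_ids <- names(classes) %||% character()
  prp_ids <- names(props) %||% character()
  el_ontology(
    classes = tibble::tibble(
      id = cls_ids,
      label = vapply(
        cls_ids,
        function(i) if (is.null(labels[[i]])) NA_character_ else labels[[i]],
        character(1), USE.NAMES = FALSE
      ),
      obsolete = cls_ids %in% deprecated
    ),
    properties = tibble::tibble(
      id = prp_ids,
      label = vapply(
        prp_ids,
        function(i) if (is.null(labels[[i]])) NA_character_ else labels[[i]],
        character(1), USE.NAMES = FALSE
      ),
      transitive = prp_ids %in% trans,
      reflexive = prp_ids %in% refl
    ),
    axioms = axioms
  )
}

# -- tokenizer / recursive-descent machinery --------------------------------

fs_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  out_tok <- character()
  out_line <- integer()
  for (ln in seq_along(lines)) {
    s <- lines[ln]
    s <- sub("#.*$", "", s) # line comments
    pat <- '"(?:[^"\\\\]|\\\\.)*"|[()=]|[^()\\s]+'
    m <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    toks <- regmatches(s, list(m))[[1L]]
    out_tok <- c(out_tok, toks)
    out_line <- c(out_line, rep(ln, length(toks)))
  }
  list(token = out_tok, line = out_line)
}

fs_peek <- function(st) {
  if (st$pos > length(st$toks)) stop("unexpected end of input", call. = FALSE)
  st$toks[st$pos]
}

fs_next <- function(st) {
  t <- fs_peek(st)
  st$pos <- st$pos + 1L
  t
}

fs_line <- function(st) {
  st$lines[min(st$pos, length(st$lines))]
}

# Read one parenthesized form: head ( arg* ); args are atoms (strings) or
# nested forms (lists with $head/$args).
fs_read_form <- function(st) {
  head <- fs_next(st)
  if (fs_peek(st) != "(") {
    stop("parse error at line ", fs_line(st), ": expected '(' after ", head, call. = FALSE)
  }
  fs_next(st)
  args <- list()
  repeat {
    if (st$pos > length(st$toks)) {
      stop("parse error at line ", st$lines[length(st$lines)],
        ": unbalanced parentheses (unclosed ", head, ")",
        call. = FALSE
      )
    }
    t <- fs_peek(st)
    if (t == ")") {
      fs_next(st)
      break
    }
    if (st$pos < length(st$toks) && st$toks[st$pos + 1L] == "(") {
      args <- c(args, list(fs_read_form(st)))
    } else {
      args <- c(args, list(fs_next(st)))
    }
  }
  list(head = head, args = args)
}

fs_skip_group <- function(st) {
  stopifnot(fs_next(st) == "(")
  depth <- 1L
  while (depth > 0L) {
    if (st$pos > length(st$toks)) {
      stop("parse error: unbalanced parentheses", call. = FALSE)
    }
    t <- fs_next(st)
    if (t == "(") depth <- depth + 1L
    if (t == ")") depth <- depth - 1L
  }
}

fs_entity <- function(x) {
  if (is.list(x)) stop("expected an entity, got ", x$head, call. = FALSE)
  x <- sub("^<(.*)>$", "\\1", x)
  sub("^:", "", x)
}

fs_unquote <- function(x) {
  x <- sub('\\^\\^.*$', "", x) # strip datatype suffix
  if (startsWith(x, '"')) x <- gsub('\\\\"', '"', substr(x, 2L, nchar(x) - 1L))
  x
}

fs_expr <- function(x) {
  if (!is.list(x)) return(ce_named(fs_entity(x)))
  if (x$head %in% FS_PROFILE_VIOLATIONS) {
    stop("OWL 2 EL profile violation: construct ", x$head, " is not supported",
      call. = FALSE
    )
  }
  switch(x$head,
    "ObjectIntersectionOf" = do.call(ce_and, lapply(x$args, fs_expr)),
    "ObjectSomeValuesFrom" = ce_some(fs_entity(x$args[[1L]]), fs_expr(x$args[[2L]])),
    stop("unsupported class expression: ", x$head, call. = FALSE)
  )
}

# ---- writer ---------------------------------------------------------------

fs_render_expr <- function(e) {
  switch(e$kind,
    named = e$id,
    some = paste0(
      "ObjectSomeValuesFrom(", e$property, " ", fs_render_expr(e$filler), ")"
    ),
    and = paste0(
      "ObjectIntersectionOf(",
      paste(vapply(e$args, fs_render_expr, character(1)), collapse = " "), ")"
    )
  )
}

fs_render_axiom <- function(ax) {
  switch(ax$type,
    subclassof = paste0(
      "SubClassOf(", fs_render_expr(ax$sub), " ", fs_render_expr(ax$sup), ")"
    ),
    equivalent = paste0(
      "EquivalentClasses(",
      paste(vapply(ax$exprs, fs_render_expr, character(1)), collapse = " "), ")"
    ),
    subpropertyof = paste0("SubObjectPropertyOf(", ax$sub, " ", ax$sup, ")"),
    chain = paste0(
      "SubObjectPropertyOf(ObjectPropertyChain(", ax$first, " ", ax$second,
      ") ", ax$sup, ")"
    )
  )
}

#' Serialize an ontology to the functional-syntax subset
#'
#' Canonical dump used for fixtures and debugging: declarations first, then
#' property characteristics, annotations, and axioms in canonical order.
#' Re-parsing the dump yields an ontology with an identical axiom multiset.
#'
#' @param ont an `el_ontology`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`) a character vector
#'   of lines.
#' @export
write_functional_subset <- function(ont, path = NULL) {
  lines <- character()
  for (id in ont$classes$id) {
    lines <- c(lines, paste0("Declaration(Class(", id, "))"))
  }
  for (id in ont$properties$id) {
    lines <- c(lines, paste0("Declaration(ObjectProperty(", id, "))"))
  }
  pt <- ont$properties
  wrap <- function(kw, ids) {
    if (length(ids)) paste0(kw, "(", ids, ")") else character()
  }
  lines <- c(
    lines,
    wrap("TransitiveObjectProperty", pt$id[pt$transitive]),
    wrap("ReflexiveObjectProperty", pt$id[pt$reflexive])
  )
  lab <- dplyr::bind_rows(
    ont$classes[, c("id", "label")],
    pt[, c("id", "label")]
  )
  lab <- lab[!is.na(lab$label), , drop = FALSE]
  lines <- c(
    lines,
    sprintf('AnnotationAssertion(rdfs:label %s "%s")', lab$id, gsub('"', '\\\\"', lab$label)),
    sprintf(
      'AnnotationAssertion(owl:deprecated %s "true")',
      ont$classes$id[ont$classes$obsolete]
    ),
    sort(vapply(ont$axioms, fs_render_axiom, character(1)))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
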