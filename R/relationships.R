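#' Parse a pedigree relationship abbreviation
#'
#' Supported families and abbreviations:
#' * linear: `GP` (grandparent), `GGP` (great-grandparent), `GnGP`
#'   (n >= 2), e.g. `G2GP`; a linear relationship `GnGP` has degree n + 2.
#' * half-siblings: `HS`.
#' * avuncular: `N` (uncle--nephew), `GN` (great-nephew), `GnN` (n >= 2);
#'   half-avuncular: `HN`, `HGN`, `HGnN`.
#' * cousins: `sC` (s-th cousins, s >= 1) and `sCtR` (t times removed),
#'   e.g. `1C`, `2C1R`; half-cousins: `HsC`, `HsCtR`, e.g. `H1C2R`.
#'
#' Full siblings (`FS`, i.e. 0th cousins) are rejected: their IBD2
#' probability is positive, and the model here is restricted to the two
#' identity states IBD0 and IBD1.
#'
#' @param abbr a single abbreviation string.
#' @return a `relationship_spec` with fields `family` and the degree
#'   parameters (`n` for linear/avuncular, `s` and `t` for cousins,
#'   `half` flag). `format()` returns the canonical abbreviation, which
#'   round-trips through parsing.
#' @examples
#' parse_relationship("H1C2R")
#' format(parse_relationship("G1GP"))  # canonicalises to "GGP"
#' @export
parse_relationship <- function(abbr) {
  if (!is.character(abbr) || length(abbr) != 1L || is.na(abbr)) {
    stop("expected a single relationship abbreviation string")
  }
  tok <- toupper(trimws(abbr))
  spec <- NULL
  if (tok %in% c("FS", "0C") || grepl("^H?0C", tok)) {
    stop("relationship '", abbr, "' (full/half siblings as 0th cousins) is ",
         "rejected: IBD2-capable states are out of scope")
  }
  if (tok == "GP") {
    spec <- list(family = "linear", n = 0L)
  } else if (tok == "GGP") {
    spec <- list(family = "linear", n = 1L)
  } else if (grepl("^G([0-9]+)GP$", tok)) {
    n <- as.integer(sub("^G([0-9]+)GP$", "\\1", tok))
    spec <- list(family = "linear", n = n)
  } else if (tok == "HS") {
    spec <- list(family = "half-sibling")
  } else if (grepl("^(H?)(G?)N$", tok)) {
    half <- grepl("^H", tok)
    n <- if (grepl("G", tok)) 1L else 0L
    spec <- list(family = if (half) "half-avuncular" else "avuncular", n = n)
  } else if (grepl("^(H?)G([0-9]+)N$", tok)) {
    half <- grepl("^H", tok)
    n <- as.integer(sub("^H?G([0-9]+)N$", "\\1", tok))
    spec <- list(family = if (half) "half-avuncular" else "avuncular", n = n)
  } else if (grepl("^(H?)([0-9]+)C(([0-9]+)R)?$", tok)) {
    half <- grepl("^H", tok)
    s <- as.integer(sub("^H?([0-9]+)C.*$", "\\1", tok))
    t <- if (grepl("R$", tok)) {
      as.integer(sub("^H?[0-9]+C([0-9]+)R$", "\\1", tok))
    } else 0L
    if (s < 1L) {
      stop("cousin degree must satisfy s >= 1 in '", abbr, "'")
    }
    spec <- list(family = if (half) "half-cousin" else "cousin", s = s, t = t)
  } else {
    stop("cannot parse relationship abbreviation: '", abbr, "'")
  }
  structure(spec, class = "relationship_spec")
}

#' @export
format.relationship_spec <- function(x, ...) {
  switch(x$family,
    "linear" = if (x$n == 0L) "GP" else if (x$n == 1L) "GGP"
               else paste0("G", x$n, "GP"),
    "half-sibling" = "HS",
    "avuncular" = ,
    "half-avuncular" = {
      core <- if (x$n == 0L) "N" else if (x$n == 1L) "GN"
              else paste0("G", x$n, "N")
      if (x$family == "half-avuncular") paste0("H", core) else core
    },
    "cousin" = ,
    "half-cousin" = {
      core <- paste0(x$s, "C", if (x$t > 0L) paste0(x$t, "R") else "")
      if (x$family == "half-cousin") paste0("H", core) else core
    })
}

#' @export
print.relationship_spec <- function(x, ...) {
  cat("<relationship_spec> ", format(x), " (", x$family, ")\n", sep = "")
  invisible(x)
}

#' Build the minimal pedigree for a named relationship
#'
#' Constructs the minimal two-person pedigree connecting the studied pair
#' as specified; all founders are mutually unrelated. The pair is stored
#' on the returned pedigree.
#'
#' @param spec a `relationship_spec` from [parse_relationship()], or an
#'   abbreviation string.
#' @return an [ibd_pedigree()] whose `pair` is the two subjects.
#' @examples
#' relationship("1C")   # 4 non-founders, 8 meioses
#' relationship("GP")
#' @export
relationship <- function(spec) {
  if (is.character(spec)) spec <- parse_relationship(spec)
  if (!inherits(spec, "relationship_spec")) {
    stop("spec must be a relationship_spec or abbreviation string")
  }
  rows <- switch(spec$family,
    "linear" = build_linear(spec$n + 2L),
    "half-sibling" = build_sibs(half = TRUE, 0L, 0L),
    "avuncular" = build_sibs(half = FALSE, 0L, spec$n + 1L),
    "half-avuncular" = build_sibs(half = TRUE, 0L, spec$n + 1L),
    "cousin" = build_sibs(half = FALSE, spec$s, spec$s + spec$t),
    "half-cousin" = build_sibs(half = TRUE, spec$s, spec$s + spec$t))
  ped <- ibd_pedigree(rows$id, rows$father, rows$mother, pair = rows$pair)
  ped$label <- format(spec)
  ped$spec <- spec
  ped
}

# Linear relationship of degree d: ancestor A, chain of d descendants each
# with an unrelated founder spouse; pair (A, last).
build_linear <- function(d) {
  stopifnot(d >= 1L)
  id <- "A"; father <- NA_character_; mother <- NA_character_
  prev <- "A"
  for (i in seq_len(d)) {
    sp <- paste0("S", i); ch <- paste0("C", i)
    id <- c(id, sp, ch)
    father <- c(father, NA, prev)
    mother <- c(mother, NA, sp)
    prev <- ch
  }
  list(id = id, father = father, mother = mother, pair = c("A", prev))
}

# Two (half-)siblings S1, S2 with chains of la and lb meioses below them;
# pair is (end of chain a, end of chain b). la = 0 makes the first subject
# the sibling itself (avuncular for lb > 0, HS for la = lb = 0).
build_sibs <- function(half, la, lb) {
  if (half) {
    id <- c("G", "P1", "P2", "S1", "S2")
    father <- c(NA, NA, NA, "G", "G")
    mother <- c(NA, NA, NA, "P1", "P2")
  } else {
    id <- c("F", "M", "S1", "S2")
    father <- c(NA, NA, "F", "F")
    mother <- c(NA, NA, "M", "M")
  }
  chain <- function(top, len, tag) {
    prev <- top
    for (i in seq_len(len)) {
      sp <- paste0(tag, "sp", i); ch <- paste0(tag, i)
      id <<- c(id, sp, ch)
      father <<- c(father, NA, prev)
      mother <<- c(mother, NA, sp)
      prev <- ch
    }
    prev
  }
  a <- chain("S1", la, "A")
  b <- chain("S2", lb, "B")
  list(id = id, father = father, mother = mother, pair = c(a, b))
}

#' Coerce to a pedigree
#'
#' Accepts an existing [ibd_pedigree()], a relationship abbreviation, or a
#' `relationship_spec`.
#' @param x object to coerce.
#' @return an [ibd_pedigree()].
#' @export
as_ibd_pedigree <- function(x) {
  if (inherits(x, "ibd_pedigree")) return(x)
  if (is.character(x) || inherits(x, "relationship_spec")) {
    return(relationship(x))
  }
  stop("cannot interpret object of class '", class(x)[1], "' as a pedigree")
}
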