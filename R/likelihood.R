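# Exact likelihoods of observed IBD segment sets and likelihood ratios.

#' Hypotheses about a pedigree relationship
#'
#' A hypothesis is a single relationship or a composite: a set of
#' relationships with prior weights (default equal). Composite
#' likelihoods mix at the genome level:
#' `Pr(E | H) = sum_j w_j Pr(E | ped_j)`.
#'
#' @param x a pedigree, abbreviation, `relationship_spec`, or a list /
#'   character vector of those for a composite.
#' @param weights positive prior weights, summing to 1 after
#'   normalisation; default equal.
#' @param label optional display label.
#' @return an object of class `ibd_hypothesis`.
#' @examples
#' hypothesis("GP")
#' hypothesis(c("HS", "N"))       # equal-weight composite
#' @export
hypothesis <- function(x, weights = NULL, label = NULL) {
  if (inherits(x, "ibd_hypothesis")) return(x)
  if (inherits(x, "ibd_pedigree") || inherits(x, "relationship_spec") ||
      !is.list(x)) {
    x <- if (is.character(x)) as.list(x) else list(x)
  }
  peds <- lapply(x, as_ibd_pedigree)
  k <- length(peds)
  if (k < 1L) stop("a hypothesis needs at least one relationship")
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights <= 0)) {
    stop("weights must be positive, one per relationship")
  }
  weights <- weights / sum(weights)
  labels <- vapply(peds, function(p) p$label, character(1))
  structure(list(
    components = peds, weights = weights,
    label = if (is.null(label)) {
      if (k == 1L) labels else paste0("{", paste(labels, collapse = ","), "}")
    } else label
  ), class = "ibd_hypothesis")
}

#' @export
print.ibd_hypothesis <- function(x, ...) {
  cat("<ibd_hypothesis> ", x$label, "\n", sep = "")
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Batch conversion: an ibd_sim_batch (or a single ibd_segments object) to
# the flat arrays the C++ forward pass consumes.
loglik_arrays <- function(segs, map) {
  if (inherits(segs, "ibd_sim_batch")) {
    s <- segs$segments
    reps <- segs$reps
    chrom_idx <- s$chromosome_idx
  } else {
    stopifnot(inherits(segs, "ibd_segments"))
    s <- as.data.frame(segs)
    reps <- 1L
    chrom_idx <- match(s$chromosome, map$chromosome)
    ord <- order(chrom_idx, s$start_cM, method = "radix")
    s <- s[ord, , drop = FALSE]
    chrom_idx <- chrom_idx[ord]
    s$rep <- 1L
  }
  counts <- tabulate(s$rep, nbins = reps)
  list(rep_off = c(0L, cumsum(counts)),
       seg_chrom = as.integer(chrom_idx),
       seg_len = s$end_cM - s$start_cM,
       seg_state = as.integer(s$ibd_state),
       reps = reps)
}

# Natural-log likelihood(s) of a batch under one pedigree.
loglik_batch <- function(ped, arrays, epsilon) {
  mod <- ibd_model(as_ibd_pedigree(ped))
  cpp_loglik_many(mod$ibd1, mod$nbits, as.integer(arrays$rep_off),
                  arrays$seg_chrom, arrays$seg_len, arrays$seg_state,
                  epsilon)
}

#' Log-likelihood of an observed IBD segment set
#'
#' Exact likelihood of a continuously observed IBD segment set under a
#' hypothesized relationship. Per chromosome, the Poisson-conditioned
#' forward recursion propagates the hidden IBD-vector distribution
#' restricted to the states compatible with each segment; interior
#' segment boundaries contribute the exit intensity to the complementary
#' class (a density in the breakpoint position) and the final segment
#' contributes a staying probability only. Chromosomes are independent,
#' so the genome log-likelihood is the sum over chromosomes.
#'
#' A segment set that is impossible under the relationship (e.g., an IBD0
#' segment for a parent--child pair) yields `-Inf`.
#'
#' @param ped pedigree (or abbreviation).
#' @param segs an [ibd_segments()] object.
#' @param map optional [genetic_map()]; defaults to the map attached to
#'   `segs`. Supplying it re-validates the segments against that map.
#' @param epsilon per-segment truncation tolerance (default `1e-10`).
#' @return the natural-log likelihood (a density in the segment
#'   breakpoints).
#' @export
segment_loglikelihood <- function(ped, segs, map = NULL, epsilon = 1e-10) {
  if (is.null(map)) {
    map <- attr(segs, "map")
    if (is.null(map)) validation_error("segments carry no map; supply one")
  } else {
    map <- as_genetic_map(map)
    segs <- ibd_segments(as.data.frame(segs), map = map)
  }
  arr <- loglik_arrays(segs, map)
  loglik_batch(ped, arr, epsilon)[1]
}

# Natural-log likelihood under a (possibly composite) hypothesis.
hypothesis_loglik <- function(h, arrays, epsilon) {
  h <- hypothesis(h)
  ll <- vapply(h$components, loglik_batch, numeric(arrays$reps),
               arrays = arrays, epsilon = epsilon)
  ll <- matrix(ll, nrow = arrays$reps)
  apply(ll, 1L, function(row) logsumexp(row + log(h$weights)))
}

#' Likelihood ratio for an observed IBD segment set
#'
#' `LR = Pr(E | H1) / Pr(E | H2)` where `E` is the whole-genome segment
#' observation; composite hypotheses mix component likelihoods at the
#' genome level with their prior weights. Swapping the hypotheses negates
#' the log LR exactly.
#'
#' @param segs an [ibd_segments()] object.
#' @param h1,h2 hypotheses ([hypothesis()], pedigree, or abbreviation).
#' @param map optional map (see [segment_loglikelihood()]).
#' @param epsilon truncation tolerance.
#' @return a list of class `lr_result` with `log10_lik1`, `log10_lik2`
#'   and `log10_lr`.
#' @export
likelihood_ratio <- function(segs, h1, h2, map = NULL, epsilon = 1e-10) {
  if (is.null(map)) map <- attr(segs, "map")
  arr <- loglik_arrays(segs, map)
  l1 <- hypothesis_loglik(h1, arr, epsilon)[1]
  l2 <- hypothesis_loglik(h2, arr, epsilon)[1]
  if (!is.finite(l1) && !is.finite(l2)) {
    stop("likelihood ratio undefined: the observation is impossible ",
         "under both hypotheses")
  }
  structure(list(
    h1 = hypothesis(h1)$label, h2 = hypothesis(h2)$label,
    log10_lik1 = l1 / log(10), log10_lik2 = l2 / log(10),
    log10_lr = (l1 - l2) / log(10)
  ), class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("log10 Pr(E|%s) = %.4f\nlog10 Pr(E|%s) = %.4f\nlog10 LR = %.4f\n",
              x$h1, x$log10_lik1, x$h2, x$log10_lik2, x$log10_lr))
  invisible(x)
}
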