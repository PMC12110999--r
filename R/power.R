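# Monte-Carlo likelihood-ratio distributions and power summaries.

#' Sample a likelihood-ratio distribution
#'
#' Simulates `reps` independent genomes under `h_true` (for a composite,
#' the generating relationship is drawn per replicate with the hypothesis
#' weights), scores each genome with the exact likelihood ratio of `h1`
#' versus `h2`, and returns the log10 LR draws. Point masses (e.g.,
#' genomes with no shared segments) are preserved as exactly repeated
#' values, never smoothed.
#'
#' @param h_true generating hypothesis.
#' @param h1,h2 hypotheses being compared.
#' @param map a [genetic_map()] (or `"fixture"` / `"toy"`).
#' @param reps number of genomes.
#' @param seed integer seed (reproducible).
#' @param epsilon forward-algorithm truncation tolerance.
#' @return object of class `lr_samples`: `log10_lr` (length `reps`),
#'   the hypothesis labels, `reps`, `seed`.
#' @export
sample_lr_distribution <- function(h_true, h1, h2, map, reps, seed,
                                   epsilon = 1e-10) {
  stopifnot(reps >= 1)
  h_true <- hypothesis(h_true); h1 <- hypothesis(h1); h2 <- hypothesis(h2)
  map <- as_genetic_map(map)
  k <- length(h_true$components)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  assign_comp <- if (k == 1L) rep(1L, reps) else
    sample.int(k, reps, replace = TRUE, prob = h_true$weights)
  comp_seeds <- sample.int(.Machine$integer.max - 1L, k)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  log10_lr <- numeric(reps)
  for (ci in seq_len(k)) {
    idx <- which(assign_comp == ci)
    if (!length(idx)) next
    batch <- simulate_ibd_genomes(h_true$components[[ci]], map,
                                  reps = length(idx), seed = comp_seeds[ci])
    arr <- loglik_arrays(batch, map)
    l1 <- hypothesis_loglik(h1, arr, epsilon)
    l2 <- hypothesis_loglik(h2, arr, epsilon)
    log10_lr[idx] <- (l1 - l2) / log(10)
  }
  structure(list(log10_lr = log10_lr, truth = h_true$label,
                 h1 = h1$label, h2 = h2$label,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "lr_samples")
}

#' @export
print.lr_samples <- function(x, ...) {
  cat(sprintf("<lr_samples> %d draws of log10 LR(%s vs %s), truth %s\n",
              x$reps, x$h1, x$h2, x$truth))
  print(summary(x$log10_lr))
  invisible(x)
}

#' Summarise the power to distinguish two hypotheses
#'
#' Rates of misleading evidence `Pr(LR > 1 | H2)` and `Pr(LR < 1 | H1)`,
#' median log10 LR under each truth, `Pr(LR = 1)` (reported explicitly:
#' identical-law pairs make this mass non-negligible), and the accuracy
#' of the classifier that assigns H1 when `LR >= 1` under equal priors:
#' `accuracy = (Pr(LR >= 1 | H1) + Pr(LR < 1 | H2)) / 2`. Binomial
#' standard errors accompany all rates.
#'
#' @param s1 [sample_lr_distribution()] draws generated under H1.
#' @param s2 draws generated under H2 (same hypothesis pair).
#' @return a list of class `power_summary`.
#' @export
summarize_power <- function(s1, s2) {
  stopifnot(inherits(s1, "lr_samples"), inherits(s2, "lr_samples"))
  if (!identical(s1$h1, s2$h1) || !identical(s1$h2, s2$h2)) {
    validation_error("the two sample sets compare different hypothesis pairs")
  }
  if (!identical(s1$truth, s1$h1) || !identical(s2$truth, s2$h2)) {
    validation_error("s1 must be generated under H1 and s2 under H2")
  }
  rate <- function(x, n) list(p = x, se = sqrt(x * (1 - x) / n))
  x1 <- s1$log10_lr; x2 <- s2$log10_lr
  acc <- (mean(x1 >= 0) + mean(x2 < 0)) / 2
  structure(list(
    h1 = s1$h1, h2 = s1$h2, n1 = s1$reps, n2 = s2$reps,
    pr_gt1_h1 = rate(mean(x1 > 0), s1$reps),
    pr_lt1_h1 = rate(mean(x1 < 0), s1$reps),
    pr_eq1_h1 = rate(mean(x1 == 0), s1$reps),
    pr_gt1_h2 = rate(mean(x2 > 0), s2$reps),
    pr_lt1_h2 = rate(mean(x2 < 0), s2$reps),
    pr_eq1_h2 = rate(mean(x2 == 0), s2$reps),
    median_log10_lr_h1 = stats::median(x1),
    median_log10_lr_h2 = stats::median(x2),
    accuracy = acc,
    accuracy_se = sqrt(stats::var(x1 >= 0) / s1$reps +
                       stats::var(x2 < 0) / s2$reps) / 2
  ), class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("H1 = %s vs H2 = %s (n1 = %d, n2 = %d)\n",
              x$h1, x$h2, x$n1, x$n2))
  cat(sprintf("  H1 true: Pr(LR>1) = %.4f  Pr(LR<1) = %.4f  median log10 LR = %.4f\n",
              x$pr_gt1_h1$p, x$pr_lt1_h1$p, x$median_log10_lr_h1))
  cat(sprintf("  H2 true: Pr(LR>1) = %.4f  Pr(LR<1) = %.4f  median log10 LR = %.4f\n",
              x$pr_gt1_h2$p, x$pr_lt1_h2$p, x$median_log10_lr_h2))
  cat(sprintf("  accuracy = %.4f (se %.4f)\n", x$accuracy, x$accuracy_se))
  invisible(x)
}

#' Pairwise power study
#'
#' Convenience wrapper: samples LR distributions under both hypotheses
#' and summarises them.
#'
#' @inheritParams sample_lr_distribution
#' @return a `power_summary`.
#' @export
power_study <- function(h1, h2, map, reps, seed, epsilon = 1e-10) {
  s1 <- sample_lr_distribution(h1, h1, h2, map, reps, seed, epsilon)
  s2 <- sample_lr_distribution(h2, h1, h2, map, reps, seed + 1L, epsilon)
  summarize_power(s1, s2)
}

#' One-vs-rest power study
#'
#' For each relationship `R` in a set, compares `H1: R` against the
#' equal-weight composite of the other relationships; H2-true genomes
#' draw their generating relationship uniformly from the complement per
#' replicate.
#'
#' @param relationships character vector (or list of pedigrees), length
#'   >= 2.
#' @inheritParams sample_lr_distribution
#' @return named list of `power_summary`, one per relationship.
#' @export
one_vs_rest_study <- function(relationships, map, reps, seed,
                              epsilon = 1e-10) {
  if (length(relationships) < 2L) {
    stop("need at least two relationships for a one-vs-rest study")
  }
  peds <- lapply(relationships, as_ibd_pedigree)
  labels <- vapply(peds, function(p) p$label, character(1))
  out <- vector("list", length(peds))
  names(out) <- labels
  for (i in seq_along(peds)) {
    h1 <- hypothesis(peds[[i]])
    h2 <- hypothesis(peds[-i])
    s1 <- sample_lr_distribution(h1, h1, h2, map, reps,
                                 seed + 2L * (i - 1L), epsilon)
    s2 <- sample_lr_distribution(h2, h1, h2, map, reps,
                                 seed + 2L * i - 1L, epsilon)
    out[[i]] <- summarize_power(s1, s2)
  }
  out
}
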