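# Exact (non-simulation) statistics of the continuous IBD process.

#' Two-locus IBD probability
#'
#' Probability that both of two loci separated by `d` cM are IBD1. Each
#' meiosis bit evolves as an independent two-state chain with switch rate
#' 0.01 per cM each way, so the transition kernel over distance `d`
#' factorises per bit: same-bit probability `(1 + exp(-0.02 d)) / 2`.
#' `kappa11(0) = kappa1` and `kappa11(d) -> kappa1^2` as `d -> Inf`.
#'
#' @param ped pedigree (or abbreviation).
#' @param d genetic distance(s) in cM, `>= 0`.
#' @return numeric vector of probabilities.
#' @export
two_locus_kappa11 <- function(ped, d) {
  stopifnot(all(d >= 0))
  a <- kappa11_coefficients(as_ibd_pedigree(ped))
  vapply(d, function(di) sum(a * exp(-0.02 * di * (seq_along(a) - 1))),
         numeric(1))
}

# kappa11(d) = sum_k a_k exp(-0.02 k d): expand
# (1/nv) sum_h c_h ((1+x)/2)^(r-h) ((1-x)/2)^h in powers of x = e^(-0.02d),
# where c_h counts ordered V1 x V1 pairs at Hamming distance h.
kappa11_coefficients <- function(ped) {
  mod <- ibd_model(ped)
  if (!is.null(ped$cache$kappa11_coef)) return(ped$cache$kappa11_coef)
  v1 <- which(mod$ibd1) - 1L
  if (length(v1)^2 > 5e7) {
    capacity_error("too many IBD1 states for the two-locus tabulation")
  }
  ch <- cpp_hamming_counts(v1, mod$nbits)
  r <- mod$nbits
  a <- numeric(r + 1)
  for (h in 0:r) {
    if (ch[h + 1] == 0) next
    p1 <- choose(r - h, 0:(r - h))              # (1+x)^(r-h)
    p2 <- choose(h, 0:h) * (-1)^(0:h)           # (1-x)^h
    conv <- rep(0, r + 1)
    for (i in seq_along(p1)) {
      idx <- (i - 1) + seq_along(p2)
      conv[idx] <- conv[idx] + p1[i] * p2
    }
    a <- a + ch[h + 1] * conv
  }
  a <- a / (mod$nv * 2^r)
  ped$cache$kappa11_coef <- a
  a
}

#' Moments of total IBD, segment count, and no-sharing probabilities
#'
#' Exact summary statistics of the continuous IBD process on a genetic
#' map:
#' * `E(T) = kappa1 * L` per chromosome, and
#'   `E(T^2) = 2 * integral_0^L (L - d) kappa11(d) dd`, evaluated in
#'   closed form from the exponential-mixture expansion of `kappa11`;
#' * expected IBD1 segment count
#'   `n_chrom * kappa1 + flux * L_total`, where `flux` is the stationary
#'   IBD0 -> IBD1 up-crossing intensity per cM;
#' * `Pr(T = 0)` per chromosome by the uniformized forward algorithm,
#'   combined across independent chromosomes into `Pr(T+ = 0)` and the
#'   moments of `N0`, the number of chromosomes without IBD.
#'
#' @param ped pedigree (or abbreviation).
#' @param map a [genetic_map()] (or `"fixture"` / `"toy"`).
#' @param epsilon truncation tolerance of the forward algorithm.
#' @return a list of class `total_ibd_moments`.
#' @examples
#' m <- total_ibd_moments("GP", "fixture")
#' m$expected_total   # 1695.68
#' @export
total_ibd_moments <- function(ped, map, epsilon = 1e-10) {
  ped <- as_ibd_pedigree(ped)
  map <- as_genetic_map(map)
  k1 <- identity_coefficients(ped)$k1
  a <- kappa11_coefficients(ped)
  L <- map$length_cM
  e_t <- k1 * L
  var_t <- vapply(L, function(l) {
    g <- vapply(seq_along(a) - 1, function(k) {
      if (k == 0) l^2 / 2
      else {
        c <- 0.02 * k
        l / c - (1 - exp(-c * l)) / c^2
      }
    }, numeric(1))
    2 * sum(a * g) - (k1 * l)^2
  }, numeric(1))
  p0 <- vapply(L, function(l) pr_no_ibd(ped, l, epsilon = epsilon),
               numeric(1))
  structure(list(
    kappa1 = k1,
    map = map,
    expected_total = k1 * sum(L),
    sd_total = sqrt(sum(var_t)),
    per_chromosome = data.frame(chromosome = map$chromosome,
                                length_cM = L, expected = e_t,
                                variance = var_t, pr_no_ibd = p0),
    expected_segments = expected_segment_count(ped, map),
    pr_no_ibd_genome = prod(p0),
    n0_mean = sum(p0),
    n0_sd = sqrt(sum(p0 * (1 - p0)))
  ), class = "total_ibd_moments")
}

#' @export
print.total_ibd_moments <- function(x, ...) {
  cat(sprintf(
    "kappa1 = %g\nE(T+) = %.2f cM, SD(T+) = %.2f cM\nE(segments) = %.2f\nPr(T+=0) = %.4g\nN0: mean %.2f, sd %.2f\n",
    x$kappa1, x$expected_total, x$sd_total, x$expected_segments,
    x$pr_no_ibd_genome, x$n0_mean, x$n0_sd))
  invisible(x)
}

#' Expected number of IBD1 segments on a map
#'
#' Stationary up-crossing argument: each chromosome starts IBD1 with
#' probability kappa1, and new IBD1 segments open at the stationary
#' IBD0 -> IBD1 crossing intensity
#' `flux = 0.01 * #\{Hamming-1 pairs V0 -> V1\} / nv` per cM.
#'
#' @inheritParams total_ibd_moments
#' @return the expected genome-wide IBD1 segment count.
#' @export
expected_segment_count <- function(ped, map) {
  ped <- as_ibd_pedigree(ped)
  map <- as_genetic_map(map)
  mod <- ibd_model(ped)
  k1 <- sum(mod$ibd1) / mod$nv
  flux <- 0.01 * cpp_crossing_pairs(mod$ibd1, mod$nbits) / mod$nv
  nrow(map) * k1 + flux * sum(map$length_cM)
}

#' Probability of no IBD on a chromosome
#'
#' `Pr(T = 0)`: the probability that the pair shares no DNA anywhere on a
#' chromosome of length `L` cM, computed by the Poisson-conditioned
#' forward algorithm restricted to the IBD0 states (truncation error at
#' most `epsilon`).
#'
#' @param ped pedigree (or abbreviation).
#' @param L chromosome length in cM (`>= 0`).
#' @param epsilon truncation tolerance.
#' @return a probability; equals kappa0 at `L = 0`.
#' @export
pr_no_ibd <- function(ped, L, epsilon = 1e-10) {
  ped <- as_ibd_pedigree(ped)
  stopifnot(length(L) == 1L, L >= 0)
  mod <- ibd_model(ped)
  if (L == 0) return(sum(!mod$ibd1 & !mod$ibd2) / mod$nv)
  ll <- cpp_loglik_many(mod$ibd1, mod$nbits,
                        rep_off = c(0L, 1L), seg_chrom = 1L,
                        seg_len = L, seg_state = 0L, eps = epsilon)
  exp(ll[1])
}

#' Monte-Carlo dispersion of the genome-wide segment count
#'
#' The standard deviation of the IBD1 segment count has no simple closed
#' form; it is estimated by simulating whole genomes, with a reported
#' (normal-approximation) standard error of the estimate.
#'
#' @inheritParams total_ibd_moments
#' @param reps number of simulated genomes (>= 1000).
#' @param seed RNG seed.
#' @return list with `sd`, `se`, `mean`, `reps`.
#' @export
segment_count_dispersion <- function(ped, map, reps = 10000L, seed = 1L) {
  stopifnot(reps >= 1000L)
  sim <- simulate_ibd_summary(ped, map, reps, seed)
  s <- stats::sd(sim$nseg)
  list(sd = s, se = s / sqrt(2 * (reps - 1)), mean = mean(sim$nseg),
       reps = as.integer(reps))
}

#' Genome-level simulation summaries
#'
#' Simulates `reps` genomes and returns only the per-genome IBD1 segment
#' count and total IBD length (no segment storage), using the same
#' per-chromosome RNG substream scheme as [simulate_ibd_genomes()].
#'
#' @inheritParams segment_count_dispersion
#' @return data frame with columns `nseg`, `total`.
#' @export
simulate_ibd_summary <- function(ped, map, reps, seed) {
  ped <- as_ibd_pedigree(ped)
  map <- as_genetic_map(map)
  mod <- ibd_model(ped)
  nseg <- integer(reps); total <- numeric(reps)
  seeds <- chromosome_seeds(seed, nrow(map))
  for (i in seq_len(nrow(map))) {
    set.seed(seeds[i])
    res <- cpp_sim_summary(mod$ibd1, mod$nbits, map$length_cM[i],
                           as.integer(reps))
    nseg <- nseg + res$nseg
    total <- total + res$total
  }
  data.frame(nseg = nseg, total = total)
}
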