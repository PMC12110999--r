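# The continuous-time Markov chain on IBD vectors and its simulation.

#' Transition intensity between IBD vector states
#'
#' Under Haldane's model each of the `2 * nnf` meioses recombines at 0.01
#' crossovers per cM, so the full IBD vector jumps between integer states
#' at rate 0.01 per cM for every Hamming-1 neighbour pair; the diagonal
#' makes rows sum to zero.
#'
#' @param a,b integer states in `[0, 2^(2*nnf))`.
#' @param nnf number of non-founders.
#' @return the intensity in per-cM units.
#' @export
transition_intensity <- function(a, b, nnf) {
  nv <- 2^(2L * nnf)
  if (any(a < 0 | a >= nv) || any(b < 0 | b >= nv)) {
    stop("state out of range [0, ", nv, ")")
  }
  h <- popcount(bitwXor(as.integer(a), as.integer(b)))
  ifelse(a == b, -0.01 * 2 * nnf, ifelse(h == 1L, 0.01, 0))
}

popcount <- function(x) {
  n <- integer(length(x))
  x <- as.integer(x)
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Uniformization plan for a chromosome
#'
#' Represents the IBD-vector chain over a chromosome of length `L` cM as a
#' Poisson number of crossovers, `N ~ Poisson(0.01 * L * 2 * nnf)`, each
#' applying the one-step kernel (a uniformly chosen meiosis flips). The
#' Poisson sum is truncated at the smallest `kmax` leaving upper-tail mass
#' at most `epsilon`.
#'
#' @param ped pedigree (or abbreviation).
#' @param L chromosome length in cM.
#' @param epsilon truncation tolerance (default `1e-10`).
#' @return a list of class `uniformization_plan`.
#' @export
uniformization_plan <- function(ped, L, epsilon = 1e-10) {
  ped <- as_ibd_pedigree(ped)
  stopifnot(L >= 0, epsilon > 0, epsilon < 1)
  nmeio <- 2L * ped$nnf
  lambda <- 0.01 * L * nmeio
  structure(list(nnf = ped$nnf, nmeioses = nmeio, L = L,
                 lambda_total = lambda, epsilon = epsilon,
                 kmax = stats::qpois(1 - epsilon, lambda)),
            class = "uniformization_plan")
}

#' One-step crossover kernel
#'
#' The discrete kernel applied at each uniformized crossover: probability
#' `1 / (2 * nnf)` of moving to each Hamming-1 neighbour of the full IBD
#' vector (one uniformly chosen meiosis flips), zero elsewhere.
#'
#' @param plan a [uniformization_plan()].
#' @return a dense `2^(2*nnf) x 2^(2*nnf)` stochastic matrix.
#' @export
one_step_kernel <- function(plan) {
  stopifnot(inherits(plan, "uniformization_plan"))
  nb <- plan$nmeioses
  if (nb > 12L) {
    capacity_error("dense one-step kernel limited to 12 meioses (4096 states)")
  }
  nv <- 2^nb
  P <- matrix(0, nv, nv)
  states <- seq_len(nv) - 1L
  for (j in seq_len(nb) - 1L) {
    nb_states <- bitwXor(states, bitwShiftL(1L, j))
    P[cbind(states + 1L, nb_states + 1L)] <- 1 / nb
  }
  P
}

# Deterministic per-chromosome RNG substreams: a genome seed expands into
# one sub-seed per chromosome so chromosome i is reproducible in
# isolation.
chromosome_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate continuously observed IBD segments
#'
#' Simulates the continuous IBD process for the pedigree pair along a
#' genetic map: per chromosome the IBD vector starts uniform, a uniformly
#' chosen meiosis flips at exponential inter-arrival times (total rate
#' 0.01 per cM per meiosis), and the observed IBD state is recorded as
#' alternating half-open segments tiling `[0, L)`. Chromosomes are
#' independent, with per-chromosome RNG substreams derived from `seed`.
#'
#' Only the meioses that can affect the pair's IBD state are simulated;
#' the law of the observed process is identical to flipping all
#' `2 * nnf` bits.
#'
#' @param ped pedigree (or abbreviation).
#' @param map a [genetic_map()] (or `"fixture"` / `"toy"`).
#' @param seed integer seed; the same seed reproduces the identical
#'   segment set.
#' @return an `ibd_segments` data frame with columns `chromosome`,
#'   `start_cM`, `end_cM`, `ibd_state`.
#' @examples
#' sim <- simulate_ibd("1C", "toy", seed = 1)
#' @export
simulate_ibd <- function(ped, map, seed) {
  sims <- simulate_ibd_genomes(ped, map, reps = 1L, seed = seed)
  segments_from_batch(sims, rep_index = 1L)
}

#' Simulate many genomes at once
#'
#' Batch version of [simulate_ibd()]: `reps` independent genomes. Genome
#' `g` of a batch uses the same per-chromosome substreams for every
#' `reps >= g`, so the first genome of any batch equals
#' `simulate_ibd(ped, map, seed)`.
#'
#' @inheritParams simulate_ibd
#' @param reps number of genomes.
#' @return a list of class `ibd_sim_batch` with the segment arrays
#'   (sorted by replicate, then chromosome), the map and `reps`.
#' @export
simulate_ibd_genomes <- function(ped, map, reps, seed) {
  ped <- as_ibd_pedigree(ped)
  map <- as_genetic_map(map)
  mod <- ibd_model(ped)
  seeds <- chromosome_seeds(seed, nrow(map))
  parts <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    set.seed(seeds[i])
    res <- cpp_sim_segments(mod$ibd1, mod$nbits, map$length_cM[i],
                            as.integer(reps))
    parts[[i]] <- data.frame(rep = res$rep, chromosome_idx = i,
                             start_cM = res$start, end_cM = res$end,
                             ibd_state = res$state)
  }
  segs <- do.call(rbind, parts)
  ord <- order(segs$rep, segs$chromosome_idx, method = "radix")
  segs <- segs[ord, , drop = FALSE]
  structure(list(segments = segs, map = map, reps = as.integer(reps),
                 seed = seed, label = ped$label),
            class = "ibd_sim_batch")
}

# Extract one replicate of a batch as an ibd_segments object.
segments_from_batch <- function(batch, rep_index) {
  stopifnot(inherits(batch, "ibd_sim_batch"))
  s <- batch$segments[batch$segments$rep == rep_index, , drop = FALSE]
  ibd_segments(data.frame(
    chromosome = batch$map$chromosome[s$chromosome_idx],
    start_cM = s$start_cM, end_cM = s$end_cM, ibd_state = s$ibd_state,
    stringsAsFactors = FALSE), map = batch$map)
}

#' IBD segment sets
#'
#' An `ibd_segments` object is a data frame with columns `chromosome`,
#' `start_cM`, `end_cM`, `ibd_state` whose rows tile each chromosome of a
#' genetic map with half-open `[start, end)` segments: the first segment
#' starts at 0, consecutive segments are contiguous, the last ends at the
#' chromosome length, and adjacent segments have different states.
#'
#' @param df data frame with the four columns above.
#' @param map the [genetic_map()] the segments refer to; if `NULL` the
#'   chromosome lengths are taken from the last `end_cM` per chromosome.
#' @param tol numeric tolerance for tiling checks (cM).
#' @return a validated `ibd_segments` object.
#' @export
ibd_segments <- function(df, map = NULL, tol = 1e-6) {
  need <- c("chromosome", "start_cM", "end_cM", "ibd_state")
  if (!all(need %in% names(df))) {
    validation_error(paste("segment table needs columns:",
                           paste(need, collapse = ", ")))
  }
  df$chromosome <- as.character(df$chromosome)
  if (nrow(df)) {
    if (!all(df$ibd_state %in% c(0L, 1L))) {
      validation_error("ibd_state must be 0 or 1")
    }
    if (is.null(map)) {
      lens <- tapply(df$end_cM, df$chromosome, max)
      map <- genetic_map(as.numeric(lens), names(lens))
    } else {
      map <- as_genetic_map(map)
      if (!all(df$chromosome %in% map$chromosome)) {
        validation_error("segments refer to chromosomes absent from the map")
      }
    }
    for (chr in unique(df$chromosome)) {
      s <- df[df$chromosome == chr, , drop = FALSE]
      s <- s[order(s$start_cM), , drop = FALSE]
      L <- map$length_cM[match(chr, map$chromosome)]
      if (abs(s$start_cM[1]) > tol) {
        validation_error(paste0("chromosome ", chr,
                                ": first segment must start at 0"))
      }
      if (nrow(s) > 1L) {
        gaps <- s$start_cM[-1] - s$end_cM[-nrow(s)]
        if (any(abs(gaps) > tol)) {
          i <- which(abs(gaps) > tol)[1]
          validation_error(sprintf(
            "chromosome %s: gap/overlap of %.6g cM between segments ending %.6g and starting %.6g",
            chr, gaps[i], s$end_cM[i], s$start_cM[i + 1]))
        }
        if (any(diff(s$ibd_state) == 0L)) {
          validation_error(paste0("chromosome ", chr,
                                  ": adjacent segments must alternate IBD state"))
        }
      }
      if (abs(s$end_cM[nrow(s)] - L) > tol) {
        validation_error(sprintf(
          "chromosome %s: last segment ends at %.6g but the chromosome is %.6g cM",
          chr, s$end_cM[nrow(s)], L))
      }
      if (any(s$end_cM - s$start_cM <= 0)) {
        validation_error(paste0("chromosome ", chr,
                                ": segments must have positive length"))
      }
    }
  } else if (is.null(map)) {
    map <- genetic_map(numeric(0), character(0))
  }
  structure(df, map = map, class = c("ibd_segments", "data.frame"))
}

#' Total IBD and segment count of a segment set
#'
#' @param segs an [ibd_segments()] object.
#' @return list with `total_ibd` (cM of IBD1) and `n_segments` (number of
#'   IBD1 segments).
#' @export
segment_summary <- function(segs) {
  ibd <- segs$ibd_state == 1L
  list(total_ibd = sum((segs$end_cM - segs$start_cM)[ibd]),
       n_segments = sum(ibd))
}
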