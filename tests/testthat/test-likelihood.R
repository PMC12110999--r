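test_that("single-segment likelihoods match closed forms", {
  for (L in c(30, 100, 250)) {
    # GP chromosome fully IBD1: log(1/2) - 0.01 L
    expect_equal(segment_loglikelihood("GP", make_segs(c(0, L), 1, L)),
                 log(0.5) - 0.01 * L, tolerance = 1e-9)
    # fully IBD0 reduces exactly to pr_no_ibd
    for (abbr in c("GP", "1C", "2C")) {
      expect_equal(segment_loglikelihood(abbr, make_segs(c(0, L), 0, L)),
                   log(pr_no_ibd(relationship(abbr), L)), tolerance = 1e-9)
    }
  }
})

test_that("multi-segment likelihoods match the telegraph closed forms", {
  # For GP the observed process is a two-state chain with switch rate
  # 0.01 both ways; for HS the rate is 0.02. A pattern with n segments
  # has density  P(x1) * rate^(n-1) * exp(-rate * L).
  cases <- list(GP = 0.01, HS = 0.02)
  bounds <- c(0, 12.5, 40, 77.25, 100)
  for (abbr in names(cases)) {
    r <- cases[[abbr]]
    for (x1 in 0:1) {
      states <- rep(c(x1, 1 - x1), length.out = 4)
      ll <- segment_loglikelihood(abbr, make_segs(bounds, states, 100))
      expect_equal(ll, log(0.5) + 3 * log(r) - r * 100, tolerance = 1e-9)
    }
  }
})

test_that("reduced state space reproduces the full 2*nnf-bit forward pass", {
  for (abbr in c("GP", "HS", "N", "1C")) {
    ped <- relationship(abbr)
    nm <- 2L * ped$nnf
    full_lookup <- vapply(seq_len(2^nm) - 1L, function(s) {
      ibd_state(ped, as.integer(intToBits(s))[seq_len(nm)]) == 1L
    }, logical(1))
    segs <- simulate_ibd(ped, toy_map, seed = 41)
    ll_red <- segment_loglikelihood(ped, segs)
    arr <- contibd:::loglik_arrays(segs, toy_map)
    ll_full <- contibd:::cpp_loglik_many(full_lookup, nm,
                                         as.integer(arr$rep_off),
                                         arr$seg_chrom, arr$seg_len,
                                         arr$seg_state, 1e-10)[1]
    expect_equal(ll_red, ll_full, tolerance = 1e-9)
  }
})

test_that("interior-boundary density agrees with simulated frequencies", {
  # 1C on one 100 cM chromosome: P(IBD1 from 0 with a single switch in
  # [20, 80]) = integral of the two-segment density over the breakpoint,
  # compared with the empirical frequency of that pattern
  grid <- seq(20, 80, length.out = 61)
  dens <- vapply(grid, function(t) {
    exp(segment_loglikelihood("1C", make_segs(c(0, t, 100), c(1, 0), 100)))
  }, numeric(1))
  h <- diff(grid)[1]
  p_exact <- sum((dens[-1] + dens[-length(dens)]) / 2) * h
  batch <- simulate_ibd_genomes("1C", chrom_map(100), reps = 200000,
                                seed = 47)
  s <- batch$segments
  nseg <- tabulate(s$rep, batch$reps)
  two <- which(nseg == 2L)
  first <- s[s$start_cM == 0, ]
  hit <- first$rep %in% two & first$ibd_state == 1L &
    first$end_cM >= 20 & first$end_cM <= 80
  phat <- sum(hit) / batch$reps
  se <- sqrt(p_exact * (1 - p_exact) / batch$reps)
  expect_lt(abs(phat - p_exact), 3.3 * se)
})

test_that("log-likelihoods add over chromosomes", {
  segs <- simulate_ibd("GGP", toy_map, seed = 53)
  ll <- segment_loglikelihood("GGP", segs)
  parts <- vapply(unique(segs$chromosome), function(chr) {
    s <- as.data.frame(segs)[segs$chromosome == chr, ]
    L <- toy_map$length_cM[match(chr, toy_map$chromosome)]
    segment_loglikelihood("GGP", ibd_segments(s, map = genetic_map(L, chr)))
  }, numeric(1))
  expect_equal(ll, sum(parts), tolerance = 1e-12)
})

test_that("impossible observations are flagged with -Inf", {
  pc <- ibd_pedigree(c("p", "q", "c"), c(NA, NA, "p"), c(NA, NA, "q"),
                     pair = c("p", "c"))
  expect_identical(segment_loglikelihood(pc, make_segs(c(0, 50), 0, 50)),
                   -Inf)
  expect_error(likelihood_ratio(make_segs(c(0, 50), 0, 50), pc, pc),
               "undefined")
})

test_that("likelihood ratios: identity, antisymmetry, composite mixing", {
  segs <- simulate_ibd("GP", toy_map, seed = 59)
  expect_equal(likelihood_ratio(segs, "GP", "GP")$log10_lr, 0)
  a <- likelihood_ratio(segs, "GP", "N")
  b <- likelihood_ratio(segs, "N", "GP")
  expect_equal(a$log10_lr, -b$log10_lr)
  # composite = weighted genome-level mixture, by direct recomputation
  comp <- likelihood_ratio(segs, "HS", hypothesis(c("GP", "N")))
  lHS <- segment_loglikelihood("HS", segs)
  lGP <- segment_loglikelihood("GP", segs)
  lN <- segment_loglikelihood("N", segs)
  mix <- log(0.5 * exp(lGP) + 0.5 * exp(lN))
  expect_equal(comp$log10_lr, (lHS - mix) / log(10), tolerance = 1e-9)
})

test_that("2C vs 1C2R likelihood ratio is exactly 1 on every genome", {
  for (seed in 1:6) {
    segs <- simulate_ibd("2C", toy_map, seed = seed)
    lr <- likelihood_ratio(segs, "2C", "1C2R")
    expect_lt(abs(lr$log10_lr), 1e-9)
  }
})

test_that("zero-sharing genomes reduce to products of pr_no_ibd", {
  df <- do.call(rbind, lapply(seq_len(nrow(toy_map)), function(i) {
    data.frame(chromosome = toy_map$chromosome[i], start_cM = 0,
               end_cM = toy_map$length_cM[i], ibd_state = 0L)
  }))
  segs <- ibd_segments(df, map = toy_map)
  lr <- likelihood_ratio(segs, "5C", "1C")
  expected <- sum(log10(vapply(toy_map$length_cM, function(L)
    pr_no_ibd("5C", L), numeric(1)))) -
    sum(log10(vapply(toy_map$length_cM, function(L)
      pr_no_ibd("1C", L), numeric(1))))
  expect_equal(lr$log10_lr, expected, tolerance = 1e-9)
})

test_that("halving epsilon leaves log10 LRs unchanged to 1e-6", {
  batch <- simulate_ibd_genomes("GP", fixture_map, reps = 50, seed = 61)
  arr <- contibd:::loglik_arrays(batch, fixture_map)
  for (abbr in c("GP", "GGP")) {
    l1 <- contibd:::loglik_batch(abbr, arr, 1e-10)
    l2 <- contibd:::loglik_batch(abbr, arr, 5e-11)
    expect_lt(max(abs(l1 - l2)) / log(10), 1e-6)
  }
})

test_that("E[LR | H2] = 1 (likelihood-ratio calibration)", {
  batch <- simulate_ibd_genomes("GGP", toy_map, reps = 20000, seed = 67)
  arr <- contibd:::loglik_arrays(batch, toy_map)
  lr <- exp(contibd:::loglik_batch("GP", arr, 1e-10) -
            contibd:::loglik_batch("GGP", arr, 1e-10))
  se <- stats::sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr) - 1), 4 * se)
})
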