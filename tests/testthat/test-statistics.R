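test_that("identity coefficients are exact for named relationships", {
  k <- identity_coefficients("GP")
  expect_identical(k$k1, 0.5)
  expect_identical(k$k2, 0)
  expect_identical(identity_coefficients("5C")$k1, 1 / 1024)
  pc <- ibd_pedigree(c("p", "q", "c"), c(NA, NA, "p"), c(NA, NA, "q"),
                     pair = c("p", "c"))
  expect_identical(identity_coefficients(pc)$k1, 1)
  expect_equal(k$k0 + k$k1 + k$k2, 1)
})

test_that("state spaces beyond the capacity limit raise a capacity error", {
  withr::local_options(contibd.max_bits = 8L)
  expect_error(identity_coefficients("5C"),
               class = "contibd_capacity_error")
})

test_that("two-locus kappa11 has the right limits and shape", {
  for (abbr in c("GP", "HS", "N", "1C", "3C")) {
    ped <- relationship(abbr)
    k1 <- identity_coefficients(ped)$k1
    expect_equal(two_locus_kappa11(ped, 0), k1)
    expect_lt(abs(two_locus_kappa11(ped, 1e4) - k1^2), 1e-9)
    d <- seq(0, 300, by = 10)
    expect_true(all(diff(two_locus_kappa11(ped, d)) <= 1e-12))
  }
  # GP closed form for the symmetric two-state reduction
  d <- c(1, 10, 50, 200)
  expect_equal(two_locus_kappa11("GP", d), 0.25 * (1 + exp(-0.02 * d)))
})

test_that("total IBD moments: expectation exact, variance cross-checked", {
  m <- total_ibd_moments("1C", fixture_map)
  expect_equal(m$expected_total, 0.25 * 3391.36)
  # GP single chromosome L = 100: analytic Var from the closed-form kappa11
  v <- total_ibd_moments("GP", chrom_map(100))$per_chromosome$variance
  expect_equal(v, 25 * 100 - 1250 * (1 - exp(-2)), tolerance = 1e-10)
  # 1-D reduction agrees with quadrature of the two-locus probability
  for (abbr in c("GP", "1C")) {
    L <- 50
    ped <- relationship(abbr)
    k1 <- identity_coefficients(ped)$k1
    et2 <- 2 * stats::integrate(function(d) (L - d) * two_locus_kappa11(ped, d),
                                0, L, rel.tol = 1e-12)$value
    v1 <- total_ibd_moments(ped, chrom_map(L))$per_chromosome$variance
    expect_equal(v1, et2 - (k1 * L)^2, tolerance = 1e-8)
  }
  # Monte-Carlo agreement, 3-SE band
  sim <- simulate_ibd_summary("GP", chrom_map(100), reps = 100000, seed = 5)
  vhat <- stats::var(sim$total)
  se <- stats::sd((sim$total - mean(sim$total))^2) / sqrt(nrow(sim))
  expect_lt(abs(vhat - (25 * 100 - 1250 * (1 - exp(-2)))), 3 * se)
})

test_that("expected segment counts match the up-crossing flux formula", {
  pc <- ibd_pedigree(c("p", "q", "c"), c(NA, NA, "p"), c(NA, NA, "q"),
                     pair = c("p", "c"))
  expect_equal(expected_segment_count(pc, fixture_map), 22)
  # simulation agreement for a spread of relationships (3-SE bands)
  for (abbr in c("GP", "HS", "N", "GGP", "1C")) {
    ec <- expected_segment_count(abbr, fixture_map)
    sim <- simulate_ibd_summary(abbr, fixture_map, reps = 20000, seed = 7)
    se <- stats::sd(sim$nseg) / sqrt(nrow(sim))
    expect_lt(abs(mean(sim$nseg) - ec), 3.3 * se)
    # single-point IBD frequency matches kappa1 too
    k1 <- identity_coefficients(abbr)$k1
    se_t <- stats::sd(sim$total) / sqrt(nrow(sim)) / 3391.36
    expect_lt(abs(mean(sim$total) / 3391.36 - k1), 3.3 * se_t)
  }
})

test_that("equal-kappa1 relationships differ in the printed order", {
  # GP < HS < N for segment counts; SD of total IBD decreases GP > HS > N
  counts <- vapply(c("GP", "HS", "N"), expected_segment_count,
                   numeric(1), map = fixture_map)
  expect_true(all(diff(counts) > 0))
  sds <- vapply(c("GP", "HS", "N"),
                function(r) total_ibd_moments(r, fixture_map)$sd_total,
                numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_equal(unname(vapply(c("GP", "HS", "N"),
                             function(r) total_ibd_moments(r, fixture_map)$expected_total,
                             numeric(1))),
               rep(1695.68, 3))
})

test_that("pr_no_ibd: limits, closed form, monotonicity, crude bound", {
  expect_equal(pr_no_ibd("GP", 0), 0.5)          # kappa0 at L = 0
  for (L in c(10, 60, 150)) {
    expect_equal(pr_no_ibd("GP", L), 0.5 * exp(-0.01 * L), tolerance = 1e-9)
  }
  p <- vapply(c(0, 5, 20, 50, 100, 200), function(L) pr_no_ibd("1C", L),
              numeric(1))
  expect_true(all(diff(p) < 0))
  # crude path bound: never below kappa0 * exp(-0.01 * 2 * nnf * L)
  nnf <- relationship("1C")$nnf
  k0 <- identity_coefficients("1C")$k0
  for (L in c(5, 50, 150)) {
    expect_gte(pr_no_ibd("1C", L), k0 * exp(-0.01 * 2 * nnf * L))
  }
})

test_that("pr_no_ibd agrees with Monte-Carlo frequency (1C, L = 100)", {
  sim <- simulate_ibd_summary("1C", chrom_map(100), reps = 100000, seed = 13)
  phat <- mean(sim$nseg == 0)
  p <- pr_no_ibd("1C", 100)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nrow(sim)))
})

test_that("genome no-sharing summaries combine independent chromosomes", {
  m <- total_ibd_moments("4C", toy_map)
  p <- m$per_chromosome$pr_no_ibd
  expect_equal(m$pr_no_ibd_genome, prod(p))
  expect_equal(m$n0_mean, sum(p))
  expect_equal(m$n0_sd, sqrt(sum(p * (1 - p))))
})

test_that("segment count dispersion is estimated with a standard error", {
  d <- segment_count_dispersion("GP", fixture_map, reps = 2000, seed = 3)
  expect_gt(d$sd, 0)
  expect_lt(d$se, d$sd)
  expect_error(segment_count_dispersion("GP", fixture_map, reps = 10),
               "reps")
  pc <- ibd_pedigree(c("p", "q", "c"), c(NA, NA, "p"), c(NA, NA, "q"),
                     pair = c("p", "c"))
  expect_equal(segment_count_dispersion(pc, toy_map, reps = 1000,
                                        seed = 1)$sd, 0)
})
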