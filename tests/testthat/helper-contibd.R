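# Shared fixtures: all built in code at test time.

toy_map <- toy_genetic_map()
fixture_map <- default_genetic_map()

# single-chromosome map of length L
chrom_map <- function(L, label = "1") genetic_map(L, label)

# convenience: a validated segment set on one chromosome of length L
make_segs <- function(bounds, states, L, chrom = "1") {
  ibd_segments(data.frame(chromosome = chrom,
                          start_cM = bounds[-length(bounds)],
                          end_cM = bounds[-1],
                          ibd_state = as.integer(states)),
               map = chrom_map(L, chrom))
}

# probability of observing a single constant-state segment over [0, L]
stay_prob <- function(ped, x, L, epsilon = 1e-10) {
  exp(segment_loglikelihood(ped, make_segs(c(0, L), x, L),
                            epsilon = epsilon))
}

# the relationships of the printed summary table, with exact kappa1
table2_relationships <- local({
  rel <- c("GP","HS","N","GGP","HN","GN","1C","G2GP","H1C","G2N","1C1R",
           "G3GP","H1C1R","G3N","2C","G4GP","H2C","G4N","2C1R","G5GP",
           "H2C1R","G5N","3C","G6GP","H3C","G6N","3C1R","G7GP","H3C1R",
           "G7N","4C","G8GP","H4C","G8N","4C1R","G9GP","H4C1R","G9N","5C")
  k1_den <- 2^c(rep(1,3), rep(2,4), rep(3,4), rep(4,4), rep(5,4), rep(6,4),
                rep(7,4), rep(8,4), rep(9,4), rep(10,4))
  data.frame(rel = rel, k1 = 1 / k1_den, stringsAsFactors = FALSE)
})
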