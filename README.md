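# contibd

Continuous identity-by-descent (IBD) models for pedigree relationship
testing.

## The problem

How well can two pedigree relationships — say, first versus second
cousins — be distinguished from genetic data on two people? Dense SNP
panels detect shared IBD segments ever more precisely, so the idealised
limit is *continuously observed IBD*: at every point of the autosomal
genome we know, without error, whether the pair shares a founder
haplotype. The discriminating power achievable in that limit depends only
on the pedigree and the recombination process, and it upper-bounds what
any finite marker panel can achieve. `contibd` implements that limit
exactly, for forensic geneticists, genetic genealogists and statistical
geneticists who need a benchmark for kinship methods.

## The model

For a two-person relationship in a pedigree with `nnf` non-founders, the
hidden state is the inheritance (IBD) vector `V_t` with one bit per
meiosis (2·nnf bits). Under Haldane's model each meiosis recombines as a
Poisson process at λ = 0.01 crossovers per cM, so `V_t` is a
continuous-time Markov chain on `{0,1}^(2·nnf)` with intensity

    q(a,b) = 0.01            if Hamming(a,b) = 1
           = 0               if Hamming(a,b) ≥ 2
           = −0.01·2·nnf     if a = b

The observed process `X_t ∈ {IBD0, IBD1}` is obtained from `V_t` by
dropping founder haplotype labels through the pedigree (relationships
with positive IBD2 probability, e.g. full siblings, are out of scope).
On this hidden Markov model the package computes, exactly:

* identity coefficients κ0, κ1 (exhaustive enumeration, exact fractions);
* two-locus probabilities κ11(d), and E/Var of total IBD
  `T = ∫ 1{X_t = 1} dt` per chromosome and genome-wide;
* expected IBD1 segment counts (stationary up-crossing flux);
* `Pr(T = 0)` and segment-set likelihoods via a Poisson-uniformized
  forward algorithm with truncation error ≤ ε (default 1e-10);
* likelihood ratios `LR = Pr(E|H1)/Pr(E|H2)`, including composite
  hypotheses mixed at the genome level,

and it simulates continuously observed IBD segments to estimate LR
distributions, rates of misleading evidence `Pr(LR>1|H2)`, `Pr(LR<1|H1)`,
and the accuracy of the classifier that assigns H1 when LR ≥ 1.

Exact computations run on a provably sufficient reduced state space (only
meioses that can affect the pair's sharing), which keeps fifth cousins at
2^14 states instead of 2^24.

## Worked example

```r
library(contibd)

identity_coefficients("1C")
#> kappa0 = 0.75  kappa1 = 1/4 (0.25)  kappa2 = 0

total_ibd_moments("1C", "fixture")
#> kappa1 = 0.25
#> E(T+) = 847.84 cM, SD(T+) = 148.61 cM
#> E(segments) = 39.41
#> Pr(T+=0) = 1.148e-21
#> N0: mean 2.96, sd 1.55
```

First cousins are expected to share 847.84 cM in about 39 segments on the
packaged 3391.36 cM map; the chance they share nothing at all is
negligible (~1e-21), and on average ~3 chromosomes carry no IBD. Simulate
a genome of continuously observed IBD and weigh first against second
cousins:

```r
segs <- simulate_ibd("1C", "fixture", seed = 7)
segment_summary(segs)
#> $total_ibd   606.967
#> $n_segments  41

likelihood_ratio(segs, "1C", "2C")
#> log10 Pr(E|1C) = -149.1353
#> log10 Pr(E|2C) = -153.8347
#> log10 LR = 4.6994
```

This genome favours first cousins by a factor of ~10^4.7. A power study
for a relationship with a composite alternative (grandparent versus
half-sibling-or-uncle, all with κ1 = 1/2):

```r
power_study("GP", hypothesis(c("HS", "N")), "fixture", reps = 400, seed = 1)
#> H1 = GP vs H2 = {HS,N} (n1 = 400, n2 = 400)
#>   H1 true: Pr(LR>1) = 0.9925  Pr(LR<1) = 0.0075  median log10 LR = 4.4934
#>   H2 true: Pr(LR>1) = 0.0050  Pr(LR<1) = 0.9950  median log10 LR = -8.5131
#>   accuracy = 0.9938 (se 0.0028)
```

Grandparents separate from the second-degree alternatives over 99% of
the time even though all three relationships share the same expected
total IBD — the extra information is in the segment structure.

## Command line

An installed script `contibd` (see `exec/`) exposes the subcommands
`coeffs`, `moments`, `simulate`, `loglik`, `lr`, `power`:

```sh
contibd simulate --relationship 1C --map fixture --seed 7 --out segs.tsv
contibd lr --segments segs.tsv --h1 1C --h2 2C
contibd power --set GP,HS,N --reps 1000 --seed 1 --out power.tsv
```

Exit codes: 0 success, 2 validation error, 3 capacity error. Runs with
`--out` also write a `<out>.run.json` provenance record.

## Package layout

* `R/`, `src/` — model, exact statistics, Rcpp simulation and forward
  algorithm
* `inst/extdata/` — packaged genetic maps (22-autosome fixture, toy map)
* `vignettes/continuous-ibd.Rmd` — methods: model, assumptions, numerical
  choices, limitations
* `tests/testthat/` — unit, property and acceptance suites
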