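---
title: "Continuous IBD: model, exact computations, and power studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous IBD: model, exact computations, and power studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contibd)
```

## The model and its assumptions

`contibd` models identity by descent (IBD) between two members of a
pedigree as a process observed *continuously* along the genome. The
assumptions are the standard ones of gene-dropping under Haldane's
recombination model:

* **Haldane crossovers.** Each meiosis experiences crossovers as a
  homogeneous Poisson process at 0.01 per centiMorgan, independently of
  all other meioses; there is no chiasma interference.
* **Sex-averaged map.** Male and female recombination rates are equal;
  distances are genetic (cM), never physical.
* **Outbred pedigree, two states.** Founders are mutually unrelated and
  non-inbred, and only pairs whose IBD2 probability is zero are accepted,
  so the observed state at a point is binary: IBD0 or IBD1. Full siblings
  (and any pedigree giving the pair positive IBD2 probability) are
  rejected at construction.
* **Independent chromosomes.** Expectations and variances add across
  chromosomes; genome likelihoods are products of chromosome likelihoods.

The hidden state is the inheritance vector $V_t$ with one bit per meiosis
(bit order frozen as: meioses sorted by child, paternal before maternal;
bit value 0 transmits the parent's paternal haplotype). $V_t$ is a
continuous-time Markov chain on the hypercube $\{0,1\}^{2 n_{nf}}$ whose
transitions flip single bits at rate 0.01 per cM. The observed state
$X_t$ is a deterministic function of $V_t$: drop two distinct haplotype
labels per founder through the pedigree and count labels shared by the
pair. The pair's single-locus distribution is given by the identity
coefficients $\kappa_0, \kappa_1$ ($\kappa_2 = 0$ by construction), with
the chain's uniform stationary law making $\Pr(X_t = 1) = \kappa_1$ at
every position.

## The reduced state space

The full chain has $2^{2 n_{nf}}$ states — $2^{24}$ for fifth cousins —
but most meiosis bits provably cannot influence the pair's sharing. A
meiosis from parent $p$ to child $c$ matters only if (i) $c$ is, or is an
ancestor of, one of the pair, and (ii) $p$ is, or descends from, a common
ancestor of the pair; any other bit chooses between two haplotypes
neither of which can ever be carried by the other subject, so toggling it
cannot change which labels are shared. All exact computations and the
simulator therefore run on the sub-hypercube of *relevant* meioses (e.g.
14 bits instead of 24 for fifth cousins), with every bit still flipping
at 0.01 per cM. The reduction is conservative (it may keep a harmless bit,
as for the grandparent pedigree where the grandparent's own transmission
choice is kept although either choice shares), and it is validated in the
test suite by exhaustive comparison with full $2^{2 n_{nf}}$-bit
label-dropping and by running the forward algorithm on both
representations. This plays the role that symmetry lumping plays in
pedigree-likelihood software; it is exact, not an approximation.

A capacity guard (`options(contibd.max_bits = 22)`) rejects pedigrees
whose reduced space is still too large, with a distinct error class.

## Simulation

`simulate_ibd()` draws $V_0$ uniformly, then flips one uniformly chosen
relevant bit at exponential inter-arrival times with total rate
$0.01 \cdot r$ per cM (aggregate-clock formulation; equivalent in law to
independent per-meiosis clocks, and to simulating all $2 n_{nf}$ bits,
since irrelevant flips never change $X_t$). Runs of constant $X_t$ are
merged into half-open alternating segments tiling $[0, L)$. A single
integer seed determines the whole genome; per-chromosome substreams are
derived deterministically from the seed so chromosome $i$ is reproducible
in isolation, and the first genome of a batch equals the single-genome
draw.

**What the generator emulates — and does not.** It produces exactly the
stated world: errorless, continuously observed IBD under Haldane's model
on a sex-averaged map. Real data differ in every inferential direction:
IBD must be inferred from markers (IBS, finite panels, genotyping error),
recombination is sex-specific and exhibits interference, and founders of
real pedigrees may be remotely related. A green test therefore certifies
the mathematics of the idealised bound, not the performance of any
marker-based pipeline; the bound is an upper bound on such pipelines.

## Exact statistics

* $E(T) = \kappa_1 L$ per chromosome, exactly.
* **Two-locus probability.** Because bits evolve independently, the
  transition kernel over distance $d$ factorises per bit with same-state
  probability $(1 + e^{-0.02 d})/2$. Tabulating Hamming distances over
  the IBD1 states gives $\kappa_{11}(d) = \sum_k a_k e^{-0.02 k d}$, an
  exact exponential mixture (this is the eigendecomposition of the
  hypercube walk). Then
  $E(T^2) = 2\int_0^L (L-d)\,\kappa_{11}(d)\,dd$ integrates in closed
  form; no quadrature is needed (a quadrature cross-check lives in the
  tests, agreeing to $10^{-8}$).
* **Expected segment count** is $n_{chrom}\,\kappa_1 + \text{flux} \cdot
  L_{total}$ where the flux $0.01 \cdot \#\{\text{Hamming-1 pairs } V_0
  \to V_1\} / n_v$ is the stationary up-crossing intensity per cM. The
  count's standard deviation has no comparably simple form and is
  estimated by Monte-Carlo with a reported standard error.
* **$\Pr(T = 0)$** uses uniformization: condition on the Poisson number
  of crossovers over the chromosome and run the forward recursion
  restricted to the IBD0 states, truncating the Poisson sum at its
  $(1-\epsilon)$-quantile so the truncation error is below $\epsilon$
  (default $10^{-10}$, configurable). Genome-wide,
  $\Pr(T_+ = 0) = \prod_i \Pr(T_i = 0)$ and the chromosomes-without-IBD
  count $N_0$ has mean $\sum_i p_i$ and variance $\sum_i p_i (1 - p_i)$.

## Segment likelihoods

The likelihood of an observed segment set factorises over segments via
the forward algorithm. Within a segment of state $x$ and length $\ell$,
the hidden chain must remain in the class $S_x$; the restricted,
Poisson-weighted uniformization sum gives that operator exactly. The
boundary treatment is the standard continuous-observation HMM density:

* an *interior* segment additionally contributes the exit intensity into
  the complementary class at its endpoint (0.01 per crossing neighbour) —
  a density with respect to the breakpoint position;
* the *last* segment on a chromosome contributes a staying probability
  only, which makes the all-IBD0 chromosome reduce exactly to
  $\Pr(T = 0)$.

The observation model has no error term, so a segment set incompatible
with the hypothesis (an IBD0 segment under a parent–child pedigree)
yields $-\infty$, returned as a flagged degenerate value. Accumulation is
in the log domain with per-segment rescaling: genome likelihoods for
distant relationships underflow doubles otherwise. The original authors'
software may normalise boundary densities differently; any such constant
depends only on the number of segments and cancels in likelihood ratios,
which is what the package reports and validates.

Composite hypotheses mix at the *genome* level,
$\Pr(E|H_2) = \sum_j w_j \Pr(E|\text{ped}_j)$ with positive weights
summing to one (default equal); per-chromosome mixing would be a
different — wrong — model. Classification ties (LR exactly 1, which has
positive probability for identical-law pairs such as 2C and 1C2R) are
assigned to H1, and $\Pr(LR = 1)$ is reported explicitly rather than
folded into either error rate.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| crossover rate | 0.01 / cM / meiosis | Haldane model; fixed by the cM unit |
| `epsilon` | 1e-10 | Poisson truncation per segment; halving it moves log10 LRs by < 1e-6 |
| `contibd.max_bits` | 22 | capacity cap on relevant meioses |
| `reps` | study-dependent | Monte-Carlo replicates; all rates carry binomial SEs |
| genetic map | packaged fixture | 22 autosomes, total 3391.36 cM |

The packaged map's 22 lengths are proportional to a published
sex-averaged human linkage map and rescaled so the total is exactly
3391.36 cM, which pins every $E(T_+)$ to $\kappa_1 \times 3391.36$. The
source map's per-chromosome lengths are not recoverable exactly, so
map-sensitive quantities (SD of $T_+$, per-chromosome $\Pr(T=0)$, $N_0$
moments) can deviate at the second or third significant digit from values
computed on other maps; the tests' tolerances account for this.

## Numerical and design choices

* **Coordinates** are floating-point cM, 0-based, half-open `[start,
  end)` segments; tiling and alternation are validated with a 1e-6 cM
  tolerance on read. Presentation output rounds to 2 decimals (segments)
  and 4 decimals (log10 LRs); machine round-trips use full precision.
* **Exact fractions.** Identity coefficients have power-of-two
  denominators, representable exactly in doubles up to the capacity cap;
  comparisons in the tests are exact identities, not tolerances.
* **Monte-Carlo scales.** The published studies used 10,000–1,000,000
  replicates per LR distribution. Desk runs here default to
  1,000–30,000 with reported binomial standard errors, which keeps every
  study inside minutes on one CPU; the acceptance script documents the
  replicate count alongside every estimate.
* **H2-true sampling for composites** draws the generating relationship
  uniformly (per weights) per replicate, matching the equal-weight
  mixture in the composite likelihood.
* **Degenerate inputs.** Empty segment files parse to empty sets
  (distinct from all-IBD0 genomes); zero-length chromosomes are rejected;
  undefined LRs (both likelihoods zero) raise an error distinct from
  infinite log-LRs.

## Known limitations

* No IBD2: full siblings and double-relationships are out of scope, as
  are inbred pedigrees, the X chromosome, sex-specific maps, and
  interference models.
* Likelihoods are for errorless continuous IBD only — not genotypes, IBS,
  or noisily called segments.
* The segment-count standard deviation is Monte-Carlo, not closed form.
* Only two-person relationships; sets of relationships are handled as
  composite hypotheses over pairs.
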