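---
title: "Dating continuous admixture from weighted LD decay"
author: "camix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating continuous admixture from weighted LD decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camix)
```

## The model

When two long-separated populations mix, chromosomes in the admixed
population become mosaics of ancestry tracts. Recombination shortens the
tracts each generation, and with them the linkage disequilibrium that the
mixing created: a pulse of admixture `l` generations before the present
contributes LD that decays with genetic distance `d` (Morgans) as
`exp(-l * d)`. Weighting the pairwise allele covariance in the admixed
sample by the product of source allele-frequency differences
`delta(x) * delta(y)` isolates this admixture-induced component (ALD), and
subtracting the proportion-weighted source-panel curves removes the
background LD each source carries in:

    z(d) = a0(d) - m1 * a1(d) - m2 * a2(d)

`z(d)` is therefore a nonnegative mixture of exponentials whose mixing
weights encode the whole admixture history, not only a single date:

    E z(d) = theta1 * sum_l C[l] * exp(-l * d) + theta0

`theta0` absorbs population substructure (a distance-free covariance
offset), `theta1` absorbs the overall scale, which depends on the source
allele-frequency divergence and need not be modeled, and the coefficient
vector `C` is characteristic of the admixture model.

### Coefficient vectors

`coefficientVector()` computes `C` for any migration schedule by a
forward recursion on the ancestry covariance `h(d)` between two loci: a
generation with total migrant inflow `a` (fractions `a1`, `a2` from the
two sources, pre-transition mean ancestry `m`) transforms

    h <- (1 - a) * exp(-d) * h + K,
    K  = a1 (1 - a1) - 2 a1 (1 - a) m + a (1 - a) m^2

Reading `h` as a polynomial in `exp(-d)`, every generation damps the
coefficient ledger by `(1 - a)` and shifts it one index up (one round of
recombination), and injects the constant `K` at index zero. Migrants
entering `l` generations before the present hence finish at basis index
`l`; a single founding pulse `n` generations ago yields exactly
`exp(-n d)`. This anchors the time convention throughout the package: the
tract simulator applies exactly `l` recombination rounds to generation-`l`
migrants, so fitted generations mean the same thing in theory, simulation
and estimates.

The supported models, and the closed forms the recursion reduces to
(window `E..S` of `n = S - E + 1` generations, final source-1 fraction
`m1`, `m2 = 1 - m1`):

* **HI** (hybrid isolation): one founding pulse at `n`; `C` is a spike
  `m1 m2` at index `n`.
* **GA / GA-I** (gradual admixture): the t-th window generation receives
  total inflow `1/t` split `m1 : m2`, so every generation contributes
  equally to final ancestry; `C` is flat, `m1 m2 / n`, over the window.
* **CGF1 / CGF1-I** (continuous gene flow, source 1 the recipient):
  constant inflow `a = 1 - m1^(1/n)` from source 2 onto an initially pure
  source-1 population; `C[l] = a (1-a)^(n + S - l)`, rising toward the
  ancient end of the window. CGF2 swaps the roles (and `C` is symmetric
  under `m1 -> 1 - m1`).

GA-I and CGF-I append an isolation period: the window `E..S` no longer
has to reach the present, and `C` is zero below `E`. A one-generation
window reproduces HI exactly for every model, which is why HI is kept as
the reference model in selection.

The recursion is validated two ways: algebraically against the closed
forms above (unit tests), and against forward simulation — for six anchor
scenarios the theoretical curve must match the binned ancestry-indicator
LD of a population of 5000 haplotypes on a 30-Morgan genome with relative
RMSE below 0.05 after fitting scale and offset.

## Fitting

`designMatrix()` tabulates the basis `A[i, l] = exp(-l * d_i)` on the
curve's distance grid with `J` columns (the onset upper bound in
generations; `J = 500` by default, generous for recent admixture). Given
`C`, the pair `(theta0, theta1)` is ordinary least squares on the
regressors `[1, A C]` in closed form. `theta1` is not sign-constrained;
negative fitted scales are flagged non-physical in reports rather than
clamped.

* **Onset scan** (HI, GA, CGF1, CGF2): every onset `n = 1..J` is fitted
  through one precomputed candidate-curve bank and a vectorized OLS
  sweep; the minimum-RSS onset wins, ties toward smaller `n`.
* **Interval search** (GA-I, CGF1-I, CGF2-I): the objective `f(E, S)` is
  minimized over windows `1 <= E <= S <= J`. Two methods are provided.
  The *exhaustive* method evaluates every window through a cached bank
  and guarantees the global optimum; it is the default whenever
  `J (J + 1) / 2` windows times the grid length stays below about 2e7
  entries (e.g. `J = 150` on a 295-bin grid). The *greedy* method starts
  from `(1, J)` and repeatedly takes the better of the two
  window-narrowing proposals `(E + 1, S)` and `(E, S - 1)` while it
  improves, with ties toward `(E + 1, S)`. The objective surface has
  diagonal valleys — moving one boundary alone shifts the window's
  center, which the OLS rescale punishes even when a narrower window
  centered elsewhere fits better — so when neither single proposal
  improves, the composite step `(E + 1, S - 1)` is tried before
  terminating. Greedy is used for large `J`, where the bank would not
  fit in memory; on a flat (degenerate) curve both methods return
  `(1, J)` with `theta1 = 0`.
* **Reference fit**: nonnegative least squares of the curve on the full
  `J`-column basis with a free offset — the "de-noised" curve that any
  adequate model should approach. The free offset is obtained jointly
  with the weights (the offset enters as a +/- column pair in one NNLS
  solve) and an alternating offset/NNLS refinement then polishes the
  split, keeping the best iterate, until the RSS improvement falls below
  1e-14 or 100 iterations.

## Model selection

For an `N`-chromosome data set there are `N + 1` curves: the full-genome
curve and `N` leave-one-chromosome-out curves, assembled by subtraction
from per-chromosome accumulators. Every core model is refitted to every
curve, including its own time search. With `L = log(msE)` of the full
curve and `L_q` of the q-th jackknife curve, the Tukey pseudo-values

    pseudo[q] = N * L - (N - 1) * L_q

are treated as approximately independent replicates. (The log is taken
first because msE values near zero would otherwise dominate the
comparison; an exactly zero msE is replaced by machine epsilon and
flagged.) All model pairs are compared by two-sided Wilcoxon signed-rank
tests on the paired pseudo-value differences — exact distribution up to
25 informative pairs without ties, normal approximation otherwise, zero
differences dropped, and a constant difference (no independent
replication across jackknives) treated as no evidence (p = 1) — and
Holm-Bonferroni adjusted. The best model is the one with the smallest
median pseudo-value; a model is *significantly larger* than the best when
its adjusted p-value is below 0.05 **and** its median exceeds the best
model's. If HI is not significantly larger than the best model, HI alone
is selected (the simplest model wins); otherwise all models not
significantly larger than the best are selected, and a multi-model
selection is reported as undetermined.

Two diagnostics qualify every fit of the full curve: `msE`, the mean
squared residual, with values above `1e-5` flagged as low data quality,
and quasi-F, the ratio of the model fit's residual sum of squares to the
reference fit's, with values above `1.5` flagging model rejection.
Fitted time intervals are summarized across jackknives by majority
coverage (the generations covered by more than half of the jackknife
windows) for continuous models and by the rounded mean for HI.

## The simulator

`simulateTracts()` is a forward-time copying-model simulator over
ancestry tracts: each generation every offspring haplotype is either a
whole unadmixed migrant haplotype (with the schedule's per-generation
probabilities) or a recombinant of two random haplotypes of the previous
generation, with crossovers a Poisson process of rate 1 per Morgan
(uniform genetic map). Chromosomes evolve independently, which leaves
within-chromosome LD — all the method consumes — unchanged. Migrant
sources are infinite reservoirs: migrants are always unadmixed.

`paintHaplotypes()` turns tracts into SNP panels. Source allele
frequencies follow a Balding-Nichols model: per-site ancestral
frequencies uniform on (0.05, 0.95) and source frequencies Beta-sampled
around them at divergence (Fst) 0.15, a synthetic stand-in for an
African-European-like source pair; source panels are Bernoulli samples of
226 haplotypes each (113 diploid individuals). Admixed alleles are drawn
per site from the frequency of the local ancestry ("frequency" painting, the study
default — faithful in every frequency and covariance the method uses),
or by copying donor slices from the source panels ("copy" painting,
closer to resampling real panels, at the price of carrying donor
sampling noise into the admixed panel).

What the generator does *not* emulate: real SNP ascertainment and LD
structure within the sources, non-uniform recombination maps, genotyping
error, and phase uncertainty. Passing tests therefore demonstrate
correctness of the machinery and reproduction of the study design's
operating characteristics at desk scale — not performance on any
particular empirical cohort.

## Problem sizes and numerical choices

* Distance bins: pairs closer than 0.005 M are excluded (background LD
  dominates below ~0.5 cM); default grid 0.005-0.3 M in 0.0002 M bins.
  The simulation study uses 0.001 M bins: at its pair densities the finer
  default adds bins but no information, and the coarser grid keeps one
  selection run around a second.
* The accuracy study runs 10 replicates of each of ten scenarios
  (pulse 50/100, gradual and continuous-gene-flow 1-50/1-100, isolation
  windows 30-100/70-100; final source-1 fraction 0.3), population 5000,
  10 chromosomes of 0.3 M, 1000 sampled haplotypes, 2000 sites per
  chromosome, and onset bound `J = 150` (all simulated histories end by
  generation 100). These sizes keep one replicate below ~10 s so the full
  study runs on a desktop in well under half an hour.
* SNP density is the main cost knob: real reference panels are an order
  of magnitude denser than 2000 sites per 0.3 M, and curve noise falls
  roughly linearly with density. At desk scale the study therefore
  operates at lower signal-to-noise than the original design, which
  shows up as more undetermined calls and a stronger pull toward the
  simpler HI model for continuous truths; the qualitative signatures
  (pulse histories identified reliably, interval truths invisible to the
  classic core set) are unaffected.
* Degenerate inputs: a numerically constant model curve forces
  `theta1 = 0` with an offset-only fit and a degenerate flag; empty
  distance grids and jackknife-empty bins raise errors naming the cause;
  bins empty in any leave-one-out curve are dropped from the whole set so
  all curves share one grid.
* Genetic positions are canonicalized to Morgans on input
  (centiMorgan maps are converted at read time); the exponential basis
  assumes Morgans throughout.

## Known limitations

Two-way admixture only; `m1` is an input, not estimated; no drift
correction in the theoretical curves (drift adds a small slowly-decaying
covariance component that the offset largely absorbs); the greedy
interval search can in principle terminate in a local optimum for large
`J`, where the exhaustive bank is unavailable; and model discrimination
among continuous histories is intrinsically hard when the coefficient
vector is concentrated near the window's ancient end (a CGF window
1-50 differs from a pulse near 45 by only a few percent of curve shape).
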