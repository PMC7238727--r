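---
title: "Detecting diel rhythms in viral gene expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diel rhythms in viral gene expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dielphage detects 24-hour transcriptional rhythms of viral genes in
multi-day metatranscriptomic time series and estimates when each rhythmic
gene peaks. This vignette explains the statistical machinery, the tunable
parameters, the synthetic-data generator used for validation, and the
design decisions taken where more than one reasonable choice existed.

```{r setup}
library(dielphage)
library(dplyr)
```

## The analysis problem

Surface-ocean cyanobacteria photosynthesize on a light–dark cycle, and the
phages that infect them inherit that rhythm: if infection is synchronized
across the population, transcripts of a phage gene should rise and fall
with a 24-h period, and genes expressed early in infection should peak at
a different clock time than genes expressed late. The raw material is a
diel metatranscriptomic series: seawater sampled every few hours over
several days, each sample sequenced, reads aligned to a protein database.
The pipeline answers three questions per gene (or per ortholog group of
genes): Is its abundance rhythmic with a 24-h period? When does it peak?
Do annotated early/middle/late gene classes peak in the expected order?

Four stages implement this, each usable on its own:

1. **Read assignment** (`assign_reads()`): score filtering, ambiguity
   rules, ortholog binning, tabulation into a gene-by-sample count matrix
   plus per-sample library totals.
2. **Rhythm screen** (`detect_rhythms()`): a rank-based umbrella test for
   24-h periodicity with Benjamini–Hochberg FDR control.
3. **Peak estimation** (`estimate_peaks()`): Poisson log-linear harmonic
   regression with a library-size offset, a chi-squared significance of
   fit, and an exhaustive delete-2 jackknife interval for the peak time.
4. **Class comparison** (`classify_peaks()`, `compare_all_classes()`):
   early/middle/late classification from a curated annotation and
   two-sample t tests between classes.

## Read assignment rules

Alignment hits carry a bit score; hits under the cutoff (default 50,
inclusive) are dropped. For each read the genes attaining the maximum bit
score are found; "equally well aligned" means exact score equality — bit
scores are discrete enough in practice that an epsilon band would add a
parameter without changing outcomes. A read is discarded when its
equally-best hits span more than one virus group, or include both a virus
and a non-virus subject; equally-best hits to several genes of one virus
group survive to ortholog binning, where the read counts once if the genes
share an ortholog and is discarded otherwise. Genes with no ortholog entry
(all non-cyanophage taxa, for which no ortholog catalogue exists) are
counted under their own gene id.

The normalization denominator `N_t` for sample `t` is the number of reads,
across all taxa, that survived both the score filter and the ambiguity
rules in that sample. Reads discarded as ambiguous are excluded from
`N_t`: whether the original protocol kept them in its denominator is not
documented, and excluding them is the self-consistent choice — every read
then appears exactly once, in the counts or in the discard log, an
invariant the tests assert.

## The rhythm screen

Counts are normalized to `x_t / N_t` and pooled into circular *phase
groups*: with a 24-h period and 4-h sampling, all samples taken at the
same clock phase on different days form one of 6 groups. Pooling days is
deliberate — the screen targets a rhythm with a 24-h period, so day-to-day
variation at fixed clock phase is noise, not signal.

A diel rhythm makes the group medians rise to a peak group and fall again:
an *umbrella alternative* on the circle. For each candidate peak group
`k`, the statistic sums Mann–Whitney pair counts (with ½ credit for ties)
along the rising limb from the antipodal trough group up to `k` and along
the falling limb from `k` back around to the trough; the trough–peak pair
lies on both limbs and is counted twice. Ranking makes the screen
invariant under any strictly monotone transform of the abundances, which
the tests verify.

Each candidate's one-sided p value uses a normal approximation with a
0.5 continuity correction. The null mean and variance are *exact* under
the permutation distribution given the observed (tied) values: every
ordered pair of pair-count terms is classified by its overlap pattern
(identical, reversed, shared first or second position, chained, disjoint)
and weighted with the corresponding moment of the tie structure. This is
verified in the tests against full enumeration, and `exact_umbrella_p()`
provides the exhaustive-enumeration oracle for small samples. The reported
p is the minimum over the `G` candidate profiles multiplied by `G`
(Bonferroni) and clamped to 1. Bonferroni over strongly correlated
candidates could be conservative in principle; empirically, at the default
design (44 points, 6 groups) the realized size at nominal 0.05 is 0.045 to
0.051 across seeds — essentially nominal — because the continuity
correction offsets the small conservatism of the multiplicity bound. The
procedure is an umbrella-alternative screen in the spirit of published
non-parametric rhythm detectors, not a re-implementation of any specific
one.

Two caveats the tests make explicit. First, for very small, heavily tied
samples the exact permutation distribution has probability atoms larger
than 0.1, and *no* continuous approximation can track it to better than
half an atom; the approximation-accuracy checks therefore use tie-free
values, and the package is intended for designs with dozens of time
points, where the approximation is excellent. Second, eligibility: only
series with at least one transcript per time point on average (default
`min_total` = number of time points, i.e. 44 in the default design) enter
the screen; sparser series carry `NA` p values and are never called
periodic. BH adjustment runs across the tests actually performed.

## Peak estimation

For each periodic unit the package fits

$$x_t \sim \mathrm{Poisson}\!\left(N_t\,
  e^{c + \alpha \cos(2\pi t/24) + \beta \sin(2\pi t/24)}\right)$$

by Fisher-scoring IRLS written in the package (start at
`c = log(sum(x)/sum(N))`, `alpha = beta = 0`; relative-deviance tolerance
1e-10; at most 100 iterations; step halving if a step worsens the
deviance). The log library total enters as an offset, so `c` is log
relative abundance and multiplying every `N_t` by a constant shifts only
`c` — a property the tests assert, along with agreement of the
coefficients with `stats::glm()` and with a generic BFGS likelihood
maximizer to 1e-6.

The fitted harmonic equals `A cos(2π(t − t_peak)/24)` with amplitude
`A = sqrt(alpha² + beta²)` and

$$t_{\mathrm{peak}} = \frac{12}{\pi}\,\mathrm{atan2}(\beta, \alpha) \bmod 24.$$

The `atan2` form is quadrant-safe: `(0, 1) → 6 h`, `(1, 0) → 0 h`,
`(−1, 0) → 12 h`, `(0, −1) → 18 h`. (A two-argument arctangent is
required; the single-argument `tan⁻¹(β/α)` form loses the quadrant and
the equivalent "6 − (12/π) tan⁻¹(α/β)" form is sometimes printed with the
coefficient inverted to π/12, which is dimensionally inconsistent with a
24-h period — the package documents and uses the 12/π form throughout.)
Times enter as absolute hours since the start of the series; only `t mod
24` matters given the 24-h basis, and reported peaks are anchored to local
clock time by the design's time offsets.

Significance of fit is the deviance difference between the intercept-only
model (with offset) and the harmonic model on a χ² with 2 degrees of
freedom, BH-adjusted across units. Under a constant-rate null its size at
0.05 measures 0.05–0.07 — the mild liberality expected of a likelihood
ratio test at moderate counts.

## The delete-2 jackknife interval

Following the resampling scheme the pipeline reproduces, every subsample
with 2 of the `n` time points deleted is refitted — all `choose(n, 2)`
of them, 946 for `n = 44` — and the 5% and 95% quantiles (type-7 linear
interpolation, fixed for reproducibility) of the subsample peak times form
the nominal 90% interval. Peak times are circular, so each subsample peak
is first unwrapped into the half-period window centred on the full-data
peak; the interval is equivariant under time-origin shifts. Degenerate
subsamples (all counts zero, non-converged refits) are dropped from the
quantile set and reported via `n_converged`, with a warning when more than
5% drop out.

A statistical caution documented deliberately: quantiles of delete-d
subsample estimates understate sampling variability. Deleting `d` of `n`
points perturbs the estimate by roughly `sqrt(d·n)/(n−d)` of its sampling
standard deviation (≈ 0.22 for `d = 2`, `n = 44`), so the nominal 90%
interval is far narrower than a calibrated one and its realized coverage
of the true phase is well below 90% (about 30% in the package's
simulations at depth 1e5 and amplitude ratio 0.5). The interval is
faithful to the resampling scheme it reproduces and is useful as a
*precision* summary — its width tracks the information content of the
series — but it should not be read as a calibrated confidence interval; a
classical delete-d jackknife would instead inflate deviations via
pseudovalues by `(n−d)/d`.

## Class comparison

Peak times of annotated early/middle/late orthologs are compared with the
classic pooled-variance two-tailed Student's t test (Welch available via
`welch = TRUE`; "Student's test" without qualification conventionally
means the pooled form). Clock times are circular, so before testing they
are linearized as hours since a dawn anchor (06:00 by default,
configurable): all observed peaks fall within one diel cycle, making the
linearization a plain rotation. No circular-statistics test
(Watson–Williams etc.) is attempted beyond this documented linearization.
The annotation ships as an editable TSV (a synthetic stand-in fixture with
the 3/11/7 early/middle/late layout is bundled under `extdata`); classes
are never inferred from expression.

## The synthetic-data generator

`simulate_counts()` emulates the field design the pipeline targets:
44 samples at 4-h spacing over 8 days (gaps allowed via an explicit time
list — which 44 of the 48 possible 4-h slots were sampled in the original
cruise is not documented, so the time list is free input), per-sample
library totals drawn log-normally (σ = 0.2 by default) around a nominal
depth to exercise the offset term, and per-gene counts drawn

$$x_{gt} \sim \mathrm{Poisson}\!\left(N_t\, r_g\,
 (1 + a_g \cos(2\pi(t - \varphi_g)/24))\right)$$

with baseline relative abundance `r_g`, relative amplitude `a_g ∈ [0, 1)`
and peak phase `φ_g`. The generator is parameterized by `(a, φ)` rather
than `(α, β)` so ground truth is directly comparable to the fitted peak
time; note the generated rate is a *linear* sinusoid while the fitted
model is log-linear — the peak location coincides, which is what the
pipeline estimates, but the waveform differs, a deliberate mild
misspecification that keeps recovery tests honest. Defaults
(`depth 1e4–1e5`, `r = 1e-3`, `a = 0.5–0.8`) give per-sample counts of
10–100, the regime where a field ortholog passes the eligibility rule
comfortably. `simulate_hits()` builds read-level hit tables in which every
read's fate under the filtering rules (kept, sub-cutoff score, multi-group
tie, virus–host tie, multi-ortholog tie) is known by construction, so
filter bookkeeping is checkable exactly; `sim_to_hits()` expands a count
simulation into an unambiguous hit table for end-to-end runs.

What the generator does *not* emulate: overdispersion beyond Poisson,
rRNA contamination, alignment error, taxonomic misassignment, day-to-day
trends, or waveforms other than a single 24-h harmonic. Passing tests on
synthetic data therefore demonstrate correctness of the algorithms under
the stated model, not robustness to every artefact of real
metatranscriptomes.

## Parameters at a glance

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `cutoff` | 50 | `assign_reads()` | bit-score cutoff, inclusive |
| `min_total` | n time points | `detect_rhythms()` | eligibility: total transcripts |
| `period_h` | 24 h | screen & fit | rhythm period |
| `interval_h` | 4 h | screen | phase-group width (6 groups) |
| `fdr` | 0.1 | screen & fit | BH threshold for periodicity / fit |
| `d` | 2 | `jackknife_ci()` | deleted points per subsample |
| `coverage` | 0.90 | `jackknife_ci()` | quantile span of the interval |
| `anchor_h` | 6 h | class tests | dawn anchor for linearization |
| `sunset_h` | 19.183 h | `diel_design()` | night annotation (19:11) |

## Problem sizes used in the validation suite

The test suite and the acceptance script regenerate everything they
measure: coefficient agreement on 20 series of 44 points; peak recovery
and interval behaviour on 100 genes at depth 1e5 (each with all 946
delete-2 refits); test size on 1000 null genes; the FDR layer on mixtures
of 100 rhythmic + 400 null genes; class separation on 100 simulated
3/11/7 early/middle/late layouts. These sizes were chosen so each
statistical assertion has narrow Monte-Carlo error while the whole suite
remains quick to run routinely.

## Known limitations

- The jackknife interval is anticonservative as a confidence interval
  (see above); it is reported because it is the resampling scheme the
  pipeline reproduces.
- The umbrella screen's normal approximation should not be trusted for
  designs with fewer than ~3 observations per phase group; use
  `exact_umbrella_p()` there.
- The Poisson model carries no overdispersion term; a negative-binomial
  variant is out of scope.
- Multi-harmonic or asymmetric waveforms are not fitted; the peak time of
  a strongly non-sinusoidal rhythm is estimated under the single-harmonic
  approximation.
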