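---
title: "Methods: detecting and modeling accept-reject foraging decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and modeling accept-reject foraging decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A *C. elegans*-style forager crawling among small bacterial patches makes a
decision at every patch encounter: accept the patch and exploit it (a long,
slow visit), or reject it and keep exploring (a brief visit, or no response
at all). Low-magnification assays track only the worm's body midpoint, so
neither the encounter itself nor the decision is directly observed. This
package reconstructs both from midpoint trajectories and models the
decision probability, end to end:

1. **Encounter detection** — geometric thresholds on the signed distance
   from the midpoint to the nearest patch edge.
2. **Exploit classification** — a two-component Gaussian mixture on
   (log duration, log mean on-patch speed) giving `p(y=1|z)`, preceded by a
   Silverman critical-bandwidth test that the feature distribution really
   has two modes.
3. **Sensing classification** — replicated semi-supervised QDA on three
   velocity features giving `p(v=1|w)`, with marginalization over features
   that are censored when a recording starts mid-encounter.
4. **Decision model** — a soft-label logistic regression of exploitation on
   patch density and foraging history, with hierarchical
   (encounter x worm) bootstrap inference.
5. **Synthetic worlds** — an agent-based simulator and a covariate-level
   generator provide ground truth for every stage; no external data is
   needed anywhere.

## Encounter detection

The signed distance `d(t)` is positive inside a patch. An encounter is a
maximal run with `d >= -0.46024` mm (the average midpoint offset when the
head first touches the patch edge in high-resolution recordings).
Candidates whose midpoint never comes within 0.28758 mm of the edge are
near misses and are dropped; gaps between same-patch candidates whose
distance standard deviation stays below 0.22221 mm are false exits
(outstretched feeding postures) and are merged, iterated to a fixed point.
The three constants were measured on high-resolution recordings; here they are
configurable defaults, and `derive_exit_threshold()` re-derives the third
on synthetic data via a two-component mixture on log gap SDs.

Numerical choices: midpoint speeds use central differences smoothed by a
1 s moving average (raw differencing at ~33 px/mm is noise-dominated;
disable with `smooth = FALSE` for analytic tracks). Nearest-patch ties go
to the lowest patch id. Encounters touching either end of the recording are
flagged `start_censored` / `end_censored`; start-censored encounters keep
their features but the deceleration-related ones are flagged biased.

Per-encounter features: `w = (s, t, u)` with `s` the minimum on-encounter
speed (um/s), `t` the OLS slope of speed on time over entry -1.5 s to
+6.5 s (um/s^2), and `u` the peak speed in the 10 s *before* entry minus
`s`, floored at zero (the "within 10 s of the encounter" phrasing is read
as 10 s before entry); `z = (ln duration, ln mean on-encounter speed)`.

## Bimodality testing and exploit classification

Encounters are projected onto the first principal component of the centered
`z` matrix (sign fixed so the log-duration loading is positive). The
critical bandwidth `h*` — the smallest Gaussian-KDE bandwidth with at most
one mode — is found by bisection to relative tolerance 1e-4; modes are
strict interior maxima on a 1024-point grid spanning the data +/- 3h, and
the Gaussian-kernel property that mode count is non-increasing in bandwidth
is asserted along the bisection path. The smoothed bootstrap resamples with
replacement and adds rescaled noise
`z~ = (z* + h* eps) / sqrt(1 + (h*/sigma)^2)`; the p-value is the fraction
of replicates whose critical bandwidth reaches `h*`, computed via the
equivalent one-evaluation rule (replicate KDE at `h*` still multimodal).
The explicit per-replicate `h*` recomputation is available as
`variant = "hstar"` and agrees up to grid ties.

The exploit classifier is a two-component full-covariance GMM with a ridge
`alpha` on the covariance diagonals, chosen by k-fold cross-validation to
minimize the held-out posterior variance `sum p(1-p)`; the grid includes
0.025, a default that separates typical encounter clusters well.
Components are labeled semantically — exploit = larger mean log-duration —
so the posterior is invariant to component order. EM starts from
k-means++ (10 restarts, fixed seed) and converges at 1e-8 relative
log-likelihood.

## Sensing classification and censoring

True negatives are encounters with bacteria-free (relative density 0)
patches; true positives are exploitation encounters drawn per replicate as
`y ~ Bern(p(y=1|z))` (1000 replicates at full scale). Each replicate runs
a semi-supervised QDA: labeled points enter with hard weights, unlabeled
points re-enter every refit with weight equal to their current posterior
(soft self-training — the specific weighting inside the original "iterative
paraboloid" loop is unspecified; this expectation-style choice converges on
total posterior variance below 1e-6 or 100 iterations). The sensing
probability is the replicate-averaged QDA posterior. Replicates that draw
fewer than four positives fall back to the top-posterior encounters; if all
exploit posteriors are zero, seeding is impossible and the function errors.

Start-censored encounters trust only `s`; their probability is
`p(v=1|s) = int int p(v=1|s,t,u) p(t,u|s) dt du`, with `p(t,u|s)` a
product-Gaussian conditional KDE over the uncensored encounters
(rule-of-thumb bandwidths, slice at `s`, renormalized) and nested adaptive
quadrature to absolute tolerance 1e-4. When the conditioning weights have
effective sample size below 5 the unconditional joint is used with a
warning; zero bandwidths give the exact discrete mixture, which is how the
point-mass contract is met. Finally, near-miss encounters whose midpoint
never entered the patch *and* whose sensing probability is below 5% are
excluded (the rule is conjunctive). The classification table composes the
three-way taxonomy as search = 1 - p_sense,
sample = p_sense (1 - p_exploit), exploit = p_sense p_exploit — the
natural reading of the taxonomy; no other composition is implied by the
two posteriors.

## The soft-label decision model

The decision model is `p(y=1|x) = logistic(beta . x)` with covariates:
`rho_k` (ln relative density of the current patch), `tau_s` (hours off food
since the last exploitation; for the first encounter, total elapsed time),
`rho_h` (ln density of the previous encounter), `rho_e` (ln density of the
last exploited patch), optionally `tau_t` (hours since transfer). `rho_h`
and `rho_e` initialize at the acclimation-plate density. Natural logs and
hours throughout (bases and units only rescale coefficients).

Because the response is a classifier posterior `q`, the model maximizes
`sum q log p + (1-q) log(1-p)`, which equals minimizing
`sum KL(q || p)` up to a constant and reduces to the Bernoulli MLE for
binary `q`. The problem is concave; a damped Newton iteration on internally
standardized covariates converges to gradient norm 1e-8, reporting
coefficients on the original scale. Unpenalized fits error on separation
(recommending ridge) and on rank-deficient designs (naming the collinear
columns); ridge fits skip the rank check because the penalty makes
deficient designs well-posed — single-density bootstrap replicates place
all mass on one `rho_k` value and would otherwise be rejected.

Inference crosses two resampling layers: *encounter sampling* draws
`v ~ Bern(p_sense)` per encounter and rebuilds the covariates on the
retained sequence (dropped-encounter dwell time counts as off-food search
time; the rebuild is skipped for worms that lost nothing, where it is the
identity), and the *worm bootstrap* resamples whole animals with
replacement. Full scale is 100 x 500 = 50,000 replicate fits; fixtures use
10 x 50. Realized exploitations inside a rebuild use the deterministic
`q >= 0.5` rule by default (replicate-deterministic), with a Bernoulli mode
available; the generator itself propagates history with Bernoulli draws,
which is why the sampler does not force a rebuild on untouched worms.
Coefficient tests use the two-tailed one-sample bootstrap rule
`p = 2 min[P(beta <= 0), P(beta >= 0)]`, floored at 2/B and
Bonferroni-adjusted; strain contrasts use the mean-of-differences Z with a
left tail for the density coefficients and Benjamini-Hochberg adjustment.
Model selection uses BIC; nested comparisons use the likelihood-ratio
statistic with a chi-squared reference, which is exact only for Bernoulli
responses — with noiseless soft labels the statistic degenerates to 0 under
the null, so the calibration tests feed realized Bernoulli outcomes.

## What the synthetic world does and does not emulate

The simulator states the world the tests assume: off-patch correlated
random walk at 198 um/s (+/-10% speed jitter, heading diffusion
1 rad/sqrt(s) — locomotion statistics are unconstrained by the source
assays and documented as free), specular reflection at the arena wall,
sensing probability monotone in patch density, a linear slowdown ramp to
52 um/s over 8 s on sensed entries, log10-normal dwell mixtures (short mode
10^1.2 ~ 16 s, long mode 10^2.9 ~ 13 min, sd 0.35 — chosen to reproduce the
short <2 min vs long 2-60 min split), and exploit decisions drawn from the
logistic rule with known coefficients; defaults use the benchmark vector
(-2, 1, 0.5, -0.5, -0.5) and acclimation density 10. The covariate-level
generator gives the GLM *noiseless* soft labels (`q` equals the true
decision probability exactly), so coefficient recovery is exact up to
numerics — a green recovery test establishes correctness of the estimator
and resampling plumbing, not robustness to classifier error. Not emulated:
body posture, feeding dynamics, bacterial depletion (negligible in the
assayed conditions), head/tail resolution, or track-stitching artifacts.

## Known limitations

- The "multinomial regression" used for sub-detection-limit densities is
  an ambiguous designation; the degree-2 polynomial-over-OD reading is
  implemented and flagged.
- The annulus half-width for edge-peak detection (10% of the edge radius,
  minimum 50 um) is a stated choice; the source does not give one.
- Bootstrap percentile intervals inherit the usual finite-replicate
  granularity; p-values below 2/B are reported at the floor.
- The pipeline's manifest records wall-clock times, so manifests are not
  byte-identical across reruns; all data tables are.
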