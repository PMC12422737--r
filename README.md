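# patchforage

Quantitative detection and modeling of **accept–reject foraging
decisions** from animal tracking data. The target system is a
*C. elegans*-style forager crawling among small bacterial patches in a
circular arena, recorded at low magnification so that only the body
midpoint is tracked. The package reconstructs discrete patch encounters
from the midpoint trajectory, classifies each encounter, and models the
per-encounter decision to exploit a patch — together with an agent-based
simulator that provides ground truth for every stage, so the whole
pipeline is testable without any external data.

**Who it is for:** behavioral neuroscientists and quantitative ethologists
analyzing patch-foraging assays, and methodologists interested in
soft-label regression and replicated semi-supervised classification.

## The model at the core

Each encounter *k* carries covariates
x_k = (1, ρ_k, τ_s, ρ_h, ρ_e[, τ_t]): log relative density of the
encountered patch, hours off food since the last exploitation, log density
of the previous encounter, log density of the last exploited patch, and
optionally hours since transfer. The decision is logistic,

&nbsp;&nbsp;&nbsp;&nbsp;p(y_k = 1 | β·x_k) = 1 / (1 + e^(−β·x_k)),

but y_k is never observed directly — a classifier supplies a posterior
q_k = p(y_k = 1 | z_k) from encounter duration and on-patch speed. Fitting
maximizes the soft-label likelihood Σ_k [q_k log p_k + (1−q_k) log(1−p_k)],
equivalent to minimizing Σ_k KL(q_k ‖ p_k), and reduces to the ordinary
Bernoulli MLE for binary q. Whether an encounter was *sensed* at all,
p(v_k = 1 | w_k), comes from a replicated semi-supervised QDA on three
slowdown features; inference crosses probabilistic encounter inclusion
(100 draws of v_k ~ Bern(p_sense)) with a hierarchical worm bootstrap
(500 resamples of whole animals).

Upstream, encounters are detected from the signed midpoint-to-patch-edge
distance with three measured thresholds (entry 0.46024 mm, near-miss
0.28758 mm, false-exit variability 0.22221 mm), and a Silverman
critical-bandwidth test with smoothed bootstrap certifies the bimodality
that justifies the two-cluster exploit classifier.

## Worked example

Simulate three plates (relative densities 0, 5, 10; two worms each,
20 minutes), detect and classify encounters, and fit the decision model:

```r
library(patchforage)
cfg <- run_config(out_dir = "pipe", n_worms_per_condition = 2,
                  n_qda_replicates = 50, n_encounter_sets = 10,
                  n_worm_sets = 50, seed = 42)
run_pipeline(cfg)
head(read_stage_table("pipe/classification.tsv")[,
  c("duration_s", "density", "p_exploit", "p_sense")], 3)
#>   duration_s density p_exploit p_sense
#> 1     24.000       0     0.002   0.751
#> 2     14.333       0     0.020   0.000
#> 3     15.333       0     0.027   0.000
```

`p_exploit` is the GMM posterior that the visit was an exploitation
(these density-0 visits are short and fast, so it is near 0), `p_sense`
the replicate-averaged QDA probability that the worm detected the patch;
the table also carries the three-way search/sample/exploit probabilities
and the bootstrap coefficient summary lands in `pipe/coefficients.tsv`.

At benchmark scale the estimator is exact: the covariate-level generator
hands the GLM noiseless soft labels, and the fit returns the generating
coefficients to machine precision,

```r
g <- generate_covariate_dataset(seed = 1)   # 200 worms x 20 encounters
fit_soft_logistic(g$dataset)
#> Soft-label logistic fit (n = 4000 , lambda = 0 )
#> intercept     rho_k     tau_s     rho_h     rho_e
#>      -2.0       1.0       0.5      -0.5      -0.5
#> soft log-likelihood: -1300.92  BIC: 2643.3
```

i.e. the generating vector β_true = (−2, 1, 0.5, −0.5, −0.5): density
raises the exploitation odds, time off food raises them, and richer recent
experience (ρ_h, ρ_e) lowers them.

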