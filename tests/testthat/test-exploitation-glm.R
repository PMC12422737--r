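test_that("build_covariates follows the documented sequential scheme", {
  acc <- 10
  # first encounter: history at acclimation, tau_s = entry time
  e1 <- raw_encounters(1, entry_s = 600, exit_s = 700, density = 5,
                       q = 0.1)
  d1 <- build_covariates(e1, acclimation_density = acc)
  expect_equal(d1$rho_h, log(acc))
  expect_equal(d1$rho_e, log(acc))
  expect_equal(d1$tau_s, 600 / 3600)
  expect_equal(d1$rho_k, log(5))
  expect_equal(d1$tau_t, 600 / 3600)

  # constructed 3-encounter timeline, exploit on encounter 2 (q = 0.9)
  e3 <- raw_encounters(1, entry_s = c(600, 1200, 3000),
                       exit_s = c(700, 1500, 3100),
                       density = c(5, 2, 8), q = c(0.1, 0.9, 0.2))
  d3 <- build_covariates(e3, acclimation_density = acc)
  expect_equal(d3$tau_s[2], (600 + 1200 - 700) / 3600)
  # tau_s at encounter 3 counts only off-patch time since leaving patch 2
  expect_equal(d3$tau_s[3], (3000 - 1500) / 3600)
  expect_equal(d3$rho_h, c(log(acc), log(5), log(2)))
  expect_equal(d3$rho_e, c(log(acc), log(acc), log(2)))

  # homogeneous history: all encounters at the acclimation density with
  # immediate exploitation
  eh <- raw_encounters(1, entry_s = c(100, 900, 1700),
                       exit_s = c(400, 1200, 2000),
                       density = acc, q = 1)
  dh <- build_covariates(eh, acclimation_density = acc)
  expect_true(all(dh$rho_k == log(acc)))
  expect_true(all(dh$rho_h == log(acc)))
  expect_true(all(dh$rho_e == log(acc)))

  # density-0 rows are dropped; their dwell counts as off-food time
  e0 <- raw_encounters(1, entry_s = c(600, 1200, 2000, 3000),
                       exit_s = c(700, 1500, 2200, 3100),
                       density = c(5, 2, 0, 8), q = c(0.1, 0.9, 0.1, 0.2))
  d0 <- build_covariates(e0, acclimation_density = acc)
  expect_equal(nrow(d0), 3L)
  expect_equal(d0$tau_s[3], (3000 - 1500) / 3600)
  expect_error(build_covariates(transform(e1, density = -1)), "negative")
  # pseudo-density keeps density-0 rows
  dp <- build_covariates(e0, acclimation_density = acc,
                         pseudo_density = 0.01)
  expect_equal(nrow(dp), 4L)
  expect_equal(dp$rho_k[3], log(0.01))
})

test_that("encounter_sample drops, rebuilds, and reduces correctly", {
  # certain inclusion: replicates identical to the input
  g <- generate_covariate_dataset(n_worms = 4, encounters_per_worm = 5,
                                  seed = 3)
  reps <- encounter_sample(g$dataset, n_sets = 3, seed = 1)
  expect_identical(reps[[1]], g$dataset)
  expect_identical(reps[[3]], g$dataset)

  # certain exclusion: empty replicates, downstream fit errors
  ds0 <- g$dataset
  ds0$p_sense <- 0
  reps0 <- encounter_sample(ds0, n_sets = 1, seed = 1)
  expect_equal(nrow(reps0[[1]]), 0L)
  expect_error(fit_soft_logistic(reps0[[1]], c("rho_k")))

  # worked 10-encounter example: dropping k1, k3, k6, k8 re-indexes the six
  # retained encounters and recomputes covariates on that sequence
  ent <- seq(600, by = 900, length.out = 10)
  ex <- ent + 300
  dens <- c(5, 2, 8, 1, 5, 10, 2, 4, 5, 8)
  qv <- c(0.1, 0.2, 0.9, 0.1, 0.8, 0.3, 0.2, 0.9, 0.4, 0.1)
  keep <- !(seq_len(10) %in% c(1, 3, 6, 8))
  raw <- raw_encounters(1, ent, ex, dens, qv, p_sense = as.numeric(keep))
  ds <- build_covariates(raw, acclimation_density = 10)
  ds$p_sense <- as.numeric(keep)   # deterministic inclusion pattern
  rep1 <- encounter_sample(ds, n_sets = 1, seed = 2)[[1]]
  manual <- build_covariates(raw[keep, ], acclimation_density = 10)
  expect_equal(rep1$k, 1:6)
  expect_equal(rep1$density, dens[keep])
  expect_equal(rep1$tau_s, manual$tau_s)
  expect_equal(rep1$rho_h, manual$rho_h)
  expect_equal(rep1$rho_e, manual$rho_e)
  # dropped-encounter dwell time counts as off-patch search: encounter k2
  # (first retained) keeps tau_s equal to its full elapsed off-food time
  expect_equal(rep1$tau_s[1], ent[2] / 3600)
})

test_that("worm_bootstrap resamples whole animals", {
  g <- generate_covariate_dataset(n_worms = 1, encounters_per_worm = 4,
                                  seed = 2)
  reps <- worm_bootstrap(g$dataset, n_sets = 3, seed = 1)
  expect_true(all(vapply(reps, identical, logical(1), y = reps[[1]])))
  # expected unique fraction ~ 1 - 1/e at n = 443
  ds <- data.frame(worm_id = 1:443)
  reps2 <- worm_bootstrap(ds, n_sets = 200, seed = 5)
  uf <- mean(vapply(reps2, function(w) length(unique(w)) / 443, numeric(1)))
  expect_lt(abs(uf - (1 - exp(-1))), 0.02)
  expect_true(all(lengths(reps2) == 443L))
})

test_that("fit_soft_logistic solves the soft ML problem", {
  # all q = 0.5, intercept-only: beta0 = 0
  ds <- data.frame(worm_id = 1, q = rep(0.5, 50), rho_k = rnorm(50))
  f0 <- fit_soft_logistic(ds, spec = character(0))
  expect_lt(abs(f0$beta[["intercept"]]), 1e-8)
  # intercept-only closed form: logit of the mean label
  set.seed(10)
  ds$q <- runif(50)
  fm <- fit_soft_logistic(ds, spec = character(0))
  expect_equal(fm$beta[["intercept"]],
               log(mean(ds$q) / (1 - mean(ds$q))), tolerance = 1e-8)
  # binary q equals the glm() Bernoulli MLE
  set.seed(11)
  ds2 <- data.frame(worm_id = 1, rho_k = rnorm(300), tau_s = rexp(300))
  eta <- -0.5 + ds2$rho_k - 0.8 * ds2$tau_s
  ds2$q <- rbinom(300, 1, plogis(eta))
  ours <- fit_soft_logistic(ds2, c("rho_k", "tau_s"))
  oracle <- glm(q ~ rho_k + tau_s, binomial, ds2,
                control = glm.control(epsilon = 1e-14, maxit = 100))
  expect_equal(unname(ours$beta), unname(coef(oracle)), tolerance = 1e-7)
  expect_equal(ours$loglik, as.numeric(logLik(oracle)), tolerance = 1e-8)
  # rank deficiency names the collinear column
  ds3 <- ds2; ds3$rho_h <- ds3$rho_k
  expect_error(fit_soft_logistic(ds3, c("rho_k", "rho_h")), "rho_h")
  # separation recommends ridge; ridge then succeeds
  ds4 <- data.frame(worm_id = 1, rho_k = c(-(20:1), 1:20),
                    q = rep(0:1, each = 20))
  expect_error(fit_soft_logistic(ds4, "rho_k"), "ridge")
  fr <- fit_ridge(ds4, "rho_k", lambda = 0.1)
  expect_true(is.finite(fr$beta[["rho_k"]]))
})

test_that("the soft likelihood is the KL objective up to a constant", {
  set.seed(12)
  ds <- data.frame(worm_id = 1, rho_k = rnorm(100), q = runif(100))
  X <- cbind(1, ds$rho_k)
  kl <- function(beta) {
    p <- plogis(X %*% beta)
    q <- ds$q
    sum(ifelse(q > 0, q * log(q / p), 0) +
          ifelse(q < 1, (1 - q) * log((1 - q) / (1 - p)), 0))
  }
  ll <- function(beta) {
    p <- plogis(X %*% beta)
    sum(ds$q * log(p) + (1 - ds$q) * log(1 - p))
  }
  betas <- lapply(1:8, function(i) rnorm(2))
  for (i in 2:8)
    expect_equal(ll(betas[[i]]) - ll(betas[[1]]),
                 kl(betas[[1]]) - kl(betas[[i]]), tolerance = 1e-10)
  # hence the same argmin: the fit minimizes total KL along a line search
  fit <- fit_soft_logistic(ds, "rho_k")
  b <- unname(fit$beta)
  for (eps in c(-0.05, 0.05))
    expect_gt(kl(b + c(eps, 0)), kl(b) - 1e-10)
})

test_that("fits are invariant to worm order and equivariant to rescaling", {
  g <- generate_covariate_dataset(n_worms = 20, encounters_per_worm = 8,
                                  seed = 6)
  ds <- g$dataset
  f1 <- fit_soft_logistic(ds)
  ds_rev <- ds[rev(seq_len(nrow(ds))), ]
  f2 <- fit_soft_logistic(ds_rev)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  # affine rescaling: tau_s in minutes instead of hours
  ds_min <- ds; ds_min$tau_s <- ds$tau_s * 60
  f3 <- fit_soft_logistic(ds_min)
  expect_equal(f3$beta[["tau_s"]], f1$beta[["tau_s"]] / 60,
               tolerance = 1e-6)
  expect_equal(f3$beta[["rho_k"]], f1$beta[["rho_k"]], tolerance = 1e-6)
})

test_that("bic and model_select rank specifications", {
  # penalty arithmetic: equal likelihood, one extra parameter
  f_small <- structure(list(beta = c(intercept = 0), loglik = -100,
                            n = 500, spec = character(0), lambda = 0),
                       class = "glm_fit")
  f_big <- structure(list(beta = c(intercept = 0, rho_k = 0),
                          loglik = -100, n = 500, spec = "rho_k",
                          lambda = 0),
                     class = "glm_fit")
  expect_equal(bic(f_big) - bic(f_small), log(500))
  g <- generate_covariate_dataset(n_worms = 30, encounters_per_worm = 10,
                                  seed = 8)
  tab <- model_select(g$dataset, list(intercept = character(0)))
  expect_equal(tab$rank, 1L)
  tab2 <- model_select(g$dataset,
                       list(intercept = character(0),
                            full = c("rho_k", "tau_s", "rho_h", "rho_e")))
  expect_equal(tab2$spec_id[1], "full")   # active covariates win
})

test_that("ridge shrinks monotonically and reduces to ML at 0", {
  g <- generate_covariate_dataset(n_worms = 25, encounters_per_worm = 8,
                                  seed = 9)
  f_ml <- fit_soft_logistic(g$dataset)
  f_0 <- fit_ridge(g$dataset, c("rho_k", "tau_s", "rho_h", "rho_e"), 0)
  expect_equal(f_ml$beta, f_0$beta, tolerance = 1e-9)
  norms <- vapply(c(0, 0.1, 1, 10, 100), function(l)
    sqrt(sum(fit_ridge(g$dataset, c("rho_k", "tau_s", "rho_h", "rho_e"),
                       l)$beta[-1]^2)), numeric(1))
  expect_true(all(diff(norms) < 1e-8))
  expect_error(fit_ridge(g$dataset, "rho_k", -1), ">= 0")
})

test_that("cv_lambda picks a grid member, favoring regularization at small n", {
  # near-separable small-n binary data: unpenalized fits overfit badly
  set.seed(14)
  n <- 60
  ds <- data.frame(worm_id = rep(1:12, each = 5),
                   rho_k = rnorm(n), tau_s = rnorm(n), rho_h = rnorm(n),
                   rho_e = rnorm(n))
  eta <- 3 * ds$rho_k - 3 * ds$tau_s + 2 * ds$rho_h
  ds$q <- rbinom(n, 1, plogis(5 * eta))
  grid <- c(0, 0.01, 0.0562, 0.1, 0.562, 1)
  sel <- cv_lambda(ds, c("rho_k", "tau_s", "rho_h", "rho_e"), grid,
                   n_folds = 4, seed = 2)
  expect_true(sel$lambda %in% grid)
  expect_gt(sel$lambda, 0)
  expect_equal(nrow(sel$cv), length(grid))
  expect_error(cv_lambda(ds, "rho_k", numeric(0)), "empty")
})

test_that("shuffle_null and coefficient_test behave on constructed ensembles", {
  g <- generate_covariate_dataset(n_worms = 15, encounters_per_worm = 6,
                                  seed = 4)
  nul <- shuffle_null(g$dataset, c("rho_k", "tau_s"), n_shuffles = 120,
                      seed = 3)
  expect_equal(dim(nul), c(120L, 3L))
  # shuffled-response coefficients straddle zero
  expect_gt(mean(nul[, "rho_k"] > 0), 0.1)
  expect_lt(mean(nul[, "rho_k"] > 0), 0.9)
  # all-positive ensemble: p at the 2/B floor
  ens <- cbind(a = abs(rnorm(200)) + 0.1, b = rnorm(200))
  ct <- coefficient_test(ens)
  expect_equal(ct$p[1], 2 / 200)
  expect_true(ct$at_floor[1])
  expect_gt(ct$p[2], 0.5)   # symmetric about 0 -> p near 1
  expect_equal(ct$p_adjusted, pmin(1, ct$p * 2))
  expect_warning(coefficient_test(ens[1:50, ]), "resolution")
})

test_that("null-data coefficient tests stay at nominal level", {
  # q independent of x: per-run any-rejection rate after Bonferroni should
  # not exceed the nominal 0.05 (3 SE margin at 200 runs)
  runs <- 200
  rej <- logical(runs)
  for (r in seq_len(runs)) {
    set.seed(1000 + r)
    ds <- data.frame(worm_id = rep(1:30, each = 10),
                     rho_k = rnorm(300), tau_s = rexp(300),
                     q = runif(300), p_sense = 1)
    class(ds) <- c("soft_label_dataset", "data.frame")
    ens <- fit_ensemble(ds, c("rho_k", "tau_s"), n_encounter_sets = 1,
                        n_worm_sets = 100, seed = r)
    ct <- coefficient_test(ens)
    rej[r] <- any(ct$p_adjusted[ct$coef != "intercept"] < 0.05)
  }
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / runs))
})

test_that("strain_compare implements the Z mean-of-differences test", {
  mk <- function(mu, sd) structure(list(beta = NULL, mean = mu, sd = sd,
                                        spec = names(mu)[-1]),
                                   class = "bootstrap_ensemble")
  nm <- c(intercept = 0, rho_k = 1, tau_s = 0.5)
  e1 <- mk(nm, c(intercept = 1, rho_k = 1, tau_s = 1))
  e1$beta <- matrix(0, 2, 3, dimnames = list(NULL, names(nm)))
  e2 <- e1
  sc <- strain_compare(e1, e2)
  expect_equal(sc$z, rep(0, 3))
  expect_equal(sc$p[sc$coef == "rho_k"], 0.5)       # left tail at Z = 0
  # Z = -1 left-tailed: Phi(-1)
  e3 <- e1
  e3$mean <- nm - c(0, sqrt(2), 0)
  sc2 <- strain_compare(e3, e2)
  expect_equal(sc2$z[sc2$coef == "rho_k"], -1)
  expect_equal(sc2$p[sc2$coef == "rho_k"], pnorm(-1), tolerance = 1e-12)
  # two-tailed default doubles; literal variant does not
  e4 <- e1
  e4$mean <- nm + c(sqrt(2), 0, 0)
  expect_equal(strain_compare(e4, e2)$p[1], 2 * pnorm(-1))
  expect_equal(strain_compare(e4, e2, two_tail_literal = TRUE)$p[1],
               pnorm(-1))
  e5 <- e1; e5$sd <- e5$sd * 0
  expect_error(strain_compare(e5, e5), "pooled variance")
})

test_that("same-truth strain ensembles stay within the nominal FDR", {
  # both ensembles drawn from the same coefficient distribution: BH-adjusted
  # rejections at q = 0.05 should be rare
  set.seed(20)
  pairs <- 100
  any_rej <- logical(pairs)
  nm <- c("intercept", "rho_k", "tau_s", "rho_h", "rho_e")
  for (i in seq_len(pairs)) {
    mk <- function() {
      B <- matrix(rnorm(200 * 5, mean = rep(c(-2, 1, 0.5, -0.5, -0.5),
                                            each = 200),
                        sd = 0.3), 200, 5, dimnames = list(NULL, nm))
      structure(list(beta = B, mean = colMeans(B),
                     sd = apply(B, 2, sd), spec = nm[-1]),
                class = "bootstrap_ensemble")
    }
    sc <- strain_compare(mk(), mk())
    any_rej[i] <- any(sc$p_adjusted < 0.05)
  }
  expect_lte(mean(any_rej), 0.05 + 3 * sqrt(0.05 * 0.95 / pairs))
})

test_that("simulate_first_exploit handles the degenerate rules", {
  one <- simulate_first_exploit(list(rep(1, 5)), n_draws = 500, seed = 1)
  expect_equal(unname(one$pmf[1]), 1)
  expect_equal(one$censored, 0)
  zero <- simulate_first_exploit(list(rep(0, 5)), n_draws = 500, seed = 1)
  expect_equal(zero$censored, 1)
  expect_message(simulate_first_exploit(list(numeric(0), c(0.5, 0.5)),
                                        n_draws = 10, seed = 1), "skipped")
  expect_error(simulate_first_exploit(list(numeric(0)), 10, 1), "non-empty")
})

test_that("predict_surface reflects the fitted coefficients", {
  beta_full <- c(intercept = -1, rho_k = 1, tau_s = 0.5, rho_h = -0.7,
                 rho_e = -0.2)
  fit_full <- structure(list(beta = beta_full, loglik = -1, n = 10,
                             spec = names(beta_full)[-1], lambda = 0),
                        class = "glm_fit")
  gk <- seq(-1, 2, length.out = 5)
  gh <- seq(-1, 2, length.out = 4)
  s <- predict_surface(fit_full, "rho_h", gk, gh,
                       fixed_values = list(tau_s = 0.3, rho_e = 0.1))
  expect_equal(dim(s), c(5L, 4L))
  # beta_h < 0: decreasing along rho_h; beta_k > 0: increasing along rho_k
  expect_true(all(apply(s, 1, diff) < 0))
  expect_true(all(apply(s, 2, diff) > 0))
  # spec without history terms: constant along the history axis
  beta_red <- beta_full[1:3]
  fit_red <- structure(list(beta = beta_red, loglik = -1, n = 10,
                            spec = c("rho_k", "tau_s"), lambda = 0),
                       class = "glm_fit")
  s2 <- predict_surface(fit_red, "rho_h", gk, gh,
                        fixed_values = list(tau_s = 0.3))
  expect_true(all(apply(s2, 1, function(r) max(r) - min(r)) == 0))
  # all-zero coefficients: surface identically 0.5
  fit0 <- fit_full
  fit0$beta[] <- 0
  s3 <- predict_surface(fit0, "rho_e", gk, gh,
                        fixed_values = list(tau_s = 0, rho_h = 0))
  expect_true(all(s3 == 0.5))
  expect_error(predict_surface(fit_full, "rho_h", gk, gh,
                               fixed_values = list(tau_s = 0.3)),
               "rho_e")
  expect_error(predict_surface(fit_red, "rho_h", gk, gh,
                               fixed_values = list(tau_s = 1, rho_e = 1)),
               "absent")
})

test_that("compare_likelihood degenerates and validates correctly", {
  g <- generate_covariate_dataset(n_worms = 20, encounters_per_worm = 6,
                                  seed = 16)
  f1 <- fit_soft_logistic(g$dataset, c("rho_k", "tau_s"))
  f2 <- fit_soft_logistic(g$dataset, c("rho_k", "tau_s"))
  same <- compare_likelihood(f1, f2)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 0L)
  expect_equal(same$p_value, 1)
  full <- fit_soft_logistic(g$dataset)
  expect_error(compare_likelihood(f1, full), "nested")
  # out-of-sample evaluation uses fixed coefficients
  g2 <- generate_covariate_dataset(n_worms = 10, encounters_per_worm = 6,
                                   seed = 17)
  cmp <- compare_likelihood(full, f1, dataset = g2$dataset)
  expect_equal(cmp$df, 2L)
  expect_true(is.finite(cmp$statistic))
})
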