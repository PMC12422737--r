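# Resampling inference for the exploitation model: encounter sampling
# (probabilistic inclusion of sensed encounters, with covariates rebuilt on
# the retained sequence), hierarchical worm bootstrap, the combined
# replicate ensemble, shuffle nulls, coefficient tests, and the mutant
# vs wild-type mean-of-differences Z comparison.

#' Encounter-sampled replicate datasets
#'
#' Per replicate, each encounter is retained with probability
#' p(v=1|w) (its `p_sense`); dropped encounters are removed and the
#' covariates of the retained sequence are rebuilt with
#' [build_covariates()], so the time a worm spent on a non-responding
#' encounter counts as off-food search time. Worms with no dropped
#' encounters keep their original covariate rows (the rebuild is the
#' identity there).
#'
#' @param dataset a `soft_label_dataset` with `p_sense` and the raw fields
#'   (`worm_id, entry_s, exit_s, density, q`).
#' @param n_sets number of replicates (default 100).
#' @param seed integer seed.
#' @param acclimation_density passed to the rebuild; defaults to the
#'   dataset's attribute.
#' @return list of `n_sets` soft_label_dataset replicates.
#' @export
encounter_sample <- function(dataset, n_sets = 100L, seed = 1L,
                             acclimation_density = NULL) {
  if (!"p_sense" %in% names(dataset)) stop_config("p_sense column required")
  acclimation_density <- acclimation_density %||%
    attr(dataset, "acclimation_density") %||% 10
  n <- nrow(dataset)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      keep <- stats::runif(n) < dataset$p_sense
      if (all(keep)) return(dataset)
      kept <- dataset[keep, , drop = FALSE]
      touched <- unique(dataset$worm_id[!keep])
      untouched <- kept[!kept$worm_id %in% touched, , drop = FALSE]
      redo <- kept[kept$worm_id %in% touched, , drop = FALSE]
      out <- if (nrow(redo))
        rbind(as.data.frame(untouched),
              as.data.frame(build_covariates(
                redo, acclimation_density = acclimation_density))[,
                  names(untouched)])
      else as.data.frame(untouched)
      out <- out[order(out$worm_id, out$entry_s), , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- c("soft_label_dataset", "data.frame")
      attr(out, "acclimation_density") <- acclimation_density
      out
    })
  })
}

#' Hierarchical worm bootstrap
#'
#' Resamples whole worms with replacement, preserving the original worm
#' count; duplicated worms contribute duplicated rows. Returns id samples,
#' not materialized datasets (the ensemble fitter indexes rows lazily).
#'
#' @param dataset a `soft_label_dataset` (>= 1 worm).
#' @param n_sets number of bootstrap samples (default 500).
#' @param seed integer seed.
#' @return list of worm-id vectors, each of the original worm count.
#' @export
worm_bootstrap <- function(dataset, n_sets = 500L, seed = 1L) {
  worms <- unique(dataset$worm_id)
  with_seed(seed, lapply(seq_len(n_sets), function(s)
    sample(worms, length(worms), replace = TRUE)))
}

#' Fit the full replicate ensemble
#'
#' Crosses `n_encounter_sets` encounter-sampled datasets with `n_worm_sets`
#' hierarchical worm-bootstrap samples (full analysis scale is 100 x 500 =
#' 50,000 replicates) and fits the soft-label logistic model on every
#' combination.
#'
#' @param dataset a `soft_label_dataset`.
#' @param spec covariate names.
#' @param n_encounter_sets,n_worm_sets replicate counts.
#' @param seed integer seed.
#' @param lambda ridge penalty for each fit.
#' @return object of class `bootstrap_ensemble`: `beta` (replicates x
#'   coefficients matrix), `provenance` (encounter-set and worm-set ids),
#'   `mean`, `sd`, `spec`.
#' @export
fit_ensemble <- function(dataset, spec = c("rho_k", "tau_s", "rho_h",
                                           "rho_e"),
                         n_encounter_sets = 100L, n_worm_sets = 500L,
                         seed = 1L, lambda = 0) {
  esets <- encounter_sample(dataset, n_encounter_sets,
                            seed = derive_seed(seed, 1L))
  wsets <- worm_bootstrap(dataset, n_worm_sets, seed = derive_seed(seed, 2L))
  p <- length(spec) + 1L
  B <- matrix(NA_real_, n_encounter_sets * n_worm_sets, p)
  prov <- matrix(NA_integer_, n_encounter_sets * n_worm_sets, 2L)
  r <- 0L
  for (e in seq_along(esets)) {
    ds <- esets[[e]]
    X <- design_matrix(ds, spec)
    q <- ds$q
    idx <- split(seq_len(nrow(ds)), ds$worm_id)
    # warm-start each bootstrap replicate at the encounter-set-wide optimum
    warm <- tryCatch(soft_logistic_engine(X, q, lambda = lambda)$beta,
                     error = function(e) NULL)
    for (w in seq_along(wsets)) {
      rows <- unlist(idx[as.character(wsets[[w]])], use.names = FALSE)
      r <- r + 1L
      fit <- soft_logistic_engine(X[rows, , drop = FALSE], q[rows],
                                  lambda = lambda, beta_init = warm)
      B[r, ] <- fit$beta
      prov[r, ] <- c(e, w)
    }
  }
  colnames(B) <- c("intercept", spec)
  structure(list(beta = B,
                 provenance = data.frame(encounter_set = prov[, 1],
                                         worm_set = prov[, 2]),
                 mean = colMeans(B), sd = apply(B, 2, stats::sd),
                 spec = spec),
            class = "bootstrap_ensemble")
}

#' Percentile bootstrap confidence intervals from an ensemble
#'
#' @param ensemble a `bootstrap_ensemble`.
#' @param level confidence level (default 0.95).
#' @return matrix with rows per coefficient and columns `lower, upper`.
#' @export
ensemble_ci <- function(ensemble, level = 0.95) {
  a <- (1 - level) / 2
  t(apply(ensemble$beta, 2, stats::quantile, probs = c(a, 1 - a),
          names = FALSE, type = 7))
}

#' Shuffle null ensemble for the exploitation coefficients
#'
#' Estimates the null coefficient distribution by permuting the response
#' vector q across rows and refitting.
#'
#' @param dataset a `soft_label_dataset`.
#' @param spec covariate names.
#' @param n_shuffles number of permutations.
#' @param seed integer seed.
#' @return matrix (n_shuffles x coefficients) of null fits.
#' @export
shuffle_null <- function(dataset, spec, n_shuffles = 500L, seed = 1L) {
  X <- design_matrix(dataset, spec)
  q <- dataset$q
  with_seed(seed, {
    B <- t(vapply(seq_len(n_shuffles), function(s)
      soft_logistic_engine(X, sample(q))$beta,
      numeric(ncol(X))))
    colnames(B) <- colnames(X)
    B
  })
}

#' Two-tailed one-sample bootstrap test on ensemble coefficients
#'
#' p = 2 min[P(beta <= 0), P(beta >= 0)] per coefficient, estimated from the
#' replicate ensemble, floored at 2/B (an all-one-sided ensemble cannot
#' resolve a smaller p), and Bonferroni-adjusted across coefficients.
#'
#' @param ensemble a `bootstrap_ensemble` or a replicates x coefficients
#'   matrix.
#' @return data.frame `coef, mean, sd, p, p_adjusted, at_floor`.
#' @export
coefficient_test <- function(ensemble) {
  B <- if (inherits(ensemble, "bootstrap_ensemble")) ensemble$beta
       else as.matrix(ensemble)
  nb <- nrow(B)
  if (nb < 100L) warning("fewer than 100 replicates: poor p-value resolution")
  p_raw <- apply(B, 2, function(b) 2 * min(mean(b <= 0), mean(b >= 0)))
  at_floor <- p_raw < 2 / nb
  p <- pmax(p_raw, 2 / nb)
  data.frame(coef = colnames(B), mean = colMeans(B),
             sd = apply(B, 2, stats::sd), p = p,
             p_adjusted = pmin(1, p * ncol(B)), at_floor = at_floor,
             row.names = NULL)
}

#' Compare coefficient ensembles between a mutant and wild type
#'
#' Mean-of-differences test Z = (mu_mutant - mu_wt) / sqrt(sd_mutant^2 +
#' sd_wt^2) per coefficient, with a left-tailed normal p-value Phi(Z) for
#' the density coefficients (rho_k, rho_h, rho_e: the mutant hypothesis is
#' reduced density sensitivity) and a two-tailed p-value for the others.
#' The default two-tailed rule is 2 Phi(-|Z|); `two_tail_literal = TRUE`
#' uses Phi(-|Z|) without the factor 2. Benjamini-Hochberg adjustment across
#' coefficients.
#'
#' @param ensemble_mutant,ensemble_wt `bootstrap_ensemble` objects with
#'   matching specs.
#' @param left_tail coefficient names tested left-tailed.
#' @param two_tail_literal use the literal single-Phi two-tailed variant.
#' @return data.frame `coef, z, tail, p, p_adjusted` (class
#'   `strain_comparison`).
#' @export
strain_compare <- function(ensemble_mutant, ensemble_wt,
                           left_tail = c("rho_k", "rho_h", "rho_e"),
                           two_tail_literal = FALSE) {
  if (!identical(colnames(ensemble_mutant$beta),
                 colnames(ensemble_wt$beta)))
    stop_config("ensembles have different coefficient specs")
  mu_m <- ensemble_mutant$mean; sd_m <- ensemble_mutant$sd
  mu_w <- ensemble_wt$mean; sd_w <- ensemble_wt$sd
  pooled <- sqrt(sd_m^2 + sd_w^2)
  if (any(pooled == 0)) stop_config("zero pooled variance: Z undefined")
  z <- (mu_m - mu_w) / pooled
  nm <- names(mu_m)
  is_left <- nm %in% left_tail
  p <- ifelse(is_left, stats::pnorm(z),
              (if (two_tail_literal) 1 else 2) * stats::pnorm(-abs(z)))
  out <- data.frame(coef = nm, z = z,
                    tail = ifelse(is_left, "left", "two"),
                    p = p, p_adjusted = stats::p.adjust(p, "BH"),
                    row.names = NULL)
  class(out) <- c("strain_comparison", "data.frame")
  out
}
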