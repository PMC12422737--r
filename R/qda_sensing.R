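# Sensing vs non-responding classification from the three velocity features
# w = (s, t, u): soft-weighted QDA, a replicated semi-supervised self-training
# loop seeded by bacteria-free true negatives and probabilistically drawn
# exploitation true positives, and marginalization over the censored features
# for encounters whose onset was not recorded.

# weighted Gaussian class moments; w1, w0 are per-row soft class weights
soft_qda_fit <- function(x, w1, w0, ridge_warn = TRUE) {
  x <- as.matrix(x); d <- ncol(x)
  n1 <- sum(w1); n0 <- sum(w0)
  if (n1 < d + 1 || n0 < d + 1)
    stop_config("each class needs total soft weight >= d + 1")
  moments <- function(w) {
    mu <- colSums(w * x) / sum(w)
    xc <- sweep(x, 2, mu)
    S <- crossprod(xc * sqrt(w)) / sum(w)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) {
      if (ridge_warn) warning("singular weighted covariance; ridged")
      S <- S + diag(1e-6 * (mean(diag(S)) + 1e-12), d)
    }
    list(mu = mu, S = S)
  }
  m1 <- moments(w1); m0 <- moments(w0)
  structure(list(mu1 = m1$mu, S1 = m1$S, mu0 = m0$mu, S0 = m0$S,
                 pi1 = n1 / (n1 + n0), pi0 = n0 / (n1 + n0)),
            class = "soft_qda")
}

#' Posterior of the positive class under a fitted QDA
#'
#' Gaussian class-conditional densities with the fitted soft priors; the
#' decision boundary is the quadratic surface where the two posteriors are
#' equal.
#'
#' @param model a `soft_qda` fit.
#' @param x matrix of feature rows.
#' @return posterior probabilities in [0,1].
#' @export
qda_posterior <- function(model, x) {
  x <- as.matrix(x)
  l1 <- log(model$pi1) + mvn_logdens(x, model$mu1, model$S1)
  l0 <- log(model$pi0) + mvn_logdens(x, model$mu0, model$S0)
  1 / (1 + exp(l0 - l1))
}

#' Fit a soft-labeled QDA and score the training rows
#'
#' Class means, covariances, and priors are computed with soft (weighted)
#' moments: row i contributes weight `labels_soft[i]` to the positive class
#' and `1 - labels_soft[i]` to the negative class. With all-0/1 labels this
#' reduces exactly to textbook QDA.
#'
#' @param features numeric matrix of rows to classify.
#' @param labels_soft values in [0,1], one per row.
#' @return list with `model` (a `soft_qda`) and `posterior` for the rows.
#' @export
qda_fit_predict <- function(features, labels_soft) {
  if (any(labels_soft < 0 | labels_soft > 1))
    stop_config("labels_soft must lie in [0,1]")
  model <- soft_qda_fit(features, labels_soft, 1 - labels_soft)
  list(model = model, posterior = qda_posterior(model, features))
}

# one semi-supervised QDA pass: hard-labeled seeds + soft self-training on
# the unlabeled rows; converges on total posterior variance
semi_qda <- function(x, pos_idx, neg_idx, tol = 1e-6, max_iter = 100L) {
  n <- nrow(x)
  lab <- rep(NA_real_, n)
  lab[pos_idx] <- 1; lab[neg_idx] <- 0
  unl <- which(is.na(lab))
  w1 <- ifelse(is.na(lab), 0, lab)
  w0 <- ifelse(is.na(lab), 0, 1 - lab)
  fit <- soft_qda_fit(x, w1, w0, ridge_warn = FALSE)
  pv_old <- Inf
  for (it in seq_len(max_iter)) {
    p_unl <- if (length(unl)) qda_posterior(fit, x[unl, , drop = FALSE])
      else numeric(0)
    pv <- sum(p_unl * (1 - p_unl))
    w1[unl] <- p_unl
    w0[unl] <- 1 - p_unl
    fit <- soft_qda_fit(x, w1, w0, ridge_warn = FALSE)
    if (abs(pv - pv_old) < tol) break
    pv_old <- pv
  }
  fit
}

#' Replicated semi-supervised sensing classification
#'
#' Seeds each replicate with hard labels: encounters on bacteria-free
#' (density 0) patches are true negatives, and exploitation encounters drawn
#' per replicate from Bern(p(y=1|z)) are true positives. The semi-supervised
#' QDA then self-trains on the remaining encounters (unlabeled rows re-enter
#' each refit with weight equal to their current posterior) until the total
#' posterior variance changes by < 1e-6 or 100 iterations. The final sensing
#' probability of every uncensored encounter is its QDA posterior averaged
#' across replicates. Start-censored encounters (biased w features) are
#' excluded from fitting and get NA here; see [marginalize_censored()].
#'
#' @param encounters encounter table with columns `s_k, t_k, u_k, density`
#'   and (optionally) `w_biased`.
#' @param exploit_posteriors an `exploit_posterior` or a numeric vector of
#'   p(y=1|z), one per encounter row.
#' @param n_replicates number of Bernoulli label draws (default 1000).
#' @param seed integer seed.
#' @return object of class `sensing_posterior`: `p` (NA for censored rows),
#'   `models` (per-replicate QDA fits), `features` (uncensored w matrix),
#'   `censored` logical, `quality` (seed-label misclassification rates).
#' @export
classify_sensing <- function(encounters, exploit_posteriors,
                             n_replicates = 1000L, seed = 1L) {
  p_y <- if (inherits(exploit_posteriors, "exploit_posterior"))
    exploit_posteriors$p else as.numeric(exploit_posteriors)
  stopifnot(length(p_y) == nrow(encounters))
  censored <- if ("w_biased" %in% names(encounters))
    as.logical(encounters$w_biased) else rep(FALSE, nrow(encounters))
  W <- as.matrix(encounters[, c("s_k", "t_k", "u_k")])
  unc <- which(!censored)
  if (!length(unc)) stop_config("no uncensored encounters")
  Wu <- W[unc, , drop = FALSE]
  dens_u <- encounters$density[unc]
  p_y_u <- p_y[unc]
  neg <- which(dens_u == 0)
  if (!length(neg))
    stop_config("no density-0 encounters: cannot seed true negatives")
  if (all(p_y_u[dens_u > 0] < .Machine$double.eps))
    stop_config("all exploit posteriors are 0: cannot seed true positives")
  post <- matrix(NA_real_, length(unc), n_replicates)
  models <- vector("list", n_replicates)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      pos <- which(stats::runif(length(unc)) < p_y_u & dens_u > 0)
      if (length(pos) < 4L) {   # degenerate draw; redraw deterministically
        pos <- utils::head(order(p_y_u, decreasing = TRUE), 4L)
      }
      fit <- semi_qda(Wu, pos, setdiff(neg, pos))
      models[[r]] <- fit
      post[, r] <- qda_posterior(fit, Wu)
    }
  })
  p <- rep(NA_real_, nrow(encounters))
  p[unc] <- rowMeans(post)
  quality <- list(
    false_sense_rate = mean(p[unc][dens_u == 0] >= 0.5),
    false_nonresponse_rate =
      if (any(p_y_u >= 0.5)) mean(p[unc][p_y_u >= 0.5] < 0.5) else NA_real_)
  structure(list(p = p, models = models, features = Wu,
                 censored = censored, n_replicates = n_replicates,
                 quality = quality),
            class = "sensing_posterior")
}

#' Marginalize the sensing posterior over censored features
#'
#' For encounters recorded from inside the patch the deceleration `t` and
#' velocity-change `u` features are biased; only the minimum on-patch
#' velocity `s` is trusted. The sensing probability is then
#' p(v=1|s) = int int p(v=1|s,t,u) p(t,u|s) dt du, where p(v=1|s,t,u) is the
#' replicate-averaged QDA posterior and p(t,u|s) is a product-Gaussian-kernel
#' conditional KDE built from the uncensored encounters (slice at `s`,
#' renormalized). Integration is adaptive quadrature (nested
#' `stats::integrate`) to absolute tolerance `abs_tol`; the result is clipped
#' to [0,1]. Zero bandwidths give the exact discrete mixture (point-mass
#' conditional density).
#'
#' @param sensing a `sensing_posterior`.
#' @param s_k trusted minimum-velocity value of the censored encounter.
#' @param bandwidths optional c(h_s, h_t, h_u); defaults to `bw.nrd0` per
#'   dimension of the uncensored features.
#' @param abs_tol quadrature absolute tolerance.
#' @param min_eff_n below this effective sample size of the `s`-conditioning
#'   weights, fall back to the unconditional joint with a warning.
#' @return marginalized sensing probability in [0,1].
#' @export
marginalize_censored <- function(sensing, s_k, bandwidths = NULL,
                                 abs_tol = 1e-4, min_eff_n = 5) {
  stopifnot(inherits(sensing, "sensing_posterior"))
  Wu <- sensing$features
  if (is.null(bandwidths))
    bandwidths <- apply(Wu, 2, stats::bw.nrd0)
  h_s <- bandwidths[1]; h_t <- bandwidths[2]; h_u <- bandwidths[3]
  if (h_s > 0) {
    w <- stats::dnorm(s_k - Wu[, 1], sd = h_s)
    if (sum(w) <= 0 || (sum(w)^2 / sum(w^2)) < min_eff_n) {
      warning("too few uncensored encounters near s_k; ",
              "using unconditional joint of (t, u)")
      w <- rep(1, nrow(Wu))
    }
  } else {
    w <- as.numeric(Wu[, 1] == s_k)   # degenerate conditioning kernel
    if (sum(w) == 0)
      stop_config("h_s = 0 and no uncensored encounter has s = s_k")
  }
  w <- w / sum(w)
  post_fn <- function(tt, uu) {  # replicate-averaged posterior at (s_k,t,u)
    x <- cbind(s_k, tt, uu)
    v <- vapply(sensing$models, qda_posterior, numeric(nrow(x)), x = x)
    if (is.matrix(v)) rowMeans(v) else mean(v)
  }
  if (h_t <= 0 && h_u <= 0)  # degenerate conditional: exact discrete sum
    return(min(1, max(0, sum(w * post_fn(Wu[, 2], Wu[, 3])))))
  t_lim <- range(Wu[, 2]) + c(-6, 6) * h_t
  u_lim <- range(Wu[, 3]) + c(-6, 6) * h_u
  inner <- function(tt) {  # integral over u at fixed t, times p(t|s)
    vapply(tt, function(t1) {
      kt <- w * stats::dnorm(t1 - Wu[, 2], sd = h_t)
      stats::integrate(function(uu)
        vapply(uu, function(u1)
          sum(kt * stats::dnorm(u1 - Wu[, 3], sd = h_u)) *
            post_fn(t1, u1), numeric(1)),
        u_lim[1], u_lim[2], abs.tol = abs_tol / 50,
        subdivisions = 200L)$value
    }, numeric(1))
  }
  val <- stats::integrate(inner, t_lim[1], t_lim[2], abs.tol = abs_tol / 5,
                          subdivisions = 200L)$value
  min(1, max(0, val))
}

#' Exclude unsensed near-miss encounters
#'
#' Drops encounters whose midpoint never entered the patch AND whose sensing
#' probability is below `cutoff` (default 5%). The rule is conjunctive:
#' either condition alone keeps the encounter.
#'
#' @param encounters encounter table with a `midpoint_entered` column.
#' @param sensing_posteriors numeric p(v=1|w) per row.
#' @param cutoff exclusion threshold.
#' @return filtered encounter table.
#' @export
exclude_low_sensing <- function(encounters, sensing_posteriors,
                                cutoff = 0.05) {
  stopifnot("midpoint_entered" %in% names(encounters),
            length(sensing_posteriors) == nrow(encounters))
  drop <- !encounters$midpoint_entered &
    !is.na(sensing_posteriors) & sensing_posteriors < cutoff
  out <- encounters[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify all encounters: exploitation, sensing, and the three-way taxonomy
#'
#' Orchestrates the per-encounter classifiers: fits the exploit GMM on
#' (log_dur, log_vel), runs the replicated semi-supervised sensing QDA,
#' marginalizes censored encounters over (t, u), applies the 5% near-miss
#' exclusion, and composes the three-way probabilities
#' search = 1 - p_sense, sample = p_sense (1 - p_exploit),
#' exploit = p_sense p_exploit.
#'
#' @param encounters encounter table from [detect_encounters()].
#' @param alpha_grid,n_folds passed to [fit_exploit_gmm()].
#' @param n_replicates passed to [classify_sensing()].
#' @param seed integer seed.
#' @return list with `encounters` (classified, filtered table gaining
#'   p_exploit, p_sense, marginalized, p_search, p_sample, p_exploit_total),
#'   `gmm`, `sensing`.
#' @export
classify_encounters <- function(encounters,
                                alpha_grid = c(0.005, 0.01, 0.025, 0.05,
                                               0.1),
                                n_folds = 5L, n_replicates = 1000L,
                                seed = 1L) {
  z <- as.matrix(encounters[, c("log_dur", "log_vel")])
  gmm <- fit_exploit_gmm(z, alpha_grid, n_folds, seed = derive_seed(seed, 1L))
  sens <- classify_sensing(encounters, gmm, n_replicates,
                           seed = derive_seed(seed, 2L))
  p_sense <- sens$p
  marginalized <- is.na(p_sense)
  for (i in which(marginalized))
    p_sense[i] <- marginalize_censored(sens, encounters$s_k[i])
  out <- encounters
  out$p_exploit <- gmm$p
  out$p_sense <- p_sense
  out$marginalized <- marginalized
  out <- exclude_low_sensing(out, out$p_sense)
  out$p_search <- 1 - out$p_sense
  out$p_sample <- out$p_sense * (1 - out$p_exploit)
  out$p_exploit_total <- out$p_sense * out$p_exploit
  list(encounters = out, gmm = gmm, sensing = sens)
}
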