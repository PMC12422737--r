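# Soft-label logistic regression: the exploit decision model. The response
# is a classifier posterior q_k in [0,1] rather than a binary outcome;
# maximizing sum_k q_k log p_k + (1 - q_k) log(1 - p_k) is equivalent (up to
# an additive constant) to minimizing the KL divergence from the classifier
# posterior to the model probability, and reduces to the standard Bernoulli
# MLE when q is binary. Optional ridge penalty on the (standardized,
# non-intercept) coefficients.

GLM_COVARIATES <- c("rho_k", "tau_s", "rho_h", "rho_e", "tau_t")

soft_loglik <- function(eta, q) {
  # numerically safe q*log(p) + (1-q)*log(1-p)
  sum(q * stats::plogis(eta, log.p = TRUE) +
        (1 - q) * stats::plogis(-eta, log.p = TRUE))
}

# Newton solver on standardized covariates; lambda penalizes standardized
# non-intercept coefficients (objective: loglik - lambda * ||beta_-0||^2)
soft_logistic_engine <- function(X, q, lambda = 0, grad_tol = 1e-8,
                                 max_iter = 200L, beta_init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(q) != n) stop_config("response length mismatch")
  if (any(q < 0 | q > 1)) stop_config("soft labels must lie in [0,1]")
  if (lambda == 0) {  # the ridge penalty makes deficient designs well-posed
    qrX <- qr(X)
    if (qrX$rank < p) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
      stop("design matrix rank deficient; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  ctr <- colMeans(X); ctr[1] <- 0
  scl <- apply(X, 2, stats::sd); scl[1] <- 1
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pen <- c(0, rep(2 * lambda, p - 1L))
  beta <- numeric(p)
  if (!is.null(beta_init)) {  # warm start, given on the original scale
    beta <- beta_init * scl
    beta[1] <- beta_init[1] + sum(beta_init[-1] * ctr[-1])
  }
  obj <- function(b) soft_loglik(Xs %*% b, q) - sum(pen / 2 * b^2)
  f_old <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xs %*% beta)
    mu <- logistic(eta)
    g <- as.numeric(crossprod(Xs, q - mu)) - pen * beta
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xs * sqrt(w)) + diag(pen, p)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, p), g))
    t_ <- 1
    repeat {
      f_new <- obj(beta + t_ * step)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-10) break
    }
    beta <- beta + t_ * step
    f_old <- obj(beta)
    if (lambda == 0 && any(abs(beta) > 40))
      stop("separation detected (coefficients diverging); ",
           "consider ridge regularization via fit_ridge()", call. = FALSE)
  }
  if (!converged) {
    eta <- as.numeric(Xs %*% beta)
    g <- as.numeric(crossprod(Xs, q - logistic(eta))) - pen * beta
    if (max(abs(g)) > 1e-4)
      stop("soft logistic fit did not converge (|grad| = ",
           signif(max(abs(g)), 3), ")", call. = FALSE)
  }
  b_orig <- beta / scl
  b_orig[1] <- beta[1] - sum(beta[-1] * ctr[-1] / scl[-1])
  names(b_orig) <- colnames(X)
  list(beta = b_orig,
       loglik = soft_loglik(as.numeric(X %*% b_orig), q),
       converged = TRUE)
}

design_matrix <- function(dataset, spec) {
  bad <- setdiff(spec, names(dataset))
  if (length(bad)) stop_config("unknown covariates: ",
                               paste(bad, collapse = ", "))
  X <- cbind(intercept = rep(1, nrow(dataset)),
             as.matrix(as.data.frame(dataset)[, spec, drop = FALSE]))
  colnames(X) <- c("intercept", spec)
  X
}

#' Fit the soft-label logistic exploitation model
#'
#' Maximizes the soft log-likelihood
#' sum_k q_k log p_k + (1 - q_k) log(1 - p_k), p_k = logistic(beta . x_k),
#' by damped Newton iteration (covariates standardized internally;
#' coefficients reported on the original scale). Equivalent to minimizing
#' sum_k KL(q_k || p_k). With binary q this is the standard logistic MLE.
#'
#' @param dataset a `soft_label_dataset` (or data.frame with the covariate
#'   columns and a `q` column).
#' @param spec character vector of covariate names to include (intercept is
#'   always included); subset of rho_k, tau_s, rho_h, rho_e, tau_t.
#' @param lambda ridge penalty on standardized non-intercept coefficients
#'   (0 = plain maximum likelihood).
#' @param q optional response override (defaults to `dataset$q`).
#' @return object of class `glm_fit`: `beta` (named), `loglik` (unpenalized
#'   soft log-likelihood), `n`, `spec`, `lambda`.
#' @export
fit_soft_logistic <- function(dataset, spec = c("rho_k", "tau_s", "rho_h",
                                                "rho_e"),
                              lambda = 0, q = NULL) {
  q <- q %||% dataset$q
  X <- design_matrix(dataset, spec)
  fit <- soft_logistic_engine(X, q, lambda = lambda)
  structure(list(beta = fit$beta, loglik = fit$loglik, n = nrow(X),
                 spec = spec, lambda = lambda),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Soft-label logistic fit (n =", x$n, ", lambda =", x$lambda, ")\n")
  print(signif(x$beta, 5))
  cat("soft log-likelihood:", signif(x$loglik, 6),
      " BIC:", signif(bic(x), 6), "\n")
  invisible(x)
}

#' Soft log-likelihood of a fitted model on a dataset
#'
#' Evaluates the fitted coefficients on (possibly new) data without
#' refitting.
#'
#' @param fit a `glm_fit`.
#' @param dataset dataset with the fit's covariates and `q`.
#' @param q optional response override.
#' @return scalar soft log-likelihood.
#' @export
loglik_soft <- function(fit, dataset, q = NULL) {
  q <- q %||% dataset$q
  X <- design_matrix(dataset, fit$spec)
  soft_loglik(as.numeric(X %*% fit$beta), q)
}

#' Bayesian information criterion of a soft-label fit
#'
#' BIC = -2 * loglik + p * ln(n); lower is better.
#'
#' @param fit a `glm_fit`.
#' @return scalar BIC.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  -2 * fit$loglik + length(fit$beta) * log(fit$n)
}

#' Rank covariate specifications by BIC
#'
#' Fits each specification on the same rows and ranks by BIC (ascending).
#'
#' @param dataset a `soft_label_dataset`.
#' @param specs named list of covariate-name vectors (use `character(0)` for
#'   the intercept-only model).
#' @param lambda ridge penalty applied to every fit.
#' @return data.frame `spec_id, df, loglik, bic, rank`, sorted by BIC.
#' @export
model_select <- function(dataset, specs, lambda = 0) {
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s)
      if (length(s)) paste(s, collapse = "+") else "intercept", "")
  rows <- lapply(names(specs), function(id) {
    f <- fit_soft_logistic(dataset, specs[[id]], lambda = lambda)
    data.frame(spec_id = id, df = length(f$beta), loglik = f$loglik,
               bic = bic(f))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bic), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Ridge-regularized soft-label fit and cross-validated penalty selection
#'
#' `fit_ridge()` maximizes soft log-likelihood minus
#' lambda * ||beta_-0||^2 (intercept unpenalized, covariates standardized
#' internally); `lambda = 0` reduces exactly to [fit_soft_logistic()].
#' `cv_lambda()` picks the grid value maximizing the mean held-out soft
#' log-likelihood across worm-level folds; ties go to the smaller lambda.
#'
#' @param dataset a `soft_label_dataset`.
#' @param spec covariate names.
#' @param lambda ridge penalty (>= 0).
#' @return `fit_ridge()`: a `glm_fit`.
#' @export
fit_ridge <- function(dataset, spec, lambda) {
  if (lambda < 0) stop_config("lambda must be >= 0")
  fit_soft_logistic(dataset, spec, lambda = lambda)
}

#' @rdname fit_ridge
#' @param grid candidate lambda values.
#' @param n_folds number of cross-validation folds (worm-level).
#' @param seed integer seed for fold assignment.
#' @return `cv_lambda()`: list with `lambda` (the selected value) and `cv`
#'   (grid table of mean held-out log-likelihood).
#' @export
cv_lambda <- function(dataset, spec, grid, n_folds = 5L, seed = 1L) {
  if (!length(grid)) stop_config("empty lambda grid")
  grid <- sort(grid)
  worms <- unique(dataset$worm_id)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(n_folds),
                                            length(worms))))
  names(fold_of) <- worms
  fold <- fold_of[as.character(dataset$worm_id)]
  score <- vapply(grid, function(l) {
    mean(vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (sum(tr) < length(spec) + 2 || sum(!tr) == 0) return(NA_real_)
      fit <- tryCatch(fit_soft_logistic(dataset[tr, , drop = FALSE], spec,
                                        lambda = l),
                      error = function(e) NULL)  # e.g. separation at l = 0
      if (is.null(fit)) return(NA_real_)
      loglik_soft(fit, dataset[!tr, , drop = FALSE]) / sum(!tr)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(lambda = grid[which.max(score)],
       cv = data.frame(lambda = grid, mean_holdout_loglik = score))
}

#' Likelihood-ratio comparison of nested specifications
#'
#' 2 (LL_full - LL_reduced) with df equal to the parameter difference and a
#' chi-squared p-value. When `dataset` is supplied, both fits are evaluated
#' on it with coefficients held fixed (out-of-sample comparison, no
#' refitting); otherwise the stored in-sample log-likelihoods are used (the
#' two fits must then be on the same rows).
#'
#' @param fit_full,fit_reduced `glm_fit` objects; `fit_reduced$spec` must be
#'   nested in `fit_full$spec`.
#' @param dataset optional common evaluation dataset.
#' @return list `statistic, df, p_value`.
#' @export
compare_likelihood <- function(fit_full, fit_reduced, dataset = NULL) {
  if (!all(fit_reduced$spec %in% fit_full$spec))
    stop_config("specifications are not nested")
  df <- length(fit_full$beta) - length(fit_reduced$beta)
  if (is.null(dataset)) {
    if (fit_full$n != fit_reduced$n)
      stop_config("fits are on different row sets")
    ll_f <- fit_full$loglik; ll_r <- fit_reduced$loglik
  } else {
    ll_f <- loglik_soft(fit_full, dataset)
    ll_r <- loglik_soft(fit_reduced, dataset)
  }
  stat <- 2 * (ll_f - ll_r)
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE)
       else as.numeric(stat <= 0)
  list(statistic = stat, df = df, p_value = p)
}
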