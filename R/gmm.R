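# Two-component Gaussian mixture on (log duration, log mean on-patch
# velocity) giving each encounter a posterior probability of exploitation.
# Covariances carry a ridge regularizer alpha chosen by cross-validation to
# minimize the held-out posterior variance sum p(1-p).

# log density of rows of x under N(mu, sigma)
mvn_logdens <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(sigma + diag(1e-8, d))
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# one EM run; z is n x d, alpha a ridge added to covariance diagonals
em_gmm2 <- function(z, alpha, init_cluster, tol = 1e-8, max_iter = 1000L) {
  n <- nrow(z); d <- ncol(z)
  resp <- cbind(as.numeric(init_cluster == 1L),
                as.numeric(init_cluster == 2L))
  resp <- pmax(resp, 0.05); resp <- resp / rowSums(resp)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- colSums(resp)
    if (any(nk < d + 1)) return(NULL)  # emptied component
    w <- nk / n
    mus <- lapply(1:2, function(k) colSums(resp[, k] * z) / nk[k])
    covs <- lapply(1:2, function(k) {
      zc <- sweep(z, 2, mus[[k]])
      crossprod(zc * sqrt(resp[, k])) / nk[k] + diag(alpha, d)
    })
    lg <- vapply(1:2, function(k)
      log(w[k]) + mvn_logdens(z, mus[[k]], covs[[k]]), numeric(n))
    m <- pmax(lg[, 1], lg[, 2])
    lse <- m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m))
    ll <- sum(lse)
    resp <- exp(lg - lse)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(weights = w, means = mus, covs = covs, resp = resp, loglik = ll)
}

fit_gmm2 <- function(z, alpha, seed = NULL, n_restarts = 10L) {
  with_seed(seed, {
    km <- tryCatch(stats::kmeans(z, 2L, nstart = n_restarts),
                   error = function(e) NULL)
    fit <- if (!is.null(km)) em_gmm2(z, alpha, km$cluster) else NULL
    tries <- 0L
    while (is.null(fit) && tries < 5L) {
      tries <- tries + 1L
      fit <- em_gmm2(z, alpha, sample(1:2, nrow(z), replace = TRUE))
    }
    if (is.null(fit))
      stop("GMM EM failed to converge across restarts", call. = FALSE)
    fit
  })
}

#' Fit the exploit/explore Gaussian mixture
#'
#' Fits a two-component full-covariance GMM to the encounter feature matrix
#' `z = (log duration, log mean on-patch velocity)`, with regularization
#' `alpha` added to the covariance diagonals. `alpha` is chosen from
#' `alpha_grid` by k-fold cross-validation to minimize the held-out posterior
#' variance sum_k p(y_k=1|z_k) p(y_k=0|z_k); ties go to the smaller alpha.
#' The component with the larger mean log-duration is labeled "exploit".
#'
#' @param z_matrix numeric matrix, rows = encounters (>= 10), columns
#'   (log_dur, log_vel).
#' @param alpha_grid positive regularization values (default includes 0.025,
#'   a widely useful default for worm-assay features; a single-point grid skips CV).
#' @param n_folds CV folds.
#' @param seed integer seed.
#' @return object of class `exploit_posterior`: list with `p` (posterior
#'   exploitation probability per row), `means`, `covs`, `weights`,
#'   `exploit_component`, `alpha`, `posterior_variance`, `cv` table.
#' @export
fit_exploit_gmm <- function(z_matrix,
                            alpha_grid = c(0.005, 0.01, 0.025, 0.05, 0.1),
                            n_folds = 5L, seed = 1L) {
  z <- as.matrix(z_matrix)
  if (nrow(z) < 10L) stop_config("need >= 10 encounters")
  if (any(alpha_grid <= 0)) stop_config("alpha_grid must be positive")
  cv_tab <- NULL
  if (length(alpha_grid) > 1L) {
    n <- nrow(z)
    folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
    score <- vapply(alpha_grid, function(a) {
      pv <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        fit <- fit_gmm2(z[tr, , drop = FALSE], a,
                        seed = derive_seed(seed, f))
        p <- gmm_posterior(fit, z[!tr, , drop = FALSE])
        mean(p * (1 - p))
      }, numeric(1))
      mean(pv)
    }, numeric(1))
    cv_tab <- data.frame(alpha = alpha_grid, posterior_variance = score)
    alpha <- alpha_grid[which.min(score)]  # which.min: first = smallest tie
  } else alpha <- alpha_grid[1]
  fit <- fit_gmm2(z, alpha, seed = derive_seed(seed, 99L))
  p <- gmm_posterior(fit, z)
  structure(list(p = p, means = fit$means, covs = fit$covs,
                 weights = fit$weights,
                 exploit_component = exploit_component(fit),
                 alpha = alpha, posterior_variance = sum(p * (1 - p)),
                 loglik = fit$loglik, cv = cv_tab),
            class = "exploit_posterior")
}

# semantic labeling: exploit = component with larger mean log-duration
exploit_component <- function(fit) {
  if (fit$means[[1]][1] >= fit$means[[2]][1]) 1L else 2L
}

# posterior probability of the exploit component for rows of z
gmm_posterior <- function(fit, z) {
  z <- as.matrix(z)
  lg <- vapply(1:2, function(k)
    log(fit$weights[k]) + mvn_logdens(z, fit$means[[k]], fit$covs[[k]]),
    numeric(nrow(z)))
  ke <- exploit_component(fit)
  1 / (1 + exp(lg[, 3L - ke] - lg[, ke]))
}

#' @export
print.exploit_posterior <- function(x, ...) {
  cat("Two-component GMM exploit classifier\n")
  cat("  alpha =", x$alpha, " n =", length(x$p),
      " total posterior variance =", signif(x$posterior_variance, 4), "\n")
  cat("  exploit component mean (log_dur, log_vel): ",
      paste(signif(x$means[[x$exploit_component]], 4), collapse = ", "),
      "\n")
  invisible(x)
}
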