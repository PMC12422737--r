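# Model-derived predictions: first-exploitation distributions over encounter
# number, and exploitation-probability surfaces over density grids.

#' Simulate the distribution of the first exploitation
#'
#' Walks each worm's ordered per-encounter exploitation probabilities,
#' drawing Bernoulli(p_k) at every step and recording the index of the first
#' success (or censoring at the sequence end). Under a constant p this mass
#' is geometric, P(k) = p (1 - p)^(k - 1).
#'
#' @param probabilities_by_encounter list of numeric probability vectors,
#'   one per worm (empty sequences are skipped with a note).
#' @param n_draws simulated walks per sequence.
#' @param seed integer seed.
#' @return list with `pmf` (probability mass over encounter index 1..K_max),
#'   `censored` (mass with no exploitation before the sequence end), and
#'   `n_draws_total`.
#' @export
simulate_first_exploit <- function(probabilities_by_encounter, n_draws,
                                   seed = 1L) {
  if (!is.list(probabilities_by_encounter))
    probabilities_by_encounter <- list(probabilities_by_encounter)
  seqs <- probabilities_by_encounter
  empty <- vapply(seqs, length, integer(1)) == 0L
  if (any(empty)) {
    message(sum(empty), " empty probability sequence(s) skipped")
    seqs <- seqs[!empty]
  }
  if (!length(seqs)) stop_config("no non-empty probability sequences")
  kmax <- max(vapply(seqs, length, integer(1)))
  counts <- numeric(kmax + 1L)  # last slot = censored
  with_seed(seed, {
    for (p in seqs) {
      K <- length(p)
      hit <- matrix(stats::runif(n_draws * K), n_draws, K) <
        matrix(p, n_draws, K, byrow = TRUE)
      first <- max.col(cbind(hit, TRUE), ties.method = "first")
      first[first == K + 1L] <- kmax + 1L
      tab <- tabulate(first, nbins = kmax + 1L)
      counts <- counts + tab
    }
  })
  total <- sum(counts)
  list(pmf = stats::setNames(counts[seq_len(kmax)] / total,
                             seq_len(kmax)),
       censored = counts[kmax + 1L] / total,
       n_draws_total = total)
}

#' Exploitation-probability surface over a density grid
#'
#' Evaluates logistic(beta . x) on a grid of (rho_k x axis1), with the
#' remaining covariates held at `fixed_values` (typically the dataset
#' averages). If the fit's specification omits the requested history axis,
#' the surface is constant along it — absent covariates have no effect.
#'
#' @param fit a `glm_fit` containing `rho_k`.
#' @param axis1 "rho_h" or "rho_e".
#' @param rho_k_grid,axis1_grid grid values (log densities).
#' @param fixed_values named list/vector of values for the fit's remaining
#'   covariates; every non-axis covariate in the spec must be supplied.
#' @return matrix of probabilities, rows = rho_k_grid, cols = axis1_grid.
#' @export
predict_surface <- function(fit, axis1 = c("rho_h", "rho_e"), rho_k_grid,
                            axis1_grid, fixed_values = list()) {
  axis1 <- match.arg(axis1)
  if (!"rho_k" %in% fit$spec) stop_config("fit does not contain rho_k")
  others <- setdiff(fit$spec, c("rho_k", axis1))
  miss <- setdiff(others, names(fixed_values))
  if (length(miss))
    stop_config("fixed_values missing covariates: ",
                paste(miss, collapse = ", "))
  unknown <- setdiff(names(fixed_values), fit$spec)
  if (length(unknown))
    stop_config("fixed_values name covariates absent from the fit: ",
                paste(unknown, collapse = ", "))
  g <- expand.grid(rho_k = rho_k_grid, a1 = axis1_grid)
  X <- matrix(0, nrow(g), length(fit$beta),
              dimnames = list(NULL, names(fit$beta)))
  X[, "intercept"] <- 1
  X[, "rho_k"] <- g$rho_k
  if (axis1 %in% fit$spec) X[, axis1] <- g$a1
  for (nm in others) X[, nm] <- fixed_values[[nm]]
  matrix(logistic(as.numeric(X %*% fit$beta)),
         nrow = length(rho_k_grid),
         dimnames = list(signif(rho_k_grid, 6), signif(axis1_grid, 6)))
}
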