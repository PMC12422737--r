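# Sequential covariate construction for the exploitation model. Per worm,
# in time order: rho_k = ln(relative density of the encountered patch),
# tau_s = hours spent off food since the last realized exploitation
# (elapsed time minus on-patch time; for the first encounter, the total
# elapsed time), rho_h = ln density of the immediately previous retained
# encounter, rho_e = ln density of the last realized-exploited patch, and
# tau_t = hours since the recording started. rho_h and rho_e are initialized
# from the acclimation-plate density.

#' Build the exploitation-model covariates from classified encounters
#'
#' Encounters on bacteria-free (density 0) patches are excluded from the
#' returned rows — they seed the sensing classifier's negatives but never
#' enter the GLM (the log transform is undefined); their dwell time counts
#' as off-food search time, exactly like encounters dropped by encounter
#' sampling. Supply `pseudo_density` to instead retain them with a
#' substitute density. Negative densities are an input error.
#'
#' Realized exploitations (which reset tau_s and update rho_e) are declared
#' deterministically where the soft label q >= `q_threshold` (default mode),
#' or drawn as Bernoulli(q) with `exploit_rule = "bernoulli"`.
#'
#' @param encounters data.frame with `worm_id, entry_s, exit_s, density` and
#'   a soft exploitation label column `q` (or `p_exploit`); optionally
#'   `p_sense`.
#' @param acclimation_density relative density initializing rho_h and rho_e.
#' @param exploit_rule "threshold" or "bernoulli".
#' @param q_threshold realized-exploit cutoff for the threshold rule.
#' @param seed integer seed (bernoulli rule only).
#' @param pseudo_density optional substitute density for density-0 rows.
#' @return a `soft_label_dataset` data.frame: worm_id, k, entry_s, exit_s,
#'   density, q, p_sense, rho_k, tau_s, rho_h, rho_e, tau_t.
#' @export
build_covariates <- function(encounters, acclimation_density = 10,
                             exploit_rule = c("threshold", "bernoulli"),
                             q_threshold = 0.5, seed = NULL,
                             pseudo_density = NULL) {
  exploit_rule <- match.arg(exploit_rule)
  enc <- as.data.frame(encounters)
  if (!"q" %in% names(enc)) {
    if ("p_exploit" %in% names(enc)) enc$q <- enc$p_exploit
    else stop_config("encounters need a soft label column `q` or `p_exploit`")
  }
  if (!"p_sense" %in% names(enc)) enc$p_sense <- 1
  if (any(enc$density < 0)) stop_config("negative relative density")
  if (!is.null(pseudo_density)) {
    enc$density[enc$density == 0] <- pseudo_density
  } else {
    enc <- enc[enc$density > 0, , drop = FALSE]
  }
  if (acclimation_density <= 0) stop_config("acclimation_density must be > 0")
  build <- function() {
    rows <- lapply(split(enc, enc$worm_id), function(e) {
      e <- e[order(e$entry_s), , drop = FALSE]
      nk <- nrow(e)
      rho_h <- rho_e <- log(acclimation_density)
      off_hr <- 0; last_exit <- 0
      out <- data.frame(worm_id = e$worm_id, k = seq_len(nk),
                        entry_s = e$entry_s, exit_s = e$exit_s,
                        density = e$density, q = e$q, p_sense = e$p_sense,
                        rho_k = log(e$density), tau_s = NA_real_,
                        rho_h = NA_real_, rho_e = NA_real_,
                        tau_t = e$entry_s / 3600)
      for (k in seq_len(nk)) {
        tau_s <- off_hr + (e$entry_s[k] - last_exit) / 3600
        out$tau_s[k] <- tau_s
        out$rho_h[k] <- rho_h
        out$rho_e[k] <- rho_e
        expl <- if (exploit_rule == "threshold") e$q[k] >= q_threshold
                else stats::runif(1) < e$q[k]
        rho_h <- log(e$density[k])
        if (expl) { rho_e <- log(e$density[k]); off_hr <- 0 }
        else off_hr <- tau_s
        last_exit <- e$exit_s[k]
      }
      out
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  }
  df <- if (exploit_rule == "bernoulli") with_seed(seed, build()) else build()
  class(df) <- c("soft_label_dataset", "data.frame")
  attr(df, "acclimation_density") <- acclimation_density
  df
}
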