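# Synthetic foraging worlds: arenas, patch layouts, agent-based worm
# trajectories, and covariate-level datasets with known ground truth.

#' Construct an arena with bacterial patches
#'
#' Builds the patch geometry for a foraging assay. The multi-patch layout is
#' an isometric (hexagonal) grid of 19 circular patches of radius 0.9 mm
#' spaced 6 mm apart inside a 30 mm diameter arena; the single-patch layout
#' is one centered patch inside a 9 mm diameter arena.
#'
#' @param layout_kind one of "isometric_grid", "single_patch", "custom".
#' @param density_condition dimensionless relative density assigned to every
#'   patch (>= 0).
#' @param seed integer seed (layouts are deterministic; kept for interface
#'   uniformity).
#' @param patches for `layout_kind = "custom"`, a data.frame with columns
#'   `patch_id, x, y, radius, density`.
#' @param arena_radius arena radius in mm; defaults depend on layout.
#' @return an object of class `arena_spec`: list with `arena_radius`,
#'   `patches` (data.frame), `layout_kind`, `grid_spacing`.
#' @export
generate_world <- function(layout_kind = c("isometric_grid", "single_patch",
                                           "custom"),
                           density_condition = 10, seed = 1L,
                           patches = NULL, arena_radius = NULL) {
  if (!is.character(layout_kind) ||
      !layout_kind[1] %in% c("isometric_grid", "single_patch", "custom"))
    stop_config("unknown layout_kind: ", layout_kind[1])
  layout_kind <- layout_kind[1]
  if (density_condition < 0) stop_config("density_condition must be >= 0")
  spacing <- 6
  if (layout_kind == "isometric_grid") {
    arena_radius <- arena_radius %||% 15
    # hexagonal grid: center + two rings = 19 patches
    a <- c(spacing, 0)
    b <- c(spacing / 2, spacing * sqrt(3) / 2)
    centers <- do.call(rbind, lapply(-2:2, function(i) {
      do.call(rbind, lapply(-2:2, function(j) c(i * a[1] + j * b[1],
                                                i * a[2] + j * b[2])))
    }))
    keep <- sqrt(rowSums(centers^2)) <= 2 * spacing + 1e-9
    centers <- centers[keep, , drop = FALSE]
    centers <- centers[order(centers[, 2], centers[, 1]), , drop = FALSE]
    pat <- data.frame(patch_id = seq_len(nrow(centers)),
                      x = centers[, 1], y = centers[, 2],
                      radius = 0.9, density = density_condition)
  } else if (layout_kind == "single_patch") {
    arena_radius <- arena_radius %||% 4.5
    pat <- data.frame(patch_id = 1L, x = 0, y = 0, radius = 0.9,
                      density = density_condition)
  } else {
    if (is.null(patches)) stop_config("custom layout requires `patches`")
    need <- c("patch_id", "x", "y", "radius", "density")
    if (!all(need %in% names(patches)))
      stop_config("custom patches need columns: ", paste(need, collapse = ", "))
    arena_radius <- arena_radius %||% 15
    pat <- as.data.frame(patches)[, need]
  }
  if (any(pat$radius <= 0)) stop_config("patch radii must be > 0")
  if (any(pat$density < 0)) stop_config("relative densities must be >= 0")
  if (any(sqrt(pat$x^2 + pat$y^2) + pat$radius > arena_radius + 1e-9))
    stop_config("patches must lie fully inside the arena")
  structure(list(arena_radius = arena_radius, patches = pat,
                 layout_kind = layout_kind, grid_spacing = spacing,
                 seed = as.integer(seed)),
            class = "arena_spec")
}

#' Behavioral parameters for the foraging simulator
#'
#' Defaults reproduce the stated world: off-patch crawling at ~198 um/s,
#' on-patch dwelling at ~52 um/s with a linear slowdown ramp at patch entry,
#' a bimodal (short/long) log10 dwell-duration mixture, density-dependent
#' sensing, and an accept-reject decision drawn from a logistic rule on the
#' same covariates used by the exploitation model.
#'
#' @param speed_off,speed_on crawling speeds off/on patch, um/s.
#' @param fps frames per second of the simulated recording.
#' @param heading_noise_sd heading diffusion, rad/sqrt(s) (free parameter of
#'   the correlated random walk; the assay papers do not constrain it).
#' @param slowdown_window seconds over which a sensing worm ramps from
#'   `speed_off` to `speed_on` after patch entry.
#' @param duration_mixture list with `short` and `long`, each `c(mean, sd)`
#'   of log10 dwell duration in seconds. Defaults: short 10^1.2 ~= 16 s,
#'   long 10^2.9 ~= 13 min.
#' @param sensing_fn monotone non-decreasing map from relative density to
#'   the probability that the worm detects the patch on encounter.
#' @param beta_true named decision coefficients
#'   (intercept, rho_k, tau_s, rho_h, rho_e) for the logistic exploit rule.
#' @param acclimation_density relative density of the acclimation plate used
#'   to initialize the history covariates.
#' @return object of class `behavior_params`.
#' @export
behavior_params <- function(speed_off = 198, speed_on = 52, fps = 3,
                            heading_noise_sd = 1.0, slowdown_window = 8,
                            duration_mixture = list(short = c(1.2, 0.35),
                                                    long = c(2.9, 0.35)),
                            sensing_fn = default_sensing_fn,
                            beta_true = c(intercept = -2, rho_k = 1,
                                          tau_s = 0.5, rho_h = -0.5,
                                          rho_e = -0.5),
                            acclimation_density = 10) {
  if (!(speed_on < speed_off)) stop_config("speed_on must be < speed_off")
  if (fps <= 0) stop_config("fps must be > 0")
  if (!is.function(sensing_fn)) stop_config("sensing_fn must be a function")
  dens_grid <- c(0, 0.1, 0.5, 1, 2, 5, 10, 50)
  pv <- vapply(dens_grid, sensing_fn, numeric(1))
  if (any(pv < 0 | pv > 1)) stop_config("sensing_fn must map into [0,1]")
  if (any(diff(pv) < -1e-12))
    stop_config("sensing_fn must be monotone non-decreasing in density")
  if (length(beta_true) != 5)
    stop_config("beta_true must have 5 elements ",
                "(intercept, rho_k, tau_s, rho_h, rho_e)")
  structure(list(speed_off = speed_off, speed_on = speed_on, fps = fps,
                 heading_noise_sd = heading_noise_sd,
                 slowdown_window = slowdown_window,
                 duration_mixture = duration_mixture,
                 sensing_fn = sensing_fn,
                 beta_true = unname(beta_true),
                 acclimation_density = acclimation_density),
            class = "behavior_params")
}

#' @rdname behavior_params
#' @param density relative density (dimensionless, >= 0).
#' @export
default_sensing_fn <- function(density) {
  stats::plogis(0.5 + 1.2 * log(density + 0.05))
}

# draw one dwell duration (seconds) from the log10 mixture mode
draw_dwell <- function(mode_pars) 10^stats::rnorm(1, mode_pars[1], mode_pars[2])

#' Simulate one foraging worm
#'
#' Frame-stepped agent: off patch the worm performs a correlated random walk
#' at `speed_off` (speed jitter +/-10%), reflecting specularly off the arena
#' wall. When its midpoint comes within the encounter margin of a patch edge,
#' the patch is sensed with probability `sensing_fn(density)`; a sensed worm
#' decides to exploit with probability `logistic(beta_true . x)` where x is
#' built from the simulated history exactly as in [build_covariates()].
#' Exploiters dwell for a long-mode duration at `speed_on` (after the linear
#' slowdown ramp), samplers dwell for a short-mode duration, and
#' non-responders pass straight through at full speed. Every encounter is
#' logged with its ground truth.
#'
#' @param arena an `arena_spec`.
#' @param params a `behavior_params`.
#' @param duration_s recording length in seconds.
#' @param seed integer seed.
#' @param worm_id identifier stored in the outputs.
#' @param entry_margin encounter margin in mm (the detection convention:
#'   an encounter spans midpoint-to-edge signed distance >= -entry_margin).
#' @return list with `trajectory` (data.frame: frame, time_s, worm_id, x_mm,
#'   y_mm) and `truth` (data.frame: worm_id, patch_id, entry_time_s,
#'   exit_time_s, sensed_true, exploited_true, rho_k, tau_s, rho_h, rho_e).
#' @export
simulate_forager <- function(arena, params, duration_s, seed = 1L,
                             worm_id = 1L, entry_margin = 0.46024) {
  stopifnot(inherits(arena, "arena_spec"), inherits(params, "behavior_params"))
  if (duration_s <= 0) stop_config("duration_s must be > 0")
  with_seed(seed, {
    fps <- params$fps
    n <- as.integer(round(duration_s * fps))
    pat <- arena$patches
    npat <- nrow(pat)
    R <- arena$arena_radius
    v_off <- params$speed_off / 1000 / fps   # mm per frame
    v_on <- params$speed_on / 1000 / fps
    hsd <- params$heading_noise_sd / sqrt(fps)
    ramp_frames <- max(1L, as.integer(round(params$slowdown_window * fps)))

    # start off-patch, away from any encounter margin
    pos <- c(0, 0)
    repeat {
      pos <- stats::runif(2, -R, R)
      if (sqrt(sum(pos^2)) > 0.95 * R) next
      if (npat == 0L) break
      dd <- pat$radius - sqrt((pos[1] - pat$x)^2 + (pos[2] - pat$y)^2)
      if (max(dd) < -entry_margin - 0.3) break
    }
    heading <- stats::runif(1, 0, 2 * pi)

    xs <- ys <- numeric(n)
    mode <- "search"
    active <- 0L            # active patch index while in an encounter
    entry_frame <- NA_integer_
    dwell_end <- Inf        # frame at which dwelling stops
    sensed <- exploited <- FALSE
    off_accum_s <- 0        # off-food time since last exploited departure
    rho_h <- rho_e <- log(params$acclimation_density)
    cov_dec <- rep(NA_real_, 4)
    log_rows <- list()

    close_encounter <- function(exit_frame) {
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        worm_id = worm_id, patch_id = pat$patch_id[active],
        entry_time_s = (entry_frame - 1L) / fps,
        exit_time_s = (exit_frame - 1L) / fps,
        sensed_true = as.integer(sensed),
        exploited_true = as.integer(exploited),
        rho_k = cov_dec[1], tau_s = cov_dec[2],
        rho_h = cov_dec[3], rho_e = cov_dec[4])
      dens <- pat$density[active]
      if (dens > 0) {
        rho_h <<- log(dens)
        if (exploited) {
          rho_e <<- log(dens)
          off_accum_s <<- 0
        }
      }
      active <<- 0L
      mode <<- "search"
    }

    for (f in seq_len(n)) {
      # --- propose a step ---
      if (mode == "search") {
        heading <- heading + stats::rnorm(1, 0, hsd)
        step <- v_off * (1 + stats::runif(1, -0.1, 0.1))
      } else if (mode == "pass") {
        heading <- heading + stats::rnorm(1, 0, 0.3 * hsd)
        step <- v_off * (1 + stats::runif(1, -0.1, 0.1))
      } else if (mode == "dwell") {
        k <- f - entry_frame
        sp <- if (k < ramp_frames)
          v_off + (v_on - v_off) * k / ramp_frames else v_on
        heading <- heading + stats::rnorm(1, 0, 2 * hsd)
        # keep the dweller inside the patch
        dc <- c(pat$x[active] - pos[1], pat$y[active] - pos[2])
        if (sqrt(sum(dc^2)) > 0.8 * pat$radius[active])
          heading <- atan2(dc[2], dc[1]) + stats::rnorm(1, 0, 0.5)
        step <- sp * (1 + stats::runif(1, -0.1, 0.1))
      } else { # leave
        dc <- c(pos[1] - pat$x[active], pos[2] - pat$y[active])
        heading <- atan2(dc[2], dc[1]) + stats::rnorm(1, 0, 0.2)
        step <- v_off * (1 + stats::runif(1, -0.1, 0.1))
      }
      new <- pos + step * c(cos(heading), sin(heading))
      # specular reflection at the arena wall
      r2 <- sqrt(sum(new^2))
      if (r2 > R) {
        nrm <- new / r2
        vel <- new - pos
        vel <- vel - 2 * sum(vel * nrm) * nrm
        heading <- atan2(vel[2], vel[1])
        new <- pos + step * c(cos(heading), sin(heading))
        if (sqrt(sum(new^2)) > R) new <- new / sqrt(sum(new^2)) * (R - 1e-6)
      }
      pos <- new
      xs[f] <- pos[1]; ys[f] <- pos[2]

      # --- encounter bookkeeping ---
      if (npat > 0L) {
        if (active == 0L) {
          off_accum_s <- off_accum_s + 1 / fps
          dd <- pat$radius - sqrt((pos[1] - pat$x)^2 + (pos[2] - pat$y)^2)
          i <- which.max(dd)
          if (dd[i] >= -entry_margin) {
            active <- i
            entry_frame <- f
            dens <- pat$density[i]
            sensed <- stats::runif(1) < params$sensing_fn(dens)
            exploited <- FALSE
            cov_dec <- c(if (dens > 0) log(dens) else NA_real_,
                         off_accum_s / 3600, rho_h, rho_e)
            if (sensed) {
              if (dens > 0) {
                x <- c(1, cov_dec)
                exploited <- stats::runif(1) <
                  logistic(sum(params$beta_true * x))
              }
              dm <- params$duration_mixture
              dwell_s <- draw_dwell(if (exploited) dm$long else dm$short)
              dwell_end <- entry_frame + max(1L, round(dwell_s * fps))
              mode <- "dwell"
            } else {
              mode <- "pass"
              dwell_end <- Inf
            }
          }
        } else {
          if (mode == "dwell" && f >= dwell_end) mode <- "leave"
          d_act <- pat$radius[active] -
            sqrt((pos[1] - pat$x[active])^2 + (pos[2] - pat$y[active])^2)
          if (d_act < -entry_margin - 0.05) close_encounter(f)
        }
      }
    }
    if (active > 0L) close_encounter(n)  # end-censored encounter

    traj <- data.frame(frame = seq_len(n) - 1L,
                       time_s = (seq_len(n) - 1L) / fps,
                       worm_id = worm_id, x_mm = xs, y_mm = ys)
    truth <- if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(worm_id = integer(), patch_id = integer(),
                 entry_time_s = numeric(), exit_time_s = numeric(),
                 sensed_true = integer(), exploited_true = integer(),
                 rho_k = numeric(), tau_s = numeric(), rho_h = numeric(),
                 rho_e = numeric())
    list(trajectory = traj, truth = truth)
  })
}

#' Simulate a cohort of worms
#'
#' Runs [simulate_forager()] once per worm with per-worm seeds derived by
#' fixed splitting from `seed`, so adding worms never perturbs earlier ones.
#'
#' @inheritParams simulate_forager
#' @param n_worms number of worms.
#' @return list with stacked `trajectory` and `truth` data.frames.
#' @export
simulate_worms <- function(arena, params, duration_s, n_worms, seed = 1L,
                           entry_margin = 0.46024) {
  out <- lapply(seq_len(n_worms), function(w) {
    simulate_forager(arena, params, duration_s,
                     seed = derive_seed(seed, w), worm_id = w,
                     entry_margin = entry_margin)
  })
  list(trajectory = do.call(rbind, lapply(out, `[[`, "trajectory")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Generate a covariate-level soft-label dataset with known coefficients
#'
#' Bypasses trajectory simulation: draws encounter sequences directly at the
#' covariate level. Patch densities are sampled from `density_menu`,
#' inter-encounter search gaps are exponential with mean `mean_search_hr`
#' hours, and history covariates (rho_h, rho_e) propagate sequentially from
#' the acclimation density using realized Bernoulli exploit draws. The soft
#' response is the exact decision probability q_k = logistic(beta_true . x_k)
#' and every encounter has sensing probability 1, so the downstream GLM sees
#' noiseless soft labels.
#'
#' @param beta_true coefficients (intercept, rho_k, tau_s, rho_h, rho_e).
#' @param n_worms,encounters_per_worm design size.
#' @param density_menu positive relative densities to sample from.
#' @param seed integer seed.
#' @param acclimation_density density initializing rho_h and rho_e.
#' @param mean_search_hr mean off-food gap between encounters, hours.
#' @return list with `dataset` (a `soft_label_dataset` data.frame) and
#'   `truth` (realized exploit draws per encounter).
#' @export
generate_covariate_dataset <- function(beta_true = c(-2, 1, 0.5, -0.5, -0.5),
                                       n_worms = 200,
                                       encounters_per_worm = 20,
                                       density_menu = c(0.5, 1, 5, 10),
                                       seed = 1L,
                                       acclimation_density = 10,
                                       mean_search_hr = 0.1) {
  if (n_worms < 1) stop_config("n_worms must be >= 1")
  if (length(density_menu) == 0 || any(density_menu <= 0))
    stop_config("density_menu must be a non-empty set of positive densities")
  beta_true <- unname(beta_true)
  dm <- list(short = c(1.2, 0.35), long = c(2.9, 0.35))
  rows <- with_seed(seed, {
    K <- encounters_per_worm
    lapply(seq_len(n_worms), function(w) {
      gap <- stats::rexp(K, 1 / mean_search_hr)
      dens <- if (length(density_menu) == 1L) rep(density_menu, K)
              else sample(density_menu, K, replace = TRUE)
      u_expl <- stats::runif(K)
      u_dwell <- stats::rnorm(K)
      rho_h <- rho_e <- log(acclimation_density)
      t_s <- 0; off_hr <- 0
      entry <- exit <- tau_s <- q <- rh <- re <- numeric(K)
      expl <- logical(K)
      for (k in seq_len(K)) {
        entry[k] <- t_s + gap[k] * 3600
        tau_s[k] <- off_hr + gap[k]
        rh[k] <- rho_h; re[k] <- rho_e
        q[k] <- logistic(sum(beta_true *
                               c(1, log(dens[k]), tau_s[k], rho_h, rho_e)))
        expl[k] <- u_expl[k] < q[k]
        md <- if (expl[k]) dm$long else dm$short
        exit[k] <- entry[k] + 10^(md[1] + md[2] * u_dwell[k])
        t_s <- exit[k]
        rho_h <- log(dens[k])
        if (expl[k]) { rho_e <- log(dens[k]); off_hr <- 0 }
        else off_hr <- tau_s[k]
      }
      data.frame(worm_id = w, k = seq_len(K), patch_id = seq_len(K),
                 entry_s = entry, exit_s = exit, density = dens, q = q,
                 p_sense = 1, rho_k = log(dens), tau_s = tau_s,
                 rho_h = rh, rho_e = re, tau_t = entry / 3600,
                 exploited_true = as.integer(expl))
    })
  })
  df <- do.call(rbind, rows)
  truth <- df[, c("worm_id", "k", "density", "q", "exploited_true")]
  ds <- df[, c("worm_id", "k", "patch_id", "entry_s", "exit_s", "density",
               "q", "p_sense", "rho_k", "tau_s", "rho_h", "rho_e", "tau_t")]
  class(ds) <- c("soft_label_dataset", "data.frame")
  attr(ds, "beta_true") <- beta_true
  attr(ds, "acclimation_density") <- acclimation_density
  list(dataset = ds, truth = truth)
}
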