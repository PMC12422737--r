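# Geometric patch-encounter detection from midpoint trajectories: signed
# distance to the nearest patch edge, threshold-based candidate runs,
# near-miss filtering, false-exit merging, and the per-encounter velocity
# features used by the classifiers.

#' Detection thresholds
#'
#' The three distance constants were measured on
#' high-resolution single-patch recordings: a patch encounter spans the time
#' the midpoint is within `entry_margin` of the patch edge; candidates whose
#' midpoint never came within `near_miss_margin` of the edge are discarded as
#' near misses; and gaps between same-patch candidates whose distance
#' standard deviation is below `exit_std_threshold` are treated as false
#' exits and merged.
#'
#' @param entry_margin mm, default 0.46024.
#' @param near_miss_margin mm, default 0.28758 (must be < `entry_margin`).
#' @param exit_std_threshold mm, default 0.22221.
#' @param decel_window seconds around encounter start over which the
#'   deceleration slope is fit, default c(-1.5, 6.5).
#' @param peak_window seconds before encounter start searched for the peak
#'   approach velocity, default 10.
#' @return object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(entry_margin = 0.46024,
                                 near_miss_margin = 0.28758,
                                 exit_std_threshold = 0.22221,
                                 decel_window = c(-1.5, 6.5),
                                 peak_window = 10) {
  if (!(near_miss_margin < entry_margin))
    stop_config("near_miss_margin must be < entry_margin")
  if (any(c(entry_margin, near_miss_margin, exit_std_threshold,
            peak_window) <= 0))
    stop_config("thresholds must be positive")
  structure(list(entry_margin = entry_margin,
                 near_miss_margin = near_miss_margin,
                 exit_std_threshold = exit_std_threshold,
                 decel_window = decel_window, peak_window = peak_window),
            class = "detection_thresholds")
}

#' Re-derive the false-exit variability threshold from off-patch gaps
#'
#' The default `exit_std_threshold` (0.22221 mm) was measured on
#' high-resolution single-patch recordings. For synthetic worlds this
#' routine re-derives it: the standard deviations of the midpoint-to-edge
#' distance during off-patch gaps are bimodal (low-variance false exits vs
#' true excursions); a two-component Gaussian mixture is fit on the log
#' SDs and the threshold is the equal-posterior boundary between the
#' components.
#'
#' @param gap_sds positive per-gap distance standard deviations, mm.
#' @return threshold in mm; attribute `mixture` holds the fitted
#'   1-D component means, sds, and weights (log scale).
#' @export
derive_exit_threshold <- function(gap_sds) {
  x <- log(gap_sds[gap_sds > 0])
  if (length(x) < 10L) stop_config("need >= 10 positive gap SDs")
  fit <- fit_gmm2(matrix(x, ncol = 1), alpha = 1e-6, seed = 1L)
  lo <- which.min(c(fit$means[[1]], fit$means[[2]]))
  hi <- 3L - lo
  # equal-posterior crossing between the component means (bisection)
  f <- function(v) {
    lg <- vapply(1:2, function(k)
      log(fit$weights[k]) +
        stats::dnorm(v, fit$means[[k]], sqrt(fit$covs[[k]][1, 1]),
                     log = TRUE), numeric(1))
    lg[lo] - lg[hi]
  }
  root <- stats::uniroot(f, c(fit$means[[lo]], fit$means[[hi]]))$root
  structure(exp(root),
            mixture = list(means = c(fit$means[[lo]], fit$means[[hi]]),
                           sds = sqrt(c(fit$covs[[lo]][1, 1],
                                        fit$covs[[hi]][1, 1])),
                           weights = fit$weights[c(lo, hi)]))
}

#' Signed distance to the nearest patch edge
#'
#' For each frame, d = patch_radius - distance(midpoint, patch_center) for
#' the nearest patch (positive inside the patch, negative outside). The
#' nearest patch minimizes center distance minus radius; ties go to the
#' lowest patch id.
#'
#' @param trajectory data.frame with `x_mm`, `y_mm` (single worm).
#' @param arena an `arena_spec`.
#' @return data.frame `d` (mm) and `nearest_patch_id`; attribute
#'   `no_patches` is TRUE (and all values NA) when the arena has no patches.
#' @export
signed_distance <- function(trajectory, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  pat <- arena$patches
  n <- nrow(trajectory)
  if (nrow(pat) == 0L)
    return(structure(data.frame(d = rep(NA_real_, n),
                                nearest_patch_id = rep(NA_integer_, n)),
                     no_patches = TRUE))
  # n x npat edge-distance matrix (outside-positive), then flip sign
  dx <- outer(trajectory$x_mm, pat$x, "-")
  dy <- outer(trajectory$y_mm, pat$y, "-")
  edge <- sqrt(dx^2 + dy^2) - matrix(pat$radius, n, nrow(pat), byrow = TRUE)
  i <- max.col(-edge, ties.method = "first")   # lowest id on ties
  structure(data.frame(d = -edge[cbind(seq_len(n), i)],
                       nearest_patch_id = pat$patch_id[i]),
            no_patches = FALSE)
}

#' Provisional encounter candidates from a distance series
#'
#' An encounter spans a maximal run of frames where the signed distance to
#' one patch satisfies d >= -entry_margin. Runs touching the first frame are
#' flagged `start_censored` (the recording began mid-encounter); runs
#' touching the last frame are flagged `end_censored`.
#'
#' @param distances output of [signed_distance()].
#' @param thresholds a `detection_thresholds`.
#' @param fps frames per second.
#' @return data.frame of candidates: `patch_id, entry_frame, exit_frame`
#'   (1-based, inclusive), `duration_s, max_d, start_censored, end_censored`.
#' @export
detect_candidates <- function(distances, thresholds = detection_thresholds(),
                              fps) {
  if (isTRUE(attr(distances, "no_patches")))
    stop_config("distance series has no patches (flagged undefined)")
  inside <- distances$d >= -thresholds$entry_margin
  n <- length(inside)
  # split runs when the nearest patch changes
  grp <- cumsum(c(TRUE, inside[-1] != inside[-n] |
                    distances$nearest_patch_id[-1] !=
                    distances$nearest_patch_id[-n]))
  idx <- which(inside)
  if (!length(idx)) return(empty_candidates())
  rows <- lapply(split(idx, grp[idx]), function(fr) {
    data.frame(patch_id = distances$nearest_patch_id[fr[1]],
               entry_frame = fr[1], exit_frame = fr[length(fr)],
               duration_s = (fr[length(fr)] - fr[1]) / fps,
               max_d = max(distances$d[fr]),
               start_censored = fr[1] == 1L,
               end_censored = fr[length(fr)] == n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$entry_frame), ]
}

empty_candidates <- function() {
  data.frame(patch_id = integer(), entry_frame = integer(),
             exit_frame = integer(), duration_s = numeric(),
             max_d = numeric(), start_censored = logical(),
             end_censored = logical())
}

#' Remove near-miss candidates
#'
#' Drops candidates whose midpoint never came within `near_miss_margin` of
#' the patch edge (max d < -near_miss_margin). Retained candidates carry
#' `midpoint_entered = (max d > 0)` for the downstream 5% sensing-exclusion
#' rule; an encounter whose midpoint entered the patch is never removed.
#'
#' @param candidates output of [detect_candidates()].
#' @param thresholds a `detection_thresholds`.
#' @return filtered candidates with a `midpoint_entered` column.
#' @export
filter_near_miss <- function(candidates,
                             thresholds = detection_thresholds()) {
  keep <- candidates$max_d >= -thresholds$near_miss_margin
  out <- candidates[keep, , drop = FALSE]
  out$midpoint_entered <- out$max_d > 0
  rownames(out) <- NULL
  out
}

#' Merge false exits between same-patch candidates
#'
#' For each gap between consecutive candidates on the same patch, computes
#' the standard deviation of the signed distance during the gap; if it is
#' below `exit_std_threshold` the worm never truly left (e.g. an outstretched
#' feeding posture) and the flanking candidates are merged, the gap counting
#' as on-encounter time. Iterated to a fixed point.
#'
#' @param candidates candidate table (after [filter_near_miss()] or before).
#' @param distances the worm's [signed_distance()] series.
#' @param thresholds a `detection_thresholds`.
#' @param fps frames per second.
#' @return merged candidate table.
#' @export
merge_false_exits <- function(candidates, distances,
                              thresholds = detection_thresholds(), fps) {
  if (nrow(candidates) < 2L) return(candidates)
  cand <- candidates[order(candidates$entry_frame), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(cand)) {
      a <- cand[i, ]; b <- cand[i + 1L, ]
      if (a$patch_id == b$patch_id) {
        gap <- seq(a$exit_frame + 1L, b$entry_frame - 1L)
        gap_sd <- if (length(gap) < 2L) 0 else stats::sd(distances$d[gap])
        if (gap_sd < thresholds$exit_std_threshold) {
          cand$exit_frame[i] <- b$exit_frame
          cand$duration_s[i] <- (b$exit_frame - a$entry_frame) / fps
          cand$max_d[i] <- max(a$max_d, b$max_d)
          cand$end_censored[i] <- b$end_censored
          if ("midpoint_entered" %in% names(cand))
            cand$midpoint_entered[i] <- a$midpoint_entered ||
              b$midpoint_entered
          cand <- cand[-(i + 1L), , drop = FALSE]
          merged <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  rownames(cand) <- NULL
  cand
}

#' Instantaneous midpoint speed
#'
#' Central-difference speed in um/s (one-sided at the endpoints), optionally
#' smoothed with a centered moving average. Raw midpoint differencing at
#' ~33 px/mm is noise-dominated, hence the default 1 s smoothing window;
#' disable it for analytic test tracks.
#'
#' @param trajectory data.frame with `x_mm`, `y_mm`, `time_s` (single worm,
#'   constant frame step).
#' @param fps frames per second.
#' @param smooth logical; apply the moving average?
#' @param smooth_window_s smoothing window in seconds.
#' @return numeric vector of speeds, um/s.
#' @export
instantaneous_velocity <- function(trajectory, fps, smooth = TRUE,
                                   smooth_window_s = 1) {
  n <- nrow(trajectory)
  if (n < 3L) stop_config("need at least 3 frames")
  if (any(diff(trajectory$time_s) <= 0))
    stop_config("duplicate or non-increasing timestamps")
  x <- trajectory$x_mm; y <- trajectory$y_mm
  v <- numeric(n)
  i <- 2:(n - 1L)
  v[i] <- sqrt((x[i + 1L] - x[i - 1L])^2 + (y[i + 1L] - y[i - 1L])^2) *
    fps / 2
  v[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) * fps
  v[n] <- sqrt((x[n] - x[n - 1L])^2 + (y[n] - y[n - 1L])^2) * fps
  v <- v * 1000  # mm/s -> um/s
  if (smooth) {
    w <- max(1L, round(smooth_window_s * fps))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L) {
      k <- rep(1 / w, w)
      sm <- stats::filter(v, k, sides = 2)
      v <- ifelse(is.na(sm), v, as.numeric(sm))  # keep raw ends
    }
  }
  v
}

#' Per-encounter velocity and duration features
#'
#' Computes the two feature vectors used downstream. `feature_w = (s, t, u)`:
#' `s` is the minimum speed during the encounter (um/s); `t` is the
#' deceleration, the OLS slope of speed on time over entry - 1.5 s to
#' entry + 6.5 s (um/s^2); `u` is the maximum velocity change, the peak
#' speed within 10 s before entry minus `s`, floored at 0 (um/s).
#' `feature_z = (ln duration_s, ln mean on-encounter speed)`.
#' Start-censored encounters compute `t` and `u` as if entry occurred at the
#' first frame and are flagged `w_biased`.
#'
#' @param encounter one candidate row (entry_frame, exit_frame,
#'   start_censored).
#' @param velocity speed series from [instantaneous_velocity()], um/s.
#' @param time_s frame times, s.
#' @param thresholds a `detection_thresholds`.
#' @param fps frames per second.
#' @return one-row data.frame: `s_k, t_k, u_k, log_dur, log_vel, w_biased`.
#' @export
extract_features <- function(encounter, velocity, time_s,
                             thresholds = detection_thresholds(), fps) {
  ef <- encounter$entry_frame; xf <- encounter$exit_frame
  if (xf < ef) stop_config("encounter shorter than 1 frame")
  on_idx <- ef:xf
  s_k <- min(velocity[on_idx])
  t0 <- time_s[ef]
  win <- which(time_s >= t0 + thresholds$decel_window[1] &
                 time_s <= t0 + thresholds$decel_window[2])
  if (length(win) < 2L) stop_config("decel window shorter than 2 frames")
  t_k <- unname(stats::coef(stats::lm(velocity[win] ~ time_s[win]))[2])
  pre <- which(time_s >= t0 - thresholds$peak_window & time_s <= t0)
  u_k <- max(0, max(velocity[pre]) - s_k)
  dur <- (xf - ef) / fps
  if (dur <= 0) dur <- 1 / fps   # single-frame encounter: one frame step
  data.frame(s_k = s_k, t_k = t_k, u_k = u_k,
             log_dur = log(dur), log_vel = log(mean(velocity[on_idx])),
             w_biased = isTRUE(encounter$start_censored))
}

#' Detect and featurize all encounters for a cohort
#'
#' Full detection pipeline per worm: signed distance, candidate runs, false
#' exit merging, near-miss filtering, velocity features.
#'
#' @param trajectory stacked trajectory data.frame (`worm_id, frame, time_s,
#'   x_mm, y_mm`).
#' @param arena an `arena_spec`.
#' @param thresholds a `detection_thresholds`.
#' @param fps frames per second.
#' @param smooth_velocity logical, passed to [instantaneous_velocity()].
#' @return encounter table: worm_id, patch_id, entry_s, exit_s, duration_s,
#'   density, s_k, t_k, u_k, log_dur, log_vel, start_censored, end_censored,
#'   midpoint_entered, w_biased.
#' @export
detect_encounters <- function(trajectory, arena,
                              thresholds = detection_thresholds(), fps,
                              smooth_velocity = TRUE) {
  out <- lapply(split(trajectory, trajectory$worm_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    ds <- signed_distance(tr, arena)
    cand <- detect_candidates(ds, thresholds, fps)
    if (!nrow(cand)) return(NULL)
    cand <- merge_false_exits(cand, ds, thresholds, fps)
    cand <- filter_near_miss(cand, thresholds)
    if (!nrow(cand)) return(NULL)
    vel <- instantaneous_velocity(tr, fps, smooth = smooth_velocity)
    feats <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      extract_features(cand[i, ], vel, tr$time_s, thresholds, fps)))
    dens <- arena$patches$density[match(cand$patch_id,
                                        arena$patches$patch_id)]
    cbind(data.frame(worm_id = tr$worm_id[1], patch_id = cand$patch_id,
                     entry_s = tr$time_s[cand$entry_frame],
                     exit_s = tr$time_s[cand$exit_frame],
                     duration_s = cand$duration_s, density = dens,
                     start_censored = cand$start_censored,
                     end_censored = cand$end_censored,
                     midpoint_entered = cand$midpoint_entered),
          feats)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(out) <- NULL
  out
}
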