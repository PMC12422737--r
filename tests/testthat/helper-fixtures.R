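# Shared fixture builders. Everything is generated in code at test time.

# straight-line trajectory at constant speed (mm/s)
straight_track <- function(speed_mm_s, fps, duration_s, start = c(0, 0),
                           heading = 0, worm_id = 1L) {
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  data.frame(frame = seq_len(n) - 1L, time_s = t, worm_id = worm_id,
             x_mm = start[1] + speed_mm_s * t * cos(heading),
             y_mm = start[2] + speed_mm_s * t * sin(heading))
}

# hand-built signed-distance series for candidate-detection tests
distance_series <- function(d, patch_id = 1L) {
  structure(data.frame(d = d,
                       nearest_patch_id = rep_len(patch_id, length(d))),
            no_patches = FALSE)
}

# two well-separated (s, t, u) feature clusters: sensed vs non-responding.
# Cluster means differ by `sep` within-cluster standard deviations per axis.
sep_w_features <- function(n_sense, n_nonsense, sep = 8, sd = 5,
                           seed = 1) {
  set.seed(seed)
  sense <- cbind(s_k = rnorm(n_sense, 30, sd),
                 t_k = rnorm(n_sense, -20 - 0 * sep, sd),
                 u_k = rnorm(n_sense, 30 + sep * sd + 120, sd))
  nons <- cbind(s_k = rnorm(n_nonsense, 30 + sep * sd, sd),
                t_k = rnorm(n_nonsense, -20 + sep * sd, sd),
                u_k = rnorm(n_nonsense, 30 + 120, sd))
  rbind(sense, nons)
}

# synthetic ring-shaped radial fluorescence profile whose edge-peak
# amplitude is `amp` by construction (peak at radius `edge_um`)
ring_profile <- function(amp, edge_um = 800, baseline = 0,
                         radius = seq(0, 1200, by = 10), center = 0) {
  ring <- (amp - baseline) * exp(-((radius - edge_um) / 40)^2)
  dome <- center * exp(-(radius / 250)^2)
  data.frame(radius_um = radius, intensity = baseline + ring + dome)
}

# calibration profile table: per condition, amplitudes follow
# amp = intercept + slope * t exactly
calibration_profiles <- function(conds, times = c(1, 2, 4, 8)) {
  do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    do.call(rbind, lapply(times, function(t) {
      a <- conds$intercept[i] + conds$slope[i] * t
      p <- ring_profile(a)
      data.frame(condition = conds$condition[i], od = conds$od[i],
                 growth_time_hr = t, radius_um = p$radius_um,
                 intensity = p$intensity)
    }))
  }))
}

# minimal raw-encounter table for covariate tests
raw_encounters <- function(worm_id, entry_s, exit_s, density, q,
                           p_sense = 1) {
  data.frame(worm_id = worm_id, entry_s = entry_s, exit_s = exit_s,
             density = density, q = q, p_sense = p_sense)
}
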