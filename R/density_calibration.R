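# Bacterial patch density calibration: edge-peak amplitude extraction from
# radial fluorescence profiles, per-condition amplitude-vs-growth-time
# regression, and the linear rescaling that anchors the reference seeding
# condition (0.5 ul, OD600 = 10, 1 hr growth) at relative density 10.

#' Peak amplitude of a radial fluorescence profile
#'
#' Bacterial lawns concentrate actively growing cells at the patch edge, so
#' the density proxy is the peak fluorescence near the edge rather than the
#' center value. The edge is located at the steepest outward intensity drop
#' beyond the half-maximum radius (ties broken toward larger radius); the
#' returned amplitude is the maximum intensity within an annulus around that
#' edge (half-width `annulus_frac` of the edge radius, at least 50 um).
#'
#' @param radius_um strictly increasing radii, um.
#' @param intensity non-negative intensities (arbitrary units).
#' @param annulus_frac annulus half-width as a fraction of the edge radius.
#' @return the peak amplitude; attribute `all_zero` is TRUE when the profile
#'   carries no signal (amplitude 0), attribute `edge_radius` gives the
#'   detected edge location.
#' @export
peak_amplitude <- function(radius_um, intensity, annulus_frac = 0.1) {
  if (length(radius_um) == 0) stop_config("empty profile")
  if (any(diff(radius_um) <= 0))
    stop_config("radius_um must be strictly increasing")
  if (all(intensity == 0))
    return(structure(0, all_zero = TRUE, edge_radius = NA_real_))
  grad <- diff(intensity) / diff(radius_um)
  mids <- (radius_um[-1] + radius_um[-length(radius_um)]) / 2
  half <- max(intensity) / 2
  r_half <- radius_um[which(intensity >= half)[1]]
  ok <- mids >= r_half
  if (!any(ok) || min(grad[ok]) >= 0) {
    # no outward drop (flat or monotone-rising profile): no edge to detect
    return(structure(max(intensity), all_zero = FALSE,
                     edge_radius = NA_real_))
  }
  g <- grad[ok]; m <- mids[ok]
  steepest <- which(g == min(g))
  edge <- max(m[steepest])              # tie-break toward larger radius
  w <- max(annulus_frac * edge, 50)
  in_ann <- abs(radius_um - edge) <= w
  structure(max(intensity[in_ann]), all_zero = FALSE, edge_radius = edge)
}

#' Fit the peak-amplitude-vs-growth-time calibration model
#'
#' For each seeding condition with directly measurable fluorescence, fits an
#' ordinary least squares line of edge-peak amplitude on growth time. For
#' conditions flagged below the fluorescence detection limit, the (intercept,
#' slope) pair is extrapolated from a degree-2 polynomial of the fitted
#' intercepts and slopes on seeded OD across the OD = {0.5, 1, 2} conditions.
#' Finally a single global scale constant is chosen so that the reference
#' condition maps to relative density 10 at its reference growth time.
#'
#' @param profiles data.frame with columns `condition`, `od`, `growth_time_hr`,
#'   `radius_um`, `intensity`; one radial profile per (condition, time).
#' @param below_detection character vector of condition ids whose amplitude
#'   model must be extrapolated over OD.
#' @param reference_condition condition id anchoring the scale.
#' @param reference_time_hr growth time (hours) at which the reference
#'   condition has relative density `reference_value`.
#' @param reference_value the anchor value (10 by convention).
#' @param od_fit_conditions condition ids used for the OD extrapolation
#'   (their `od` fields must be distinct; defaults to the conditions with
#'   od in {0.5, 1, 2}).
#' @return object of class `density_model`: per-condition `coef` table
#'   (condition, od, intercept, slope, extrapolated) and `scale_constant`.
#' @export
fit_amplitude_model <- function(profiles, below_detection = character(),
                                reference_condition, reference_time_hr = 1,
                                reference_value = 10,
                                od_fit_conditions = NULL) {
  need <- c("condition", "od", "growth_time_hr", "radius_um", "intensity")
  if (!all(need %in% names(profiles)))
    stop_config("profiles need columns: ", paste(need, collapse = ", "))
  key <- interaction(profiles$condition, profiles$growth_time_hr, drop = TRUE)
  amp <- do.call(rbind, lapply(split(profiles, key), function(p) {
    data.frame(condition = p$condition[1], od = p$od[1],
               growth_time_hr = p$growth_time_hr[1],
               amplitude = as.numeric(peak_amplitude(p$radius_um,
                                                     p$intensity)))
  }))
  direct <- setdiff(unique(amp$condition), below_detection)
  coefs <- do.call(rbind, lapply(direct, function(cn) {
    a <- amp[amp$condition == cn, ]
    if (nrow(a) < 2)
      stop_config("condition '", cn, "' has fewer than 2 time points")
    fit <- stats::lm(amplitude ~ growth_time_hr, data = a)
    data.frame(condition = cn, od = a$od[1],
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]), extrapolated = FALSE)
  }))
  if (length(below_detection)) {
    if (is.null(od_fit_conditions))
      od_fit_conditions <- coefs$condition[coefs$od %in% c(0.5, 1, 2)]
    base <- coefs[coefs$condition %in% od_fit_conditions, ]
    if (nrow(base) < 3)
      stop_config("OD extrapolation needs >= 3 directly fitted conditions")
    fi <- stats::lm(intercept ~ stats::poly(od, 2, raw = TRUE), data = base)
    fs <- stats::lm(slope ~ stats::poly(od, 2, raw = TRUE), data = base)
    lows <- do.call(rbind, lapply(below_detection, function(cn) {
      odv <- profiles$od[profiles$condition == cn][1]
      if (is.na(odv)) stop_config("unknown below-detection condition: ", cn)
      nd <- data.frame(od = odv)
      data.frame(condition = cn, od = odv,
                 intercept = unname(stats::predict(fi, nd)),
                 slope = unname(stats::predict(fs, nd)), extrapolated = TRUE)
    }))
    coefs <- rbind(coefs, lows)
  }
  ref <- coefs[coefs$condition == reference_condition, ]
  if (nrow(ref) != 1)
    stop_config("reference condition '", reference_condition, "' not fitted")
  ref_amp <- ref$intercept + ref$slope * reference_time_hr
  if (ref_amp <= 0)
    stop_config("reference condition has non-positive predicted amplitude")
  structure(list(coef = coefs, scale_constant = reference_value / ref_amp,
                 reference = list(condition = reference_condition,
                                  time_hr = reference_time_hr,
                                  value = reference_value)),
            class = "density_model")
}

#' Relative density of a condition at a growth time
#'
#' Linearly rescales the predicted edge-peak amplitude by the model's global
#' scale constant; clipped at 0 from below.
#'
#' @param model a `density_model`.
#' @param condition condition id.
#' @param growth_time_hr growth time, hours.
#' @return dimensionless relative density (reference condition -> 10).
#' @export
relative_density <- function(model, condition, growth_time_hr) {
  stopifnot(inherits(model, "density_model"))
  i <- match(condition, model$coef$condition)
  if (any(is.na(i))) stop_config("unknown condition: ",
                                 paste(condition[is.na(i)], collapse = ", "))
  amp <- model$coef$intercept[i] + model$coef$slope[i] * growth_time_hr
  pmax(0, model$scale_constant * amp)
}

#' Tabulate relative densities for all fitted conditions
#'
#' @param model a `density_model`.
#' @param growth_times_hr growth times (hours) to evaluate.
#' @return data.frame `condition, growth_time_hr, relative_density`.
#' @export
density_lookup_table <- function(model, growth_times_hr) {
  g <- expand.grid(condition = model$coef$condition,
                   growth_time_hr = growth_times_hr,
                   stringsAsFactors = FALSE)
  g$relative_density <- relative_density(model, g$condition,
                                         g$growth_time_hr)
  g[order(g$condition, g$growth_time_hr), ]
}
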