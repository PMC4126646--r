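# closed-form simple linear regression; returns slope, intercept, r2
lin_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(slope = NA_real_, intercept = NA_real_, r2 = 0))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r2 = r2)
}

# best-R^2 linear slope over sliding windows restricted to points whose
# force lies in [lo, hi] of the peak force; returns NA when too few points
elastic_slope <- function(x, y, f, f_peak, window = c(0.10, 0.40),
                          min_points = 4L) {
  idx <- which(f >= window[1] * f_peak & f <= window[2] * f_peak)
  if (length(idx) < min_points) {
    # fall back to the first points after the origin
    idx <- seq_len(min(length(x), max(min_points, 4L)))[-1L]
  }
  if (length(idx) < 3L) return(NA_real_)
  width <- max(3L, ceiling(length(idx) / 2))
  best <- NULL
  for (s in seq_len(length(idx) - width + 1L)) {
    w <- idx[s:(s + width - 1L)]
    fit <- lin_fit(x[w], y[w])
    if (is.null(best) || (!is.na(fit$slope) && fit$r2 > best$r2)) best <- fit
  }
  best$slope
}

#' Mechanical trait configuration
#'
#' Thresholds and window bounds used when reducing force-displacement
#' records to mechanical traits.
#'
#' @param tensile_span_ratio_min Minimal gauge-length / mean-diameter ratio
#'   for a valid tensile specimen (default 30).
#' @param bending_span_ratio_min Minimal span / depth-diameter ratio for a
#'   valid bending specimen (shear-free three-point bending).
#' @param break_drop_fraction Post-peak force drop, as a fraction of the
#'   peak, required to call a break.
#' @param elastic_window Force band (fractions of peak force) searched for
#'   the linear elastic region.
#' @return A named list.
#' @export
mech_config <- function(tensile_span_ratio_min = 30,
                        bending_span_ratio_min = 10,
                        break_drop_fraction = 0.30,
                        elastic_window = c(0.10, 0.40)) {
  stopifnot(tensile_span_ratio_min > 0, bending_span_ratio_min > 0,
            break_drop_fraction > 0, break_drop_fraction < 1,
            length(elastic_window) == 2L, elastic_window[1] < elastic_window[2])
  list(tensile_span_ratio_min = tensile_span_ratio_min,
       bending_span_ratio_min = bending_span_ratio_min,
       break_drop_fraction = break_drop_fraction,
       elastic_window = elastic_window)
}

#' Reduce a tensile force-displacement record to its mechanical traits
#'
#' The break is the global force maximum, accepted only if the record then
#' drops by at least `break_drop_fraction` of the peak; a record that ends
#' still ascending has no detectable break and is marked invalid. Maximal
#' tensile stress is the breaking force over the root cross-sectional area
#' (circular section on the mean of the three diameter readings); ultimate
#' strain is the clamp displacement at break over the initial gauge length;
#' the tensile modulus is the best-R^2 linear slope of the stress-strain
#' curve within the elastic force band. Specimens that failed outside the
#' middle third, slipped in the clamps, or have a gauge shorter than
#' `tensile_span_ratio_min` diameters are flagged invalid.
#'
#' @param test A `tensile_test` (see [generate_tensile_tests] for fields).
#' @param config A [mech_config].
#' @return A `tensile_result` list: `t_max` (MPa), `eps_ult` (%),
#'   `tensile_modulus` (MPa), `csa` (mm^2), `mean_diameter` (mm), `valid`,
#'   `invalid_reasons`.
#' @examples
#' tt <- generate_tensile_tests(default_archetypes()[["C. anomala"]],
#'                              generator_config(seed = 1, n_tensile = 1,
#'                                               noise_cv = 0))
#' tensile_curve_metrics(tt[[1]])
#' @export
tensile_curve_metrics <- function(test, config = mech_config()) {
  curve <- test$curve
  stopifnot(nrow(curve) >= 3, test$gauge_length > 0)
  if (any(diff(curve$displacement) <= 0)) {
    stop("curve displacement must be strictly increasing")
  }
  d_mean <- mean(test$diameters)
  csa <- pi * d_mean^2 / 4

  reasons <- character()
  i_peak <- which.max(curve$force)
  f_peak <- curve$force[i_peak]
  dropped <- i_peak < nrow(curve) &&
    any(curve$force[(i_peak + 1):nrow(curve)] <=
          (1 - config$break_drop_fraction) * f_peak)
  if (!dropped) reasons <- c(reasons, "no_detectable_break")
  if (!identical(test$failure_location, "middle_third")) {
    reasons <- c(reasons, "failure_outside_middle_third")
  }
  if (isTRUE(test$slipped)) reasons <- c(reasons, "slipped_in_clamps")
  span_ratio <- test$gauge_length / d_mean
  if (span_ratio < config$tensile_span_ratio_min) {
    reasons <- c(reasons, "gauge_below_span_ratio")
  }

  t_max <- f_peak / csa
  eps_ult <- 100 * curve$displacement[i_peak] / test$gauge_length
  modulus <- elastic_slope(curve$displacement / test$gauge_length,
                           curve$force / csa,
                           curve$force, f_peak, config$elastic_window)

  structure(list(root_id = test$root_id, species = test$species,
                 t_max = t_max, eps_ult = eps_ult,
                 tensile_modulus = modulus, csa = csa,
                 mean_diameter = d_mean, span_ratio = span_ratio,
                 valid = length(reasons) == 0L, invalid_reasons = reasons),
            class = "tensile_result")
}

#' Fit the power-law strength-diameter relation
#'
#' Ordinary least squares on (log D, log T_max) over the *valid* tensile
#' results only: \eqn{T_{max} = \alpha D^{-\beta}} with
#' \eqn{\alpha = \exp(\mathrm{intercept})} and
#' \eqn{\beta = -\mathrm{slope}}, so positive \eqn{\beta} means strength
#' decreasing with diameter. The log-log fit (rather than nonlinear least
#' squares) matches the logarithmic-axis presentation conventional for root
#' strength data and makes multiplicative lognormal scatter homoskedastic.
#'
#' @param results List of `tensile_result` objects, or a data frame with
#'   columns `t_max`, `mean_diameter` and `valid`.
#' @return A `power_law_fit` list: `alpha` (MPa mm^beta), `beta`,
#'   `r_squared`, `n`.
#' @examples
#' d <- c(0.2, 0.5, 1, 2)
#' res <- data.frame(t_max = 20 * d^-0.8, mean_diameter = d, valid = TRUE)
#' fit_tmax_power_law(res)
#' @export
fit_tmax_power_law <- function(results) {
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r) {
      data.frame(t_max = r$t_max, mean_diameter = r$mean_diameter,
                 valid = r$valid)
    }))
  df <- df[df$valid, , drop = FALSE]
  if (nrow(df) < 3 || length(unique(df$mean_diameter)) < 3) {
    stop("need >= 3 valid tensile results with distinct diameters")
  }
  if (any(df$t_max <= 0) || any(df$mean_diameter <= 0)) {
    stop("stresses and diameters must be positive")
  }
  fit <- lin_fit(log(df$mean_diameter), log(df$t_max))
  structure(list(alpha = exp(fit$intercept), beta = -fit$slope,
                 r_squared = fit$r2, n = nrow(df)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("T_max = %0.3g * D^-%0.3g  (R^2 = %0.3f, n = %d)\n",
              x$alpha, x$beta, x$r_squared, x$n))
  invisible(x)
}

#' Axial second moment of inertia of an elliptical root section
#'
#' \eqn{I = \pi w d^3 / 64} about the bending neutral axis, with `d` the
#' depth diameter (direction of loading) and `w` the width diameter. For a
#' circular section (`w = d`) this reduces to \eqn{\pi d^4 / 64}.
#'
#' @param d Depth diameter (mm). Vectorised.
#' @param w Width diameter (mm); defaults to `d` (circular).
#' @return Second moment of inertia (mm^4).
#' @examples
#' second_moment_of_inertia(2)          # pi * 16 / 64
#' second_moment_of_inertia(2, w = 4)
#' @export
second_moment_of_inertia <- function(d, w = d) {
  if (any(d < 0) || any(w < 0)) stop("diameters must be non-negative")
  pi * w * d^3 / 64
}

#' Reduce a three-point bending record to its mechanical traits
#'
#' The bending stiffness k is the best-R^2 linear slope of the
#' load-deflection curve shortly after the beginning of the test (within the
#' elastic force band); the bending modulus follows from the three-point
#' central-load relation \eqn{F = 48 E I \delta / L^3}, i.e.
#' \eqn{E = k L^3 / (48 I)} with I the elliptical-section second moment.
#' Rigidity EI is reported in kN mm^2. Tests whose span/depth ratio falls
#' below the configured threshold (shear contamination) or whose initial
#' region is non-monotone are invalid.
#'
#' @param test A `bending_test` (see [generate_bending_tests] for fields).
#' @param config A [mech_config].
#' @return A `bending_result` list: `second_moment` (mm^4),
#'   `bending_modulus` (MPa), `rigidity` EI (kN mm^2), `span_ratio`,
#'   `valid`, `invalid_reasons`.
#' @examples
#' bt <- generate_bending_tests(default_archetypes()[["R. chinensis"]],
#'                              generator_config(seed = 1, n_bending = 1,
#'                                               noise_cv = 0))
#' bending_metrics(bt[[1]])
#' @export
bending_metrics <- function(test, config = mech_config()) {
  curve <- test$curve
  stopifnot(nrow(curve) >= 3, test$span > 0,
            test$depth_diameter > 0, test$width_diameter > 0)
  if (any(diff(curve$deflection) <= 0)) {
    stop("curve deflection must be strictly increasing")
  }
  reasons <- character()
  i_sec <- second_moment_of_inertia(test$depth_diameter, test$width_diameter)
  f_peak <- max(curve$force)
  # the initial region (up to the elastic band's upper bound) must rise
  init <- which(curve$force <= config$elastic_window[2] * f_peak)
  if (length(init) >= 2 && any(diff(curve$force[init]) < 0)) {
    reasons <- c(reasons, "non_monotone_initial_region")
  }
  span_ratio <- test$span / test$depth_diameter
  if (span_ratio < config$bending_span_ratio_min) {
    reasons <- c(reasons, "span_below_span_ratio")
  }
  k <- elastic_slope(curve$deflection, curve$force, curve$force, f_peak,
                     config$elastic_window)
  e_mod <- k * test$span^3 / (48 * i_sec)
  structure(list(root_id = test$root_id, species = test$species,
                 second_moment = i_sec, bending_modulus = e_mod,
                 rigidity = e_mod * i_sec / 1000, span_ratio = span_ratio,
                 valid = length(reasons) == 0L, invalid_reasons = reasons),
            class = "bending_result")
}

#' Tabulate mechanical traits for sets of tensile and bending tests
#'
#' Runs [tensile_curve_metrics] and [bending_metrics] over whole test sets
#' and returns one row per root — the `mech_traits` table consumed by the
#' scoring stage.
#'
#' @param tensile_tests List of `tensile_test` records (may be empty).
#' @param bending_tests List of `bending_test` records (may be empty).
#' @param config A [mech_config].
#' @return Data frame with columns `root_id`, `species`, `kind`
#'   (`"tensile"`/`"bending"`), `mean_diameter`, `t_max`, `eps_ult`,
#'   `tensile_modulus`, `second_moment`, `bending_modulus`, `rigidity`,
#'   `valid`, `invalid_reasons`.
#' @export
mech_traits <- function(tensile_tests = list(), bending_tests = list(),
                        config = mech_config()) {
  rows <- list()
  for (t in tensile_tests) {
    r <- tensile_curve_metrics(t, config)
    rows[[length(rows) + 1L]] <- data.frame(
      root_id = r$root_id, species = r$species, kind = "tensile",
      mean_diameter = r$mean_diameter, t_max = r$t_max, eps_ult = r$eps_ult,
      tensile_modulus = r$tensile_modulus, second_moment = NA_real_,
      bending_modulus = NA_real_, rigidity = NA_real_, valid = r$valid,
      invalid_reasons = paste(r$invalid_reasons, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (t in bending_tests) {
    r <- bending_metrics(t, config)
    rows[[length(rows) + 1L]] <- data.frame(
      root_id = r$root_id, species = r$species, kind = "bending",
      mean_diameter = mean(c(t$depth_diameter, t$width_diameter)),
      t_max = NA_real_, eps_ult = NA_real_, tensile_modulus = NA_real_,
      second_moment = r$second_moment, bending_modulus = r$bending_modulus,
      rigidity = r$rigidity, valid = r$valid,
      invalid_reasons = paste(r$invalid_reasons, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(root_id = character(), species = character(),
                      kind = character(), mean_diameter = numeric(),
                      t_max = numeric(), eps_ult = numeric(),
                      tensile_modulus = numeric(), second_moment = numeric(),
                      bending_modulus = numeric(), rigidity = numeric(),
                      valid = logical(), invalid_reasons = character()))
  }
  do.call(rbind, rows)
}
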