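#' Gravimetric water contents and dry bulk density of a soil sample
#'
#' From the fresh mass \eqn{m_i}, saturated mass \eqn{m_s}, oven-dry mass
#' \eqn{m_d} (g) and paraffin-displacement volume \eqn{v} (cm^3):
#' \deqn{w_i = 100 (m_i - m_d) / m_d, \quad
#'       w_s = 100 (m_s - m_d) / m_d, \quad
#'       \rho_d = m_d / v.}
#' Water contents are gravimetric (percent of dry mass).
#'
#' @param sample A `soil_sample` or list with fields `m_i`, `m_s`, `m_d`
#'   (g) and `v` (cm^3); `m_s >= m_i >= m_d > 0`, `v > 0`.
#' @return A `soil_physical` list: `w_i` (%), `w_s` (%), `rho_d`
#'   (g cm^-3).
#' @examples
#' gravimetric_properties(list(m_i = 120, m_s = 150, m_d = 100, v = 80))
#' @export
gravimetric_properties <- function(sample) {
  with(sample, {
    if (m_d <= 0) stop("dry mass m_d must be positive")
    if (v <= 0) stop("volume v must be positive")
    if (m_i < m_d) stop("mass ordering violated: fresh mass m_i < dry mass m_d")
    if (m_s < m_i) stop("mass ordering violated: saturated mass m_s < fresh mass m_i")
    structure(list(w_i = 100 * (m_i - m_d) / m_d,
                   w_s = 100 * (m_s - m_d) / m_d,
                   rho_d = m_d / v),
              class = "soil_physical")
  })
}

#' Mohr-Coulomb failure envelope from direct-shear tests
#'
#' Converts each record's normal load and peak shear force to stresses over
#' the shear-box plan area (\eqn{\sigma = N/A}, \eqn{\tau = F/A}, kPa) and
#' fits the Mohr-Coulomb line \eqn{\tau = c + \sigma\tan\phi} by ordinary
#' least squares. A negative fitted intercept (apparent cohesion) is
#' reported as-is with a warning, not clipped at zero.
#'
#' @param tests List of `shear_test` records (`normal_load` N, `box_area`
#'   m^2, `peak_shear_force` N), or a data frame with columns
#'   `normal_stress` and `shear_stress` (kPa).
#' @return A `mohr_coulomb_fit` list: `cohesion` c (kPa), `friction_angle`
#'   \eqn{\phi} (degrees), `r_squared`, `n`.
#' @examples
#' sigma <- c(200, 300, 500) / 0.0036 / 1000
#' df <- data.frame(normal_stress = sigma,
#'                  shear_stress = 5 + sigma * tan(30 * pi / 180))
#' mohr_coulomb_fit(df)
#' @export
mohr_coulomb_fit <- function(tests) {
  df <- if (is.data.frame(tests)) tests else
    do.call(rbind, lapply(tests, function(t) {
      data.frame(normal_stress = t$normal_load / t$box_area / 1000,
                 shear_stress = t$peak_shear_force / t$box_area / 1000)
    }))
  if (any(df$normal_stress <= 0)) stop("normal stresses must be positive")
  if (length(unique(df$normal_stress)) < 2) {
    stop("need >= 2 distinct normal stresses; slope undefined otherwise")
  }
  fit <- stats::lm(shear_stress ~ normal_stress, data = df)
  c0 <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (c0 < 0) {
    warning("negative apparent cohesion fitted (", signif(c0, 3),
            " kPa); reported as-is")
  }
  r2 <- lin_fit(df$normal_stress, df$shear_stress)$r2
  structure(list(cohesion = c0,
                 friction_angle = atan(slope) * 180 / pi,
                 r_squared = r2, n = nrow(df)),
            class = "mohr_coulomb_fit")
}

#' @export
print.mohr_coulomb_fit <- function(x, ...) {
  cat(sprintf("tau = %0.3g + sigma * tan(%0.3g deg)  (R^2 = %0.3f, n = %d)\n",
              x$cohesion, x$friction_angle, x$r_squared, x$n))
  invisible(x)
}

#' Soil physical trait table per site and horizon
#'
#' Reduces soil samples and shear tests grouped by (site, horizon) to a
#' `soil_traits` table: mean gravimetric water contents, mean dry bulk
#' density, Mohr-Coulomb cohesion and friction angle. In-situ vane and
#' penetrometer readings, if supplied, are passed through as mean and
#' standard error only.
#'
#' @param soil_samples List of `soil_sample` records.
#' @param shear_tests List of `shear_test` records.
#' @param site,horizon Labels for the reduced group.
#' @param vane,penetrometer Optional numeric vectors of in-situ readings
#'   (kPa); summarised descriptively.
#' @return One-row data frame.
#' @export
soil_traits <- function(soil_samples, shear_tests, site = "hotspot",
                        horizon = "A", vane = NULL, penetrometer = NULL) {
  phys <- lapply(soil_samples, gravimetric_properties)
  mc <- mohr_coulomb_fit(shear_tests)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  data.frame(site = site, horizon = horizon,
             w_i = mean(vapply(phys, `[[`, 0, "w_i")),
             w_s = mean(vapply(phys, `[[`, 0, "w_s")),
             rho_d = mean(vapply(phys, `[[`, 0, "rho_d")),
             cohesion = mc$cohesion, friction_angle = mc$friction_angle,
             mc_r_squared = mc$r_squared,
             vane_mean = if (is.null(vane)) NA_real_ else mean(vane),
             vane_se = if (is.null(vane)) NA_real_ else se(vane),
             penetrometer_mean = if (is.null(penetrometer)) NA_real_ else
               mean(penetrometer),
             penetrometer_se = if (is.null(penetrometer)) NA_real_ else
               se(penetrometer),
             stringsAsFactors = FALSE)
}
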