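#' Generator configuration
#'
#' Shared settings for the synthetic-data generators. A fixed `seed` makes
#' every generator deterministic (identical calls return identical objects).
#' `noise_cv` is the coefficient of variation of the measurement-scale noise
#' each generator applies; `0` switches noise off entirely, which is the
#' round-trip regime in which every analysis routine must recover the true
#' parameters exactly.
#'
#' @param seed Integer random seed.
#' @param n_plants,n_tensile,n_bending,n_shear Record counts. `n_shear` is
#'   the number of load *triplets* (replicate sets over the applied loads).
#' @param noise_cv Dimensionless coefficient of variation, `>= 0`.
#' @param invalid_fraction Fraction of tensile/bending specimens generated
#'   with a deliberate validity violation (clamp failure, slippage or a
#'   too-short gauge/span), in `[0, 1]`.
#' @param site_label `"hotspot"` or `"stable"`.
#' @return A list of class `generator_config`.
#' @examples
#' generator_config(seed = 1, n_tensile = 50)
#' @export
generator_config <- function(seed = 1L, n_plants = 6L, n_tensile = 100L,
                             n_bending = 20L, n_shear = 8L, noise_cv = 0.2,
                             invalid_fraction = 0, site_label = c("hotspot", "stable")) {
  site_label <- match.arg(site_label)
  stopifnot(length(seed) == 1L, is.finite(seed))
  counts <- c(n_plants = n_plants, n_tensile = n_tensile,
              n_bending = n_bending, n_shear = n_shear)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("'noise_cv' must be a non-negative number")
  }
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    stop("'invalid_fraction' must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_plants = as.integer(n_plants),
                 n_tensile = as.integer(n_tensile),
                 n_bending = as.integer(n_bending),
                 n_shear = as.integer(n_shear), noise_cv = noise_cv,
                 invalid_fraction = invalid_fraction,
                 site_label = site_label),
            class = "generator_config")
}

# multiplicative lognormal noise factor with E[log] = 0 and cv on the
# natural scale; cv = 0 returns exact ones
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))
}

as_config <- function(config) {
  if (inherits(config, "generator_config")) return(config)
  do.call(generator_config, config)
}

#' Generate one plant's excavated root system
#'
#' Draws a root system consistent with an archetype: maximal rooting depth
#' and per-sector lateral extents uniform within the archetype ranges, and
#' root segments bucketed into 10-cm depth layers and up/downslope sectors.
#' Segment abundance decays exponentially with depth (roots concentrate near
#' the surface); segment diameters are lognormal and volumes follow the
#' cylinder approximation. Linear-layout archetypes (creepers, underground
#' stems) additionally carry a per-sector along-stem extent so the
#' individual soil volume can use the quarter-cylinder model.
#'
#' @param archetype A [species_archetype].
#' @param config A [generator_config]; `config$seed` fixes the draw.
#' @param plant_id Identifier for the generated plant.
#' @return A `root_system` list: `plant_id`, `species`, `site`,
#'   `collar_diameter` (cm), `max_radius_up`/`max_radius_down` (m),
#'   `max_depth` (m), `layout`, `stem_length` (m, linear layouts only) and a
#'   `segments` data frame (`depth_layer`, `sector`, `diameter` mm,
#'   `length` mm, `volume` mm^3).
#' @examples
#' rs <- generate_root_system(default_archetypes()[["P. stricta"]],
#'                            generator_config(seed = 1))
#' head(rs$segments)
#' @export
generate_root_system <- function(archetype, config = generator_config(),
                                 plant_id = paste0(archetype$name, "_1")) {
  stopifnot(inherits(archetype, "species_archetype"))
  config <- as_config(config)
  set.seed(config$seed)

  max_depth <- stats::runif(1, archetype$max_depth_range[1],
                            archetype$max_depth_range[2])
  r_up <- stats::runif(1, archetype$max_radius_range[1],
                       archetype$max_radius_range[2])
  r_down <- stats::runif(1, archetype$max_radius_range[1],
                         archetype$max_radius_range[2])
  collar <- stats::runif(1, 0.3, 1.2) # cm

  n_layers <- max(1L, ceiling(max_depth / 0.10))
  seg <- list()
  for (layer in seq_len(n_layers) - 1L) {
    for (sector in c("up", "down")) {
      # abundance halves roughly every 15 cm of depth
      lambda <- 12 * exp(-0.45 * layer)
      n_seg <- stats::rpois(1, lambda)
      if (n_seg == 0) next
      d <- stats::rlnorm(n_seg, archetype$diameter_meanlog,
                         archetype$diameter_sdlog)
      # keep segment depths within the sampled maximum
      len <- stats::runif(n_seg, 20, 150)
      seg[[length(seg) + 1L]] <- data.frame(
        depth_layer = layer, sector = sector, diameter = d, length = len,
        volume = pi * (d / 2)^2 * len, stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg)) do.call(rbind, seg) else
    data.frame(depth_layer = integer(), sector = character(),
               diameter = numeric(), length = numeric(), volume = numeric())

  out <- list(plant_id = plant_id, species = archetype$name,
              site = config$site_label, collar_diameter = collar,
              max_radius_up = r_up, max_radius_down = r_down,
              max_depth = max_depth, layout = archetype$root_layout,
              stem_length = NULL, segments = segments)
  if (archetype$root_layout == "linear") {
    # along-stem extent per sector, reusing the lateral-extent range
    out$stem_length <- stats::runif(1, archetype$max_radius_range[1],
                                    archetype$max_radius_range[2])
  }
  class(out) <- "root_system"
  out
}

# piecewise force-displacement curve for one tensile specimen: concave toe,
# linear elastic, shallower linear plastic to the break point, then a sharp
# post-break drop so break detection has something to find
tensile_curve <- function(f_peak, u_break) {
  u_toe <- 0.10 * u_break
  u_el <- 0.60 * u_break
  f_toe <- 0.15 * f_peak
  f_el <- 0.75 * f_peak
  u1 <- seq(0, u_toe, length.out = 6)
  f1 <- f_toe * (u1 / u_toe)^2
  u2 <- seq(u_toe, u_el, length.out = 10)[-1]
  f2 <- f_toe + (f_el - f_toe) * (u2 - u_toe) / (u_el - u_toe)
  u3 <- seq(u_el, u_break, length.out = 10)[-1]
  f3 <- f_el + (f_peak - f_el) * (u3 - u_el) / (u_break - u_el)
  u4 <- u_break * c(1.02, 1.05)
  f4 <- f_peak * c(0.30, 0.05)
  data.frame(displacement = c(u1, u2, u3, u4), force = c(f1, f2, f3, f4))
}

#' Generate tensile test records
#'
#' Each specimen draws a diameter from the archetype's lognormal
#' distribution; its true breaking stress is
#' \eqn{\alpha D^{-\beta}} times a multiplicative lognormal factor with
#' coefficient of variation `config$noise_cv` (log-scale mean zero, so
#' log-log regression recovers \eqn{\alpha} without bias). The
#' force-displacement record is a three-phase curve — concave toe
#' (stretching), linear elastic, shallower linear plastic phase ending at
#' the break — followed by a post-break force drop. The gauge length is at
#' least 30 diameters except for the `invalid_fraction` of specimens given a
#' deliberate violation (clamp failure, slippage, or a short gauge).
#'
#' @inheritParams generate_root_system
#' @return List of `tensile_test` records: `root_id`, `species`, `site`,
#'   `depth_layer`, `sector`, `diameters` (three readings, mm),
#'   `gauge_length` (mm), `curve` (displacement mm, force N),
#'   `failure_location`, `slipped`, `season_label`, and the generating truth
#'   in attribute `truth`.
#' @examples
#' tt <- generate_tensile_tests(default_archetypes()[["C. anomala"]],
#'                              generator_config(seed = 1, n_tensile = 5))
#' tt[[1]]$gauge_length
#' @export
generate_tensile_tests <- function(archetype, config = generator_config()) {
  stopifnot(inherits(archetype, "species_archetype"))
  config <- as_config(config)
  if (config$n_tensile < 1) stop("'n_tensile' must be >= 1")
  if (config$noise_cv < 0) stop("'noise_cv' must be non-negative")
  set.seed(config$seed)

  n <- config$n_tensile
  d <- stats::rlnorm(n, archetype$diameter_meanlog, archetype$diameter_sdlog)
  t_true <- archetype$tmax_alpha * d^(-archetype$tmax_beta)
  t_obs <- t_true * lnorm_noise(n, config$noise_cv)
  eps <- archetype$eps_ult_mean * lnorm_noise(n, config$noise_cv * 0.5)
  invalid <- stats::runif(n) < config$invalid_fraction
  modes <- sample(c("clamp", "outer_third", "slipped", "short_gauge"),
                  n, replace = TRUE)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    gauge <- 30 * d[i] * 1.25
    failure_location <- "middle_third"
    slipped <- FALSE
    if (invalid[i]) {
      switch(modes[i],
             clamp = failure_location <- "clamp",
             outer_third = failure_location <- "outer_third",
             slipped = slipped <- TRUE,
             short_gauge = gauge <- 30 * d[i] * 0.8)
    }
    csa <- pi * d[i]^2 / 4
    u_break <- eps[i] / 100 * gauge
    test <- list(root_id = sprintf("%s_t%03d", archetype$name, i),
                 species = archetype$name, site = config$site_label,
                 depth_layer = sample(0:3, 1), sector = sample(c("up", "down"), 1),
                 diameters = rep(d[i], 3), gauge_length = gauge,
                 curve = tensile_curve(t_obs[i] * csa, u_break),
                 failure_location = failure_location, slipped = slipped,
                 season_label = "wet")
    attr(test, "truth") <- list(t_max = t_obs[i], eps_ult = eps[i],
                                diameter = d[i], invalid = invalid[i])
    class(test) <- "tensile_test"
    out[[i]] <- test
  }
  attr(out, "truth") <- list(alpha = archetype$tmax_alpha,
                             beta = archetype$tmax_beta)
  out
}

#' Generate three-point bending test records
#'
#' Each specimen is a coarse root with depth diameter `d` and width diameter
#' `w` (mild eccentricity under noise, `w = d` when `noise_cv = 0`). The true
#' bending modulus E is lognormal around the archetype mean and the
#' load-deflection curve has initial slope \eqn{k = 48 E I / L^3}
#' (three-point bending with central load, span L, elliptical-section second
#' moment I), softening beyond half the peak load. Spans satisfy the
#' span-to-depth validity threshold except for the `invalid_fraction` of
#' specimens built too short.
#'
#' @inheritParams generate_root_system
#' @param span_ratio_threshold Minimal span/depth ratio for a valid test.
#' @return List of `bending_test` records with the generating truth in
#'   attribute `truth` (per test: `e_modulus`).
#' @examples
#' bt <- generate_bending_tests(default_archetypes()[["R. chinensis"]],
#'                              generator_config(seed = 1, n_bending = 3))
#' attr(bt[[1]], "truth")$e_modulus
#' @export
generate_bending_tests <- function(archetype, config = generator_config(),
                                   span_ratio_threshold = 10) {
  stopifnot(inherits(archetype, "species_archetype"))
  config <- as_config(config)
  if (config$n_bending < 1) stop("'n_bending' must be >= 1")
  set.seed(config$seed + 1L)

  n <- config$n_bending
  # bending specimens are coarse: shift the diameter distribution up
  d <- 2 + stats::rlnorm(n, archetype$diameter_meanlog, archetype$diameter_sdlog / 2)
  ecc <- if (config$noise_cv == 0) rep(1, n) else
    exp(stats::rnorm(n, 0, 0.05))
  w <- d * ecc
  e_true <- archetype$bending_modulus_mean * lnorm_noise(n, config$noise_cv)
  invalid <- stats::runif(n) < config$invalid_fraction

  out <- vector("list", n)
  for (i in seq_len(n)) {
    span <- span_ratio_threshold * d[i] * if (invalid[i]) 0.7 else 1.5
    i_sec <- pi * w[i] * d[i]^3 / 64
    k <- 48 * e_true[i] * i_sec / span^3 # N/mm
    delta_max <- span / 20
    u1 <- seq(0, delta_max / 2, length.out = 12)
    f1 <- k * u1
    u2 <- seq(delta_max / 2, delta_max, length.out = 8)[-1]
    f2 <- f1[length(f1)] + 0.6 * k * (u2 - delta_max / 2)
    test <- list(root_id = sprintf("%s_b%03d", archetype$name, i),
                 species = archetype$name, site = config$site_label,
                 depth_layer = sample(0:2, 1), sector = sample(c("up", "down"), 1),
                 depth_diameter = d[i], width_diameter = w[i], span = span,
                 curve = data.frame(deflection = c(u1, u2), force = c(f1, f2)))
    attr(test, "truth") <- list(e_modulus = e_true[i], invalid = invalid[i])
    class(test) <- "bending_test"
    out[[i]] <- test
  }
  out
}

#' Generate direct-shear test records
#'
#' Produces `config$n_shear` replicate sets over the given normal loads. For
#' each record the true peak shear stress follows the Mohr-Coulomb envelope
#' \eqn{\tau = c + \sigma \tan\phi} with normal stress
#' \eqn{\sigma = \mathrm{load} / \mathrm{box\_area}}; homoskedastic Gaussian
#' noise with standard deviation `noise_cv` times the mean true shear stress
#' over the load set is added (none when `noise_cv = 0`).
#'
#' @param cohesion True soil cohesion c (kPa).
#' @param friction_angle True internal friction angle \eqn{\phi} (degrees),
#'   in `[0, 90)`.
#' @param loads Applied normal loads (N); defaults to the 200/300/500 N
#'   protocol.
#' @param config A [generator_config].
#' @param box_area Shear-box plan area (m^2); defaults to a 60 mm x 60 mm box.
#' @param horizon Soil horizon label, `"A"` or `"B"`.
#' @return List of `shear_test` records (`normal_load` N, `box_area` m^2,
#'   `peak_shear_force` N, `site`, `horizon`).
#' @examples
#' st <- generate_shear_tests(5, 30, config = generator_config(seed = 1,
#'                            n_shear = 2, noise_cv = 0))
#' mohr_coulomb_fit(st)
#' @export
generate_shear_tests <- function(cohesion, friction_angle,
                                 loads = c(200, 300, 500),
                                 config = generator_config(),
                                 box_area = 0.06 * 0.06,
                                 horizon = c("A", "B")) {
  horizon <- match.arg(horizon)
  config <- as_config(config)
  if (length(loads) == 0) stop("'loads' must not be empty")
  if (any(loads <= 0)) stop("'loads' must be positive")
  if (friction_angle < 0 || friction_angle >= 90) {
    stop("'friction_angle' must lie in [0, 90) degrees")
  }
  set.seed(config$seed + 2L)

  sigma <- rep(loads, times = config$n_shear) / box_area / 1000 # kPa
  tau_true <- cohesion + sigma * tan(friction_angle * pi / 180)
  noise_sd <- config$noise_cv * mean(cohesion +
    (loads / box_area / 1000) * tan(friction_angle * pi / 180))
  tau <- tau_true + stats::rnorm(length(sigma), 0, noise_sd)

  lapply(seq_along(sigma), function(i) {
    structure(list(normal_load = rep(loads, times = config$n_shear)[i],
                   box_area = box_area,
                   peak_shear_force = tau[i] * box_area * 1000,
                   site = config$site_label, horizon = horizon),
              class = "shear_test")
  })
}

#' Generate soil mass/volume sample records
#'
#' Emits `(m_i, m_s, m_d, v)` tuples (fresh, saturated, oven-dry mass in g
#' and paraffin-displacement volume in cm^3) whose gravimetric water
#' contents and dry bulk density scatter around the requested true values
#' with coefficient of variation `config$noise_cv`.
#'
#' @param true_w_i,true_w_s True initial and saturated gravimetric water
#'   contents (% of dry mass); `true_w_s >= true_w_i` required.
#' @param true_rho_d True dry bulk density (g cm^-3).
#' @param n Number of samples.
#' @param config A [generator_config].
#' @return List of `soil_sample` records.
#' @examples
#' s <- generate_soil_samples(20, 50, 1.25, n = 1,
#'                            config = generator_config(seed = 1, noise_cv = 0))
#' gravimetric_properties(s[[1]])
#' @export
generate_soil_samples <- function(true_w_i, true_w_s, true_rho_d, n = 7,
                                  config = generator_config()) {
  config <- as_config(config)
  if (true_w_i < 0 || true_rho_d <= 0) stop("targets must be positive")
  if (true_w_s < true_w_i) {
    stop("infeasible targets: saturated water content below initial content")
  }
  set.seed(config$seed + 3L)
  m_d <- 100 * lnorm_noise(n, config$noise_cv * 0.2)
  w_i <- true_w_i * lnorm_noise(n, config$noise_cv)
  w_s <- pmax(true_w_s * lnorm_noise(n, config$noise_cv), w_i)
  rho <- true_rho_d * lnorm_noise(n, config$noise_cv)
  lapply(seq_len(n), function(i) {
    structure(list(m_i = m_d[i] * (1 + w_i[i] / 100),
                   m_s = m_d[i] * (1 + w_s[i] / 100),
                   m_d = m_d[i], v = m_d[i] / rho[i]),
              class = "soil_sample")
  })
}

#' Generate a quadrat stem-count survey
#'
#' Per-quadrat Poisson stem counts with the given per-species mean densities
#' (stems m^-2 in 1-m^2 quadrats).
#'
#' @param species_densities Named numeric vector, mean stems per m^2.
#' @param n_quadrats Number of quadrats.
#' @param config A [generator_config].
#' @param year Survey year label.
#' @return Data frame with `quadrat`, `species`, `count`, `site`, `year`.
#' @examples
#' generate_quadrat_survey(c("C. anomala" = 4), n_quadrats = 2,
#'                         config = generator_config(seed = 1))
#' @export
generate_quadrat_survey <- function(species_densities, n_quadrats = 8,
                                    config = generator_config(), year = 2010) {
  config <- as_config(config)
  if (is.null(names(species_densities)) || any(!nzchar(names(species_densities)))) {
    stop("'species_densities' must be a named vector")
  }
  if (any(species_densities < 0)) stop("densities must be >= 0")
  set.seed(config$seed + 4L)
  grid <- expand.grid(quadrat = seq_len(n_quadrats),
                      species = names(species_densities),
                      stringsAsFactors = FALSE)
  grid$count <- stats::rpois(nrow(grid),
                             species_densities[grid$species])
  grid$site <- config$site_label
  grid$year <- year
  grid
}
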