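#' Species root-system archetypes
#'
#' An archetype bundles the qualitative root-system description of a species
#' (growth form, radial vs linear layout, rooting depth and lateral spread
#' ranges) with the statistical parameters the synthetic-data generators use:
#' a lognormal root-diameter distribution, a power-law tensile strength
#' \eqn{T_{max} = \alpha D^{-\beta}}, a mean ultimate tensile strain, a mean
#' bending modulus, and mean nitrogen and cellulose mass fractions.
#'
#' A negative `tmax_beta` encodes strength *increasing* with diameter, as
#' observed for *F. tikoua* and *J. curcas*. A linear root layout (roots
#' organised along a horizontal stem rather than radiating from the collar)
#' is only admissible for creepers or species with underground stems; it
#' switches the individual-soil-volume model from quarter-ellipsoids to
#' quarter-cylinders.
#'
#' @param name Species label.
#' @param growth_form One of `"herb"`, `"shrub"`, `"creeper"`, `"climber"`,
#'   `"tree"`.
#' @param root_layout `"radial"` (default) or `"linear"`.
#' @param underground_stem Logical; `TRUE` for species whose coarse axes are
#'   underground stems rather than true roots.
#' @param max_depth_range Numeric length-2, rooting-depth interval (m).
#' @param max_radius_range Numeric length-2, lateral-extent interval (m).
#'   For linear layouts this is the along-stem extent per slope sector.
#' @param diameter_meanlog,diameter_sdlog Lognormal parameters of the root
#'   diameter distribution (mm).
#' @param tmax_alpha Strength coefficient \eqn{\alpha} (MPa mm^\eqn{\beta}).
#' @param tmax_beta Dimensionless exponent \eqn{\beta}; positive means
#'   strength decreases with diameter.
#' @param eps_ult_mean Mean ultimate tensile strain at breakage (%).
#' @param bending_modulus_mean Mean bending modulus of elasticity E (MPa).
#' @param n_concentration_mean Mean root nitrogen concentration (% dry mass).
#' @param cellulose_mean Mean root cellulose content (% dry mass).
#' @return An object of class `species_archetype`.
#' @examples
#' arch <- species_archetype("testplant", "herb",
#'   max_depth_range = c(0.2, 0.4), max_radius_range = c(0.2, 0.5),
#'   tmax_alpha = 20, tmax_beta = 0.8)
#' arch$tmax_alpha
#' @export
species_archetype <- function(name,
                              growth_form = c("herb", "shrub", "creeper",
                                              "climber", "tree"),
                              root_layout = c("radial", "linear"),
                              underground_stem = FALSE,
                              max_depth_range = c(0.2, 0.4),
                              max_radius_range = c(0.2, 0.5),
                              diameter_meanlog = log(0.5),
                              diameter_sdlog = 0.7,
                              tmax_alpha = 20,
                              tmax_beta = 0.8,
                              eps_ult_mean = 15,
                              bending_modulus_mean = 300,
                              n_concentration_mean = 1.2,
                              cellulose_mean = 18) {
  growth_form <- match.arg(growth_form)
  root_layout <- match.arg(root_layout)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(max_depth_range) != 2L || any(max_depth_range <= 0) ||
      diff(max_depth_range) < 0) {
    stop("'max_depth_range' must be a positive, non-decreasing interval (m)")
  }
  if (length(max_radius_range) != 2L || any(max_radius_range <= 0) ||
      diff(max_radius_range) < 0) {
    stop("'max_radius_range' must be a positive, non-decreasing interval (m)")
  }
  if (root_layout == "linear" && !(growth_form == "creeper" || underground_stem)) {
    stop("linear root layout is only admissible for creepers or ",
         "underground-stem species")
  }
  stopifnot(diameter_sdlog > 0, tmax_alpha > 0, eps_ult_mean > 0,
            bending_modulus_mean > 0, n_concentration_mean >= 0,
            cellulose_mean >= 0)
  structure(
    list(name = name, growth_form = growth_form, root_layout = root_layout,
         underground_stem = underground_stem,
         max_depth_range = as.numeric(max_depth_range),
         max_radius_range = as.numeric(max_radius_range),
         diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
         tmax_alpha = tmax_alpha, tmax_beta = tmax_beta,
         eps_ult_mean = eps_ult_mean,
         bending_modulus_mean = bending_modulus_mean,
         n_concentration_mean = n_concentration_mean,
         cellulose_mean = cellulose_mean),
    class = "species_archetype")
}

#' @export
print.species_archetype <- function(x, ...) {
  cat(sprintf("<species_archetype> %s (%s, %s layout)\n", x$name,
              x$growth_form, x$root_layout))
  cat(sprintf("  depth %0.2f-%0.2f m, radius %0.2f-%0.2f m\n",
              x$max_depth_range[1], x$max_depth_range[2],
              x$max_radius_range[1], x$max_radius_range[2]))
  cat(sprintf("  T_max = %0.1f * D^-%0.2f MPa, eps_ult ~ %0.1f%%\n",
              x$tmax_alpha, x$tmax_beta, x$eps_ult_mean))
  invisible(x)
}

#' Default archetypes for the nine study species
#'
#' Qualitative stand-ins for the nine species studied on degraded slopes of
#' the Salween valley (Yunnan): a rosette succulent with underground stems
#' (*Agave americana*), two herbs (*Arthraxon hispidus*, *Chloris anomala*),
#' a composite herb with descending laterals (*Artemisia codonocephala*), a
#' leguminous liana (*Bauhinia championii*), a creeping fig (*Ficus tikoua*),
#' a small tree (*Jatropha curcas*), a deep-taprooted leguminous shrub
#' (*Pueraria stricta*) and a root-sprouting tree (*Rhus chinensis*).
#'
#' Numeric parameter values are plausible fixtures chosen to reproduce the
#' qualitative ordering of the field observations (e.g. *P. stricta* fine
#' roots strongest and least extensible, *F. tikoua* most extensible with
#' strength increasing with diameter); they are not estimates of the
#' unpublished raw data.
#'
#' @return Named list of [species_archetype] objects.
#' @examples
#' names(default_archetypes())
#' @export
default_archetypes <- function() {
  a <- list(
    species_archetype("A. americana", "herb", "linear", underground_stem = TRUE,
      max_depth_range = c(0.10, 0.30), max_radius_range = c(0.20, 0.50),
      diameter_meanlog = log(1.2), diameter_sdlog = 0.8,
      tmax_alpha = 15, tmax_beta = -0.2, eps_ult_mean = 12,
      bending_modulus_mean = 150,
      n_concentration_mean = 0.8, cellulose_mean = 15),
    species_archetype("A. codonocephala", "herb",
      max_depth_range = c(0.20, 0.40), max_radius_range = c(0.30, 0.60),
      diameter_meanlog = log(0.4), diameter_sdlog = 0.7,
      tmax_alpha = 30, tmax_beta = 0.9, eps_ult_mean = 12,
      bending_modulus_mean = 250,
      n_concentration_mean = 2.5, cellulose_mean = 25),
    species_archetype("A. hispidus", "herb",
      max_depth_range = c(0.05, 0.15), max_radius_range = c(0.05, 0.15),
      diameter_meanlog = log(0.3), diameter_sdlog = 0.6,
      tmax_alpha = 25, tmax_beta = 0.7, eps_ult_mean = 20,
      bending_modulus_mean = 100,
      n_concentration_mean = 0.9, cellulose_mean = 12),
    species_archetype("B. championii", "climber",
      max_depth_range = c(0.40, 0.70), max_radius_range = c(0.40, 0.80),
      diameter_meanlog = log(0.8), diameter_sdlog = 0.8,
      tmax_alpha = 18, tmax_beta = 0.6, eps_ult_mean = 19,
      bending_modulus_mean = 400,
      n_concentration_mean = 1.5, cellulose_mean = 13),
    species_archetype("C. anomala", "herb",
      max_depth_range = c(0.05, 0.20), max_radius_range = c(0.05, 0.20),
      diameter_meanlog = log(0.35), diameter_sdlog = 0.6,
      tmax_alpha = 28, tmax_beta = 0.8, eps_ult_mean = 13,
      bending_modulus_mean = 120,
      n_concentration_mean = 0.9, cellulose_mean = 24),
    species_archetype("F. tikoua", "creeper", "linear",
      max_depth_range = c(0.10, 0.30), max_radius_range = c(0.20, 0.60),
      diameter_meanlog = log(0.7), diameter_sdlog = 0.7,
      tmax_alpha = 20, tmax_beta = -0.3, eps_ult_mean = 23,
      bending_modulus_mean = 200,
      n_concentration_mean = 0.9, cellulose_mean = 24),
    species_archetype("J. curcas", "tree",
      max_depth_range = c(0.20, 0.40), max_radius_range = c(0.20, 0.40),
      diameter_meanlog = log(1.0), diameter_sdlog = 0.7,
      tmax_alpha = 10, tmax_beta = -0.2, eps_ult_mean = 13,
      bending_modulus_mean = 500,
      n_concentration_mean = 0.8, cellulose_mean = 26),
    species_archetype("P. stricta", "shrub",
      max_depth_range = c(0.40, 0.60), max_radius_range = c(0.20, 0.50),
      diameter_meanlog = log(0.5), diameter_sdlog = 0.7,
      tmax_alpha = 32, tmax_beta = 0.8, eps_ult_mean = 9.8,
      bending_modulus_mean = 600,
      n_concentration_mean = 2.3, cellulose_mean = 12),
    species_archetype("R. chinensis", "tree",
      max_depth_range = c(0.40, 0.60), max_radius_range = c(0.40, 0.80),
      diameter_meanlog = log(1.0), diameter_sdlog = 0.7,
      tmax_alpha = 8, tmax_beta = 0.5, eps_ult_mean = 19,
      bending_modulus_mean = 450,
      n_concentration_mean = 1.4, cellulose_mean = 10)
  )
  stats::setNames(a, vapply(a, `[[`, "", "name"))
}
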