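# shared fixtures for the suite

test_archetype <- function(alpha = 20, beta = 0.8, ...) {
  species_archetype("testplant", "herb", tmax_alpha = alpha,
                    tmax_beta = beta, ...)
}

# expected scorecard cells of the published multi-criteria table, in the
# species order of the shipped fixture (frozen after cell-by-cell
# verification against the printed table)
expected_cards <- data.frame(
  species = c("A. americana", "A. codonocephala", "A. hispidus",
              "B. championii", "C. anomala", "F. tikoua", "J. curcas",
              "P. stricta", "R. chinensis"),
  composite_tension = c(1, 3, 3, 2, 3, 2, 1, 3, 1),
  composite_bending = c(3, 1, 1, 2, 1, 1, 3, 3, 3),
  global_abundance = c(2, 2, 2, 2, 1, 1, 1, 2, 2),
  global_mechanical = c(3, 3, 1, 1, 3, 1, 3, 3, 1),
  global_physiological = c(1, 3, 1, 1, 2, 1, 2, 3, 1),
  stringsAsFactors = FALSE)

# Monte-Carlo volume of one ISV sector, for use as an independent oracle.
# Radial: quarter ellipsoid of revolution (upslope half of the below-ground
# half), sampled in the box [0,r] x [-r,r] x [0,z]. Linear: quarter
# elliptical cylinder of length l, sampled in [0,l] x [0,r] x [0,z].
mc_sector_volume <- function(r, z, l = NULL, n = 1e6) {
  if (is.null(l)) {
    x <- runif(n, 0, r); y <- runif(n, -r, r); t <- runif(n, 0, z)
    mean((x / r)^2 + (y / r)^2 + (t / z)^2 <= 1) * (2 * r^2 * z)
  } else {
    y <- runif(n, 0, r); t <- runif(n, 0, z)
    mean((y / r)^2 + (t / z)^2 <= 1) * (r * z) * l
  }
}

# build a tensile test record directly (bypassing the generator)
make_tensile_test <- function(curve, diameters, gauge_length,
                              failure_location = "middle_third",
                              slipped = FALSE) {
  structure(list(root_id = "r1", species = "testplant", site = "hotspot",
                 depth_layer = 0, sector = "up", diameters = diameters,
                 gauge_length = gauge_length, curve = curve,
                 failure_location = failure_location, slipped = slipped,
                 season_label = "wet"),
            class = "tensile_test")
}
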