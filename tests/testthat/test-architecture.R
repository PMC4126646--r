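radial_system <- function(r_up = 1, r_down = 1, z = 1, dc = 1) {
  list(max_radius_up = r_up, max_radius_down = r_down, max_depth = z,
       collar_diameter = dc, layout = "radial")
}

test_that("radial ISV equals the quarter-ellipsoid closed form and its MC oracle", {
  isv <- individual_soil_volume(radial_system())
  expect_equal(isv$total, 2 * pi / 3, tolerance = 1e-12)
  expect_equal(isv$isv_over_dc, 2 * pi / 3, tolerance = 1e-12)
  set.seed(1)
  mc <- mc_sector_volume(1, 1) + mc_sector_volume(1, 1)
  expect_lt(abs(isv$total - mc) / mc, 0.005)

  asym <- individual_soil_volume(radial_system(r_up = 0.8, r_down = 0.3,
                                               z = 0.5, dc = 2))
  expect_equal(asym$total,
               pi * 0.8^2 * 0.5 / 3 + pi * 0.3^2 * 0.5 / 3,
               tolerance = 1e-12)
  expect_equal(asym$isv_over_dc, asym$total / 2, tolerance = 1e-12)
})

test_that("linear ISV equals the quarter-cylinder closed form", {
  sys <- list(max_radius_up = 0.4, max_radius_down = 0.2, max_depth = 0.3,
              collar_diameter = 1, layout = "linear", stem_length = 1.5)
  isv <- individual_soil_volume(sys)
  expect_equal(isv$total,
               pi * 0.4 * 0.3 * 1.5 / 4 + pi * 0.2 * 0.3 * 1.5 / 4,
               tolerance = 1e-12)
  set.seed(2)
  mc <- mc_sector_volume(0.4, 0.3, l = 1.5) + mc_sector_volume(0.2, 0.3, l = 1.5)
  expect_lt(abs(isv$total - mc) / mc, 0.005)
  expect_error(individual_soil_volume(sys[setdiff(names(sys), "stem_length")]),
               "stem_length")
})

test_that("slab partition sums to the total for any layer width", {
  for (h in c(0.03, 0.10, 0.17, 0.25)) {
    isv <- individual_soil_volume(radial_system(r_up = 0.7, r_down = 0.4,
                                                z = 0.55), layer_height = h)
    expect_equal(sum(isv$per_sector_per_layer$volume), isv$total,
                 tolerance = 1e-9)
    expect_true(all(isv$per_sector_per_layer$volume >= 0))
  }
  sys <- list(max_radius_up = 0.4, max_radius_down = 0.2, max_depth = 0.3,
              collar_diameter = 1, layout = "linear", stem_length = 1.5)
  isv <- individual_soil_volume(sys, layer_height = 0.04)
  expect_equal(sum(isv$per_sector_per_layer$volume), isv$total,
               tolerance = 1e-9)
})

test_that("degenerate extents give zero volume", {
  expect_equal(individual_soil_volume(radial_system(z = 0))$total, 0)
  expect_equal(individual_soil_volume(radial_system(r_up = 0, r_down = 0))$total, 0)
})

test_that("RAR worked cases: single perpendicular root and V_r/V", {
  # one vertical root of 2 mm crossing a 100-mm layer over A = 1e4 mm^2
  seg <- data.frame(depth_layer = 0, sector = "up", diameter = 2,
                    length = 100, volume = NA)
  r <- root_area_ratio(seg, reference_area = 1e4, layer_height = 100)
  expect_equal(r$rar[r$class == "coarse"], pi * 1e-4, tolerance = 1e-12)
  expect_equal(r$rar[r$class == "fine"], 0)
  expect_equal(r$rar[r$class == "all"], pi * 1e-4, tolerance = 1e-12)

  seg2 <- data.frame(depth_layer = 0, sector = "up", diameter = 1,
                     length = NA, volume = 100)
  r2 <- root_area_ratio(seg2, reference_area = 1e3, layer_height = 100)
  expect_equal(r2$rar[r2$class == "all"], 100 / 1e5, tolerance = 1e-12)
})

test_that("fine + coarse RAR partitions the total, with 2 mm in the coarse class", {
  set.seed(42)
  seg <- data.frame(depth_layer = sample(0:3, 60, TRUE),
                    sector = sample(c("up", "down"), 60, TRUE),
                    diameter = exp(rnorm(60, log(1), 1)),
                    length = runif(60, 10, 200), volume = NA)
  seg$diameter[1:3] <- 2 # boundary diameter
  r <- root_area_ratio(seg, reference_area = 1e4, layer_height = 100)
  wide <- reshape(as.data.frame(r), idvar = c("depth_layer", "sector"),
                  timevar = "class", direction = "wide")
  expect_equal(wide$rar.fine + wide$rar.coarse, wide$rar.all,
               tolerance = 1e-12)
  # boundary roots went coarse
  b <- root_area_ratio(seg[1:3, ], reference_area = 1e4, layer_height = 100)
  expect_true(all(b$rar[b$class == "fine"] == 0))
})

test_that("RAR decreases when any segment is removed and counts each segment once", {
  set.seed(7)
  seg <- data.frame(depth_layer = sample(0:2, 30, TRUE),
                    sector = sample(c("up", "down"), 30, TRUE),
                    diameter = runif(30, 0.2, 4),
                    length = runif(30, 10, 100), volume = NA)
  A <- 1e4; h <- 100
  full <- root_area_ratio(seg, A, h)
  total_rar <- sum(full$rar[full$class == "all"])
  for (i in c(1, 15, 30)) {
    less <- root_area_ratio(seg[-i, ], A, h)
    expect_lt(sum(less$rar[less$class == "all"]), total_rar)
  }
  # exhaustive, disjoint bucketing: summed cell volumes recover the total
  expect_equal(sum(full$rar[full$class == "all"]) * A * h,
               sum(pi * (seg$diameter / 2)^2 * seg$length),
               tolerance = 1e-9)
  expect_error(root_area_ratio(data.frame(depth_layer = 0, sector = "up",
                                          diameter = NA, length = NA,
                                          volume = NA), A, h),
               "neither")
})

test_that("system-level RAR and arch_traits run end to end on generated plants", {
  arch <- test_archetype()
  systems <- lapply(1:2, function(i) {
    generate_root_system(arch, generator_config(seed = i),
                         plant_id = paste0("p", i))
  })
  tab <- arch_traits(systems)
  expect_true(all(tab$rar >= 0))
  expect_setequal(unique(tab$class), c("fine", "coarse", "all"))
  expect_true(all(tab$isv_total > 0))
  # footprint override: a fixed reference area gives the scalar-A result
  rar_fixed <- system_rar(systems[[1]], reference_area = 1e4)
  direct <- root_area_ratio(systems[[1]]$segments, 1e4, 100)
  expect_equal(sort(rar_fixed$rar[rar_fixed$class == "all"]),
               sort(direct$rar[direct$class == "all"]), tolerance = 1e-12)
})
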