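test_that("generators are deterministic under a fixed seed", {
  arch <- test_archetype()
  cfg <- generator_config(seed = 7, n_tensile = 20, n_bending = 5,
                          n_shear = 3, noise_cv = 0.2)
  expect_identical(generate_root_system(arch, cfg),
                   generate_root_system(arch, cfg))
  expect_identical(generate_tensile_tests(arch, cfg),
                   generate_tensile_tests(arch, cfg))
  expect_identical(generate_bending_tests(arch, cfg),
                   generate_bending_tests(arch, cfg))
  expect_identical(generate_shear_tests(5, 30, config = cfg),
                   generate_shear_tests(5, 30, config = cfg))
  expect_identical(generate_soil_samples(20, 50, 1.25, n = 4, config = cfg),
                   generate_soil_samples(20, 50, 1.25, n = 4, config = cfg))
  expect_identical(generate_quadrat_survey(c(a = 4), config = cfg),
                   generate_quadrat_survey(c(a = 4), config = cfg))
})

test_that("root systems respect archetype geometry and layout", {
  arch <- species_archetype("taprooted", "shrub",
                            max_depth_range = c(0.4, 0.6),
                            max_radius_range = c(0.2, 0.5))
  rs <- generate_root_system(arch, generator_config(seed = 1))
  expect_true(rs$max_depth >= 0.4 && rs$max_depth <= 0.6)
  expect_true(all(c(rs$max_radius_up, rs$max_radius_down) >= 0.2))
  # every segment layer lies within the sampled maximal depth
  expect_true(all(rs$segments$depth_layer * 0.10 < rs$max_depth))
  expect_true(all(rs$segments$sector %in% c("up", "down")))
  expect_null(rs$stem_length)

  creeper <- species_archetype("creeping", "creeper", "linear",
                               max_depth_range = c(0.1, 0.3),
                               max_radius_range = c(0.2, 0.6))
  rs2 <- generate_root_system(creeper, generator_config(seed = 1))
  expect_identical(rs2$layout, "linear")
  expect_true(is.numeric(rs2$stem_length) && rs2$stem_length > 0)
})

test_that("linear layout is rejected for ordinary radial growth forms", {
  expect_error(species_archetype("bad", "shrub", "linear"),
               "creepers or")
})

test_that("noiseless tensile tests hit the power law exactly and noisy ones do not", {
  arch <- test_archetype(alpha = 20, beta = 0.8)
  tt <- generate_tensile_tests(arch, generator_config(seed = 3, n_tensile = 25,
                                                      noise_cv = 0))
  for (t in tt) {
    truth <- attr(t, "truth")
    expect_equal(max(t$curve$force) / (pi * mean(t$diameters)^2 / 4),
                 20 * truth$diameter^-0.8, tolerance = 1e-12)
    expect_true(t$gauge_length >= 30 * mean(t$diameters))
  }
  noisy <- generate_tensile_tests(arch, generator_config(seed = 3,
                                                         n_tensile = 25,
                                                         noise_cv = 0.2))
  t_obs <- sapply(noisy, function(t) attr(t, "truth")$t_max)
  d <- sapply(noisy, function(t) attr(t, "truth")$diameter)
  expect_gt(sd(log(t_obs) - log(20 * d^-0.8)), 0)
})

test_that("deliberately injected specimen violations are flagged and countable", {
  arch <- test_archetype()
  tt <- generate_tensile_tests(arch, generator_config(seed = 11,
                                                      n_tensile = 100,
                                                      noise_cv = 0.1,
                                                      invalid_fraction = 0.1))
  flagged <- sapply(tt, function(t) attr(t, "truth")$invalid)
  # binomial(100, 0.1) within 3 sigma of its mean
  expect_gte(sum(flagged), 1)
  expect_lte(sum(flagged), 19)
  res <- lapply(tt, tensile_curve_metrics)
  valid <- sapply(res, `[[`, "valid")
  expect_true(all(!valid[flagged]))
  expect_true(all(valid[!flagged]))
})

test_that("shear generation maps loads to the stated normal stresses", {
  st <- generate_shear_tests(5, 30, loads = c(200, 300, 500),
                             config = generator_config(seed = 1, n_shear = 1,
                                                       noise_cv = 0))
  sigma <- sapply(st, function(t) t$normal_load / t$box_area / 1000)
  expect_equal(sigma, c(200, 300, 500) / 0.0036 / 1000, tolerance = 1e-12)
  expect_equal(round(sigma, 2), c(55.56, 83.33, 138.89))
  expect_error(generate_shear_tests(5, 30, loads = numeric()), "empty")
  expect_error(generate_shear_tests(5, 95), "90")
  expect_error(generate_shear_tests(5, 30, loads = c(-1, 200)), "positive")
})

test_that("soil sample generation round-trips and rejects infeasible targets", {
  s <- generate_soil_samples(20, 50, 1.25, n = 3,
                             config = generator_config(seed = 1, noise_cv = 0))
  for (x in s) {
    p <- gravimetric_properties(x)
    expect_equal(p$w_i, 20, tolerance = 1e-12)
    expect_equal(p$w_s, 50, tolerance = 1e-12)
    expect_equal(p$rho_d, 1.25, tolerance = 1e-12)
    expect_true(x$m_s >= x$m_i && x$m_i >= x$m_d && x$v > 0)
  }
  expect_error(generate_soil_samples(50, 20, 1.25), "infeasible")
})

test_that("quadrat surveys are Poisson with the requested means", {
  expect_true(all(generate_quadrat_survey(c(absent = 0), n_quadrats = 50,
                                          config = generator_config(seed = 2))$count == 0))
  big <- generate_quadrat_survey(c(sp = 4), n_quadrats = 1000,
                                 config = generator_config(seed = 5))
  se <- sqrt(4 / 1000)
  expect_lt(abs(mean(big$count) - 4), 3 * se)
  expect_error(generate_quadrat_survey(c(sp = -1)), ">= 0")
})
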