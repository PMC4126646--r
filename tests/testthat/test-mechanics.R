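test_that("tensile metrics implement force/area and displacement/gauge", {
  d <- sqrt(4 * 0.5 / pi) # CSA = 0.5 mm^2
  curve <- data.frame(displacement = c(0, 1, 2, 3, 4, 5, 5.2, 5.4),
                      force = c(0, 2, 4, 7, 9, 10, 3, 0.5))
  test <- make_tensile_test(curve, rep(d, 3), gauge_length = 50)
  r <- tensile_curve_metrics(test)
  expect_equal(r$t_max, 10 / 0.5, tolerance = 1e-12)
  expect_equal(r$eps_ult, 100 * 5 / 50, tolerance = 1e-12)
  expect_equal(r$csa, 0.5, tolerance = 1e-12)
  expect_true(r$valid)
})

test_that("specimen validity rules exclude clamp failures, slippage and short gauges", {
  d <- 1
  curve <- data.frame(displacement = 0:6,
                      force = c(0, 2, 4, 6, 8, 2, 0.5))
  clamp <- make_tensile_test(curve, rep(d, 3), 40, failure_location = "clamp")
  expect_false(tensile_curve_metrics(clamp)$valid)
  expect_true("failure_outside_middle_third" %in%
                tensile_curve_metrics(clamp)$invalid_reasons)
  slip <- make_tensile_test(curve, rep(d, 3), 40, slipped = TRUE)
  expect_true("slipped_in_clamps" %in% tensile_curve_metrics(slip)$invalid_reasons)
  short <- make_tensile_test(curve, rep(d, 3), 20)
  expect_true("gauge_below_span_ratio" %in%
                tensile_curve_metrics(short)$invalid_reasons)
  # a record that ends still ascending has no detectable break
  rising <- make_tensile_test(data.frame(displacement = 0:5,
                                         force = c(0, 1, 2, 3, 4, 5)),
                              rep(d, 3), 40)
  r <- tensile_curve_metrics(rising)
  expect_false(r$valid)
  expect_true("no_detectable_break" %in% r$invalid_reasons)
})

test_that("power-law fit is exact on noiseless data and filters invalid results", {
  d <- c(0.2, 0.4, 0.8, 1.6)
  df <- data.frame(t_max = 20 * d^-0.8, mean_diameter = d, valid = TRUE)
  fit <- fit_tmax_power_law(df)
  expect_equal(fit$alpha, 20, tolerance = 1e-10)
  expect_equal(fit$beta, 0.8, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_identical(fit$n, 4L)

  df$valid <- FALSE
  expect_error(fit_tmax_power_law(df), "valid")
  mixed <- rbind(df, data.frame(t_max = c(5, 500, 50),
                                mean_diameter = c(1, 1e-3, 0.1),
                                valid = TRUE))
  fit2 <- fit_tmax_power_law(mixed)
  expect_identical(fit2$n, 3L) # only the valid rows enter
  expect_error(fit_tmax_power_law(data.frame(t_max = c(-1, 2, 3),
                                             mean_diameter = c(1, 2, 3),
                                             valid = TRUE)), "positive")
})

test_that("with positive beta the fitted curve is strictly decreasing in diameter", {
  arch <- test_archetype(alpha = 30, beta = 0.9)
  tt <- generate_tensile_tests(arch, generator_config(seed = 4, n_tensile = 80,
                                                      noise_cv = 0.2))
  fit <- fit_tmax_power_law(lapply(tt, tensile_curve_metrics))
  expect_gt(fit$beta, 0)
  dd <- seq(0.1, 3, length.out = 50)
  pred <- fit$alpha * dd^(-fit$beta)
  expect_true(all(diff(pred) < 0))
})

test_that("second moment matches the circular closed form and scales cubically", {
  expect_equal(second_moment_of_inertia(2), pi * 2^4 / 64, tolerance = 1e-15)
  d_grid <- 10^seq(-1, 1.5, length.out = 20)
  expect_equal(second_moment_of_inertia(d_grid), pi * d_grid^4 / 64,
               tolerance = 1e-15)
  expect_identical(second_moment_of_inertia(0), 0)
  expect_equal(second_moment_of_inertia(2 * 1.3, w = 0.7),
               8 * second_moment_of_inertia(1.3, w = 0.7), tolerance = 1e-12)
  expect_error(second_moment_of_inertia(-1), "non-negative")
})

test_that("bending metrics recover a known modulus from the closed form", {
  arch <- test_archetype()
  bt <- generate_bending_tests(arch, generator_config(seed = 2, n_bending = 10,
                                                      noise_cv = 0))
  for (t in bt) {
    r <- bending_metrics(t)
    e_true <- attr(t, "truth")$e_modulus
    expect_lt(abs(r$bending_modulus - e_true) / e_true, 1e-3)
    expect_equal(r$rigidity, r$bending_modulus * r$second_moment / 1000,
                 tolerance = 1e-12)
    expect_true(r$valid)
  }
})

test_that("bending validity enforces the span ratio and monotone start", {
  arch <- test_archetype()
  bt <- generate_bending_tests(arch, generator_config(seed = 3, n_bending = 20,
                                                      noise_cv = 0,
                                                      invalid_fraction = 1))
  r <- bending_metrics(bt[[1]])
  expect_false(r$valid)
  expect_true("span_below_span_ratio" %in% r$invalid_reasons)

  wiggle <- bt[[2]]
  wiggle$span <- wiggle$depth_diameter * 20
  wiggle$curve$force[3] <- wiggle$curve$force[3] * -0.5
  r2 <- bending_metrics(wiggle)
  expect_true("non_monotone_initial_region" %in% r2$invalid_reasons)
})

test_that("mech_traits tabulates both test kinds with validity carried through", {
  arch <- test_archetype()
  cfg <- generator_config(seed = 6, n_tensile = 8, n_bending = 4,
                          noise_cv = 0.1, invalid_fraction = 0.25)
  tab <- mech_traits(generate_tensile_tests(arch, cfg),
                     generate_bending_tests(arch, cfg))
  expect_identical(nrow(tab), 12L)
  expect_setequal(unique(tab$kind), c("tensile", "bending"))
  expect_true(all(!tab$valid | tab$invalid_reasons == ""))
  expect_true(all(is.na(tab$t_max[tab$kind == "bending"])))
})
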