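test_that("analytical sensitivity follows A_effect / (n A_FOV v t)", {
  p <- pe_sampling()
  expect_equal(analytical_sensitivity(p), 385 / (25 * 0.0031 * 2000 * 1),
               tolerance = 1e-12)
  expect_equal(analytical_sensitivity(p), 2.4839, tolerance = 1e-4)
  # identity parameter set
  expect_equal(analytical_sensitivity(sampling_params(4, 2, 2, 1, 1)), 1)
  # homogeneity: degree -1 in n_fov, a_fov, flow, duration; +1 in area
  base <- analytical_sensitivity(sampling_params(100, 0.01, 10, 1000, 5))
  expect_equal(analytical_sensitivity(sampling_params(100, 0.01, 20, 1000, 5)),
               base / 2)
  expect_equal(analytical_sensitivity(sampling_params(100, 0.02, 10, 1000, 5)),
               base / 2)
  expect_equal(analytical_sensitivity(sampling_params(100, 0.01, 10, 2000, 5)),
               base / 2)
  expect_equal(analytical_sensitivity(sampling_params(100, 0.01, 10, 1000, 10)),
               base / 2)
  expect_equal(analytical_sensitivity(sampling_params(200, 0.01, 10, 1000, 5)),
               base * 2)
  expect_error(sampling_params(385, 0.0031, 0, 2000, 1), "positive|integer")
  expect_error(sampling_params(-1, 0.0031, 25, 2000, 1), "positive")
  expect_error(sampling_params(0.01, 0.0031, 25, 2000, 1), "exceeds")
})

test_that("exact Poisson intervals match their closed forms", {
  unit <- sampling_params(4, 2, 2, 1, 1) # AS = 1
  # zero counts: lower 0, two-sided upper solves exp(-U) = 0.025
  e0 <- count_to_concentration(0, unit)
  expect_equal(e0$concentration_fcc, 0)
  expect_equal(e0$ci_fcc[1], 0)
  expect_equal(e0$ci_fcc[2], -log(0.025), tolerance = 1e-9)
  expect_equal(e0$ci_fcc[2], 3.689, tolerance = 1e-3)
  # N = 4: chi-square closed form
  e4 <- count_to_concentration(4, unit)
  expect_equal(e4$ci_fcc, c(1.090, 10.242), tolerance = 1e-3)
  # concentration is linear in N at fixed parameters
  p <- pe_sampling()
  as_fcc <- analytical_sensitivity(p)
  for (n in c(1, 10, 37))
    expect_equal(count_to_concentration(n, p)$concentration_fcc, n * as_fcc)
  expect_error(count_to_concentration(-1, p), "non-negative")
})

test_that("two-sided 95% interval coverage is conservative but bounded", {
  unit <- sampling_params(4, 2, 2, 1, 1)
  with_fixed_seed(5, {
    for (lambda in c(0.5, 10)) {
      n <- rpois(2000, lambda)
      covered <- vapply(n, function(ni) {
        ci <- count_to_concentration(ni, unit)$ci_fcc
        ci[1] <= lambda && lambda <= ci[2]
      }, logical(1))
      expect_gte(mean(covered), 0.93)
      expect_lte(mean(covered), 0.999)
    }
  })
})

test_that("limit of detection is the zero-count bound times the sensitivity", {
  p <- pe_sampling()
  expect_equal(limit_of_detection(p), -log(0.05) * analytical_sensitivity(p),
               tolerance = 1e-12)
  # with AS = 1 the LOD is the bare 2.996-fiber factor
  expect_equal(limit_of_detection(sampling_params(4, 2, 2, 1, 1)), 2.996,
               tolerance = 1e-3)
  # doubling the sampled volume halves the LOD
  p2 <- sampling_params(385, 0.0031, 25, 4000, 1)
  expect_equal(limit_of_detection(p2), limit_of_detection(p) / 2)
  # consistency with the N = 0 estimate through the same machinery
  e0 <- count_to_concentration(0, p, confidence = 0.90)
  expect_equal(limit_of_detection(p), e0$ci_fcc[2], tolerance = 1e-12)
})

test_that("the stopping rule fires on either cap and logs its reason", {
  expect_identical(termination_check(25, 12, n_max = 25),
                   list(stop = TRUE, reason = "n_max"))
  expect_identical(termination_check(3, 100, fiber_cap = 100),
                   list(stop = TRUE, reason = "fiber_cap"))
  expect_identical(termination_check(10, 12, fiber_cap = 100, n_max = 100),
                   list(stop = FALSE, reason = "continue"))
  expect_error(termination_check(-1, 0), "non-negative")
})

test_that("transect fields march outward edge to edge from the filter center", {
  # 64 x 48 um fields: a_fov = 0.003072 mm^2, width 0.064 mm
  centers <- fov_transect(12.5, 0.003072, 5)
  expect_equal(centers * 1000, c(0, 64, 128, 192, 256), tolerance = 1e-9)
  expect_equal(fov_transect(12.5, 0.003072, 1), 0)
  expect_error(fov_transect(0.2, 0.003072, 5), "exceeds")
})

test_that("calibration recovers exact lines and flags degenerate input", {
  x <- c(0, 0.02, 0.15, 0.37, 0.89, 1.7)
  fit <- calibrate_standards(x, 400 * x)
  expect_equal(fit$slope, 400, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 0.001)

  flat <- calibrate_standards(x, rep(7, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(calibrate_standards(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibrate_standards(rep(1, 5), 1:5), "variance")
})

test_that("calibration on simulated standards recovers the true slope", {
  # Poisson counting noise is heteroscedastic, so the plain OLS slope CI is
  # anti-conservative here; the estimator itself is unbiased and precise.
  p <- pe_sampling()
  series <- pe_standard_series()
  k <- 716 / 1.74
  fits <- lapply(1:60, function(s) {
    sim <- simulate_pe_experiment(series$mass_pct, p, k = k, seed = 4000 + s)
    calibrate_standards(sim$mass_pct, sim$concentration_fcc)
  })
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  expect_equal(mean(slopes), k, tolerance = 0.02)
  expect_gte(mean(abs(slopes - k) < 0.1 * k), 0.9)
  expect_gte(mean(vapply(fits, `[[`, numeric(1), "r_squared") >= 0.95), 0.9)
})
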