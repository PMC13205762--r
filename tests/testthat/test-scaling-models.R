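test_that("power-law slopes are recovered exactly on clean data", {
  A <- c(1, 4, 16, 64)
  surf <- data.frame(area_m2 = A, time_months = 1,
                     richness = exp(0.097 * log(A) + 2))
  f <- fit_power_law(surf, "area", "richness")
  expect_equal(f$model, "SAR")
  expect_lt(abs(f$slope - 0.097), 1e-10)
  expect_lt(abs(f$intercept - 2), 1e-10)
  expect_equal(f$r_squared, 1)
})

test_that("two-point SAR slope equals the log-ratio by hand", {
  surf <- data.frame(area_m2 = c(1, 10), time_months = 1,
                     richness = c(10, 20))
  f <- fit_power_law(surf, "area", "richness")
  expect_equal(f$slope, log(2) / log(10), tolerance = 1e-12)
})

test_that("degenerate power-law inputs are flagged or rejected", {
  surf <- data.frame(area_m2 = c(1, 4, 16), time_months = 1,
                     richness = c(7, 7, 7))
  f <- fit_power_law(surf, "area", "richness")
  expect_true(f$degenerate)
  expect_equal(f$slope, 0)
  expect_equal(f$r_squared, 0)
  expect_error(fit_power_law(
    data.frame(area_m2 = c(2, 2, 2), time_months = 1,
               richness = c(1, 2, 3)), "area", "richness"),
    "no variance")
  expect_error(fit_power_law(
    data.frame(area_m2 = c(1, 2, 4), time_months = 1,
               richness = c(0, 2, 3)), "area", "richness"),
    "positive")
})

test_that("interaction model recovers injected exponents exactly", {
  s <- simulate_star_surface(0.139, 0.366, -0.03, 5, noise_sd = 0)
  f <- fit_star(s)
  expect_lt(abs(f$z - 0.139), 1e-8)
  expect_lt(abs(f$w - 0.366), 1e-8)
  expect_lt(abs(f$u + 0.03), 1e-8)
  expect_lt(abs(f$b - 5), 1e-8)
  expect_equal(f$r_squared, 1)
  # PD channel through pd_coef behaves identically
  s2 <- simulate_star_surface(0.139, 0.366, -0.03, 5, noise_sd = 0,
                              pd_coef = list(z = 0.124, w = 0.331,
                                             u = -0.02, b = 4.5))
  fp <- fit_star(s2, "pd")
  expect_lt(abs(fp$z - 0.124), 1e-8)
  expect_lt(abs(fp$w - 0.331), 1e-8)
})

test_that("single-scale designs are rejected as rank-deficient", {
  s <- simulate_star_surface(0.1, 0.3, -0.02, 3, 0, time_lengths = 2)
  expect_error(fit_star(s), "rank-deficient")
  s2 <- simulate_star_surface(0.1, 0.3, -0.02, 3, 0, area_sizes = 4)
  expect_error(fit_star(s2), "rank-deficient")
})

test_that("model R-squared degrades with noise", {
  r2 <- vapply(c(0, 0.05, 0.3), function(sd) {
    mean(vapply(1:20, function(i)
      fit_star(simulate_star_surface(0.14, 0.37, -0.03, 5, sd,
                                     seed = i * 100 + round(sd * 1e3))
               )$r_squared, 0))
  }, 0)
  expect_equal(r2[1], 1)
  expect_true(all(diff(r2) < 0))
})

test_that("without interaction the spatial exponent matches per-time SAR", {
  s <- simulate_star_surface(0.21, 0.33, 0, 2, noise_sd = 0)
  f <- fit_star(s)
  for (tm in unique(s$time_months)) {
    sar <- fit_power_law(s[s$time_months == tm, ], "area", "richness")
    expect_lt(abs(sar$slope - f$z), 1e-10)
  }
})

test_that("equivalence ratio follows the exponent algebra", {
  f <- structure(list(response = "richness", z = 0.2, w = 0.2, u = -0.1,
                      b = 1, r_squared = 1, n = 10, area_unit = "m2",
                      time_unit = "month"), class = "star_fit")
  expect_equal(equivalence_ratio(f)$value, 1)
  f$w <- 0.5
  expect_equal(equivalence_ratio(f)$value, exp(3), tolerance = 1e-12)
  f$u <- 0
  expect_error(equivalence_ratio(f), "undefined")
  f$u <- 1e-12
  expect_warning(equivalence_ratio(f), "unstable")
})

test_that("unit rescaling is exact and consistent with refitting", {
  s <- simulate_star_surface(0.139, 0.366, -0.05, 5, noise_sd = 0)
  f <- fit_star(s)
  # identity
  f1 <- rescale_units(f, 1, 1)
  expect_equal(f1[c("z", "w", "u", "b")], f[c("z", "w", "u", "b")])
  # direct arithmetic: z' = z + u ln t
  f2 <- rescale_units(f, 1, 12)
  expect_equal(f2$z, 0.139 - 0.05 * log(12), tolerance = 1e-12)
  # refit oracle: rescaling the surface axes then refitting agrees
  a <- 1e6; tfac <- 12
  s_new <- s
  s_new$area_m2 <- s$area_m2 / a
  s_new$time_months <- s$time_months / tfac
  f_refit <- fit_star(s_new)
  f_conv <- rescale_units(f, a, tfac)
  for (cf in c("z", "w", "u", "b"))
    expect_lt(abs(f_refit[[cf]] - f_conv[[cf]]), 1e-8)
  # ratio transformation law, exact
  r0 <- equivalence_ratio(f)$value
  expect_lt(abs(equivalence_ratio(f_conv)$value - r0 * tfac / a),
            1e-10 * r0 * tfac / a + 1e-300)
  expect_error(rescale_units(f, -1, 12), "positive")
})
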