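test_that("permutation p-values use the add-one estimator", {
  # observed larger than all 199 nulls
  expect_equal(starscale:::perm_pvalue(1, seq_len(199) / 400, "upper"),
               1 / 200)
  # a null made of copies of the observed statistic gives p = 1
  expect_equal(starscale:::perm_pvalue(0.3, rep(0.3, 99), "upper"), 1)
  expect_equal(starscale:::perm_pvalue(-0.5, rep(0.5, 99), "two_sided"),
               1)
  # p always in {1/(R+1), ..., 1}
  set.seed(1)
  for (i in 1:20) {
    p <- starscale:::perm_pvalue(rnorm(1), rnorm(50), "two_sided")
    expect_true(p >= 1 / 51 && p <= 1)
    expect_equal(round(p * 51), p * 51)
  }
})

test_that("trailing remainder blocks stay intact", {
  blocks <- starscale:::block_partition(17, 3)
  expect_length(blocks, 6)
  expect_equal(lengths(blocks), c(3, 3, 3, 3, 3, 2))
  expect_identical(unlist(blocks), 1:17)
})

test_that("block permutation test reports valid, reproducible results", {
  d <- tiny_design(n_points = 5, n_times = 12)
  p <- simulation_params(pool_size = 60, depth_mean = 400,
                         temporal_turnover = 0.15, seed = 21)
  x <- simulate_communities(d, p)
  pt <- block_permutation_test(x, d, n_rand = 199, seed = 5)
  expect_s3_class(pt$r_squared, "permutation_result")
  expect_true(pt$r_squared$p_value >= 1 / 200 &&
                pt$r_squared$p_value <= 1)
  expect_equal(pt$r_squared$n_rand + pt$r_squared$n_discarded, 199)
  expect_named(pt, c("r_squared", "z", "w", "u"))
  fit <- attr(pt, "fit")
  expect_gt(fit$r_squared, 0.9)
  # same seed reproduces the null exactly
  pt2 <- block_permutation_test(x, d, n_rand = 199, seed = 5)
  expect_identical(pt$r_squared$null, pt2$r_squared$null)
  # cannot form two blocks on the time axis
  expect_error(block_permutation_test(x, d, n_rand = 19,
                                      block_size = 12),
               "2 blocks")
  expect_error(block_permutation_test(x, d, response = "pd",
                                      n_rand = 19), "requires a tree")
})

test_that("identical richness and PD responses give a null STAR-PTAR contrast", {
  s <- simulate_star_surface(0.14, 0.37, -0.03, 5, noise_sd = 0.01,
                             seed = 3)
  s$pd <- s$richness
  res <- star_ptar_difference_test(s, "w", n_rand = 99, seed = 7)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  expect_error(star_ptar_difference_test(s, "w", n_rand = 0), "n_rand")
  s$pd <- NULL
  expect_error(star_ptar_difference_test(s, "w", n_rand = 9),
               "phylogenetic")
})

test_that("the contrast test estimates the exponent gap and has sensitivity", {
  # the observed statistic recovers the injected temporal-exponent gap
  res <- vapply(1:50, function(i) {
    s <- simulate_star_surface(0.139, 0.366, -0.03, 5, noise_sd = 0.02,
                               seed = i,
                               pd_coef = list(z = 0.139, w = 0.331,
                                              u = -0.03, b = 5))
    out <- star_ptar_difference_test(s, "w", n_rand = 199,
                                     block_size = 1, seed = 1000 + i)
    c(obs = out$observed, hit = out$p_value < 0.05)
  }, c(obs = 0, hit = 0))
  expect_lt(abs(mean(res["obs", ]) - 0.035), 0.01)
  # per-scale swaps detect the gap well above the nominal level;
  # the contrast is conservative by construction (null spread scales
  # with the gap), so moderate power is the honest expectation here
  expect_gte(mean(res["hit", ]), 0.2)
})

test_that("window enumeration matches exhaustive listing", {
  w <- enumerate_windows(17, 5:7)
  expect_equal(as.vector(table(w$size)), c(13, 12, 11))
  expect_equal(nrow(enumerate_windows(17, 17)), 1)
  for (K in c(5, 11, 20)) for (s in 2:K) {
    wk <- enumerate_windows(K, s)
    expect_equal(nrow(wk), K - s + 1)
    expect_equal(wk$start, seq_len(K - s + 1))
  }
  expect_warning(out <- enumerate_windows(5, c(3, 9)), "exceed")
  expect_equal(unique(out$size), 3L)
})

test_that("window families cover every window and plot", {
  d <- make_design(1, 2, 5, 17, 3)
  p <- simulation_params(pool_size = 80, depth_mean = 400, seed = 31)
  x <- simulate_communities(d, p)
  fam <- fit_window_family(x, d, sizes = 5:14)
  expect_equal(nrow(fam), 2 * sum(17 - (5:14) + 1))  # 2 plots x 85
  expect_equal(sum(fam$ok), nrow(fam))
  expect_true(all(fam$window_size %in% 5:14))
  cnt <- table(fam$window_size[fam$plot_id == fam$plot_id[1]])
  expect_equal(as.vector(cnt), 17 - (5:14) + 1)
  # a window covering the whole series equals the whole-series fit
  d5 <- make_design(1, 1, 5, 5, 3)
  x5 <- simulate_communities(d5, simulation_params(pool_size = 50,
                                                   depth_mean = 300,
                                                   seed = 9))
  fam5 <- fit_window_family(x5, d5, sizes = 5)
  full <- fit_star(build_accumulation_surface(x5, d5))
  expect_equal(nrow(fam5), 1)
  expect_equal(fam5$z, full$z, tolerance = 1e-10)
  expect_equal(fam5$w, full$w, tolerance = 1e-10)
})

test_that("an exact power-law surface yields identical exponents on any subset", {
  s <- simulate_star_surface(0.14, 0.35, -0.025, 4, noise_sd = 0)
  f_full <- fit_star(s)
  set.seed(2)
  for (i in 1:5) {
    rows <- sample(nrow(s), 30)
    sub <- s[rows, ]
    if (length(unique(sub$area_m2)) < 2 ||
        length(unique(sub$time_months)) < 2) next
    f_sub <- fit_star(sub)
    expect_lt(abs(f_sub$z - f_full$z), 1e-8)
    expect_lt(abs(f_sub$w - f_full$w), 1e-8)
    expect_lt(abs(f_sub$u - f_full$u), 1e-8)
  }
})

test_that("mixed-model contrast recovers an injected treatment shift", {
  fam <- synthetic_family(shift = -0.6, sd = 0.1, seed = 101)
  es <- lmm_effect_size(fam, "w", fixed = "treatment", control = "ctrl",
                        random_nesting = c("window_size", "plot_id"))
  expect_s3_class(es, "effect_size")
  expect_true(es$estimate > -0.7 && es$estimate < -0.5)
  expect_lt(es$p_value, 0.05)
  # identical groups: estimate near zero
  fam0 <- synthetic_family(shift = 0, sd = 0.05, seed = 102)
  es0 <- lmm_effect_size(fam0, "w", fixed = "treatment",
                         control = "ctrl",
                         random_nesting = c("window_size", "plot_id"))
  expect_lt(abs(es0$estimate), 0.05)
  # single treatment level is rejected
  fam1 <- fam[fam$treatment == "ctrl", ]
  expect_error(lmm_effect_size(fam1, "w", fixed = "treatment"),
               "single level")
})

test_that("mixed-model sign recovery is reliable for strong shifts", {
  hits <- vapply(1:100, function(i) {
    sh <- sample(c(-0.5, 0.5), 1)
    fam <- synthetic_family(shift = sh, sd = 0.15, seed = 200 + i)
    es <- lmm_effect_size(fam, "w", fixed = "treatment",
                          control = "ctrl", ar1 = FALSE,
                          random_nesting = c("window_size", "plot_id"))
    sign(es$estimate) == sign(sh)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("ln response ratio and Cohen's d match hand arithmetic", {
  expect_equal(ln_response_ratio(c(2, 2, 2), c(2, 2, 2))$estimate, 0)
  expect_equal(ln_response_ratio(c(2, 2, 2, 2), c(1, 1, 1, 1))$estimate,
               log(2))
  expect_error(ln_response_ratio(c(1, 2), c(0, 0)), "positive")
  # antisymmetry
  a <- c(1.2, 1.5, 1.9); b <- c(0.7, 0.8, 1.1)
  expect_equal(ln_response_ratio(a, b)$estimate,
               -ln_response_ratio(b, a)$estimate)
  d1 <- cohens_d(c(0.5, 1, 1.5), c(-0.5, 0, 0.5))
  expect_equal(d1$estimate, 1 / 0.5)
  expect_equal(cohens_d(a, b)$estimate, -cohens_d(b, a)$estimate)
  expect_equal(cohens_d(a, a)$estimate, 0)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("Spearman screening ranks and adjusts as expected", {
  rates <- data.frame(up = 1:6, down = 6:1)
  het <- data.frame(x = c(2, 4, 5, 7, 8, 11))
  out <- spearman_fdr(rates, het)
  expect_equal(out$rho[out$rate == "up"], 1)
  expect_equal(out$rho[out$rate == "down"], -1)
  # Benjamini-Hochberg step-up by hand
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "BH"),
               c(0.03, 0.04, 0.04))
  rates$flat <- rep(1, 6)
  out2 <- spearman_fdr(rates, het)
  expect_true(out2$degenerate[out2$rate == "flat"])
  expect_true(is.na(out2$rho[out2$rate == "flat"]))
  expect_error(spearman_fdr(rates[1:3, ], het[1:3, , drop = FALSE]),
               "at least 4")
})
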