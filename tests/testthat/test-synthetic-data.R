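test_that("sample count equals the product of the design dimensions", {
  cases <- list(c(2, 2, 21, 17, 5), c(1, 1, 1, 1, 1), c(3, 2, 7, 4, 3))
  for (cs in cases) {
    d <- make_design(cs[1], cs[2], cs[3], cs[4], cs[5])
    expect_equal(nrow(d$samples), prod(cs[1:4]))
    expect_false(anyDuplicated(d$samples$sample_id) > 0)
  }
})

test_that("area levels are nested, strictly growing, and validated", {
  d <- make_design(1, 1, 21, 3, 5)
  sets <- lapply(d$area_levels, `[[`, "points")
  sizes <- vapply(d$area_levels, `[[`, 0, "area_m2")
  for (j in 2:5) {
    expect_true(all(sets[[j - 1]] %in% sets[[j]]))
    expect_gt(length(sets[[j]]), length(sets[[j - 1]]))
  }
  expect_true(all(diff(sizes) > 0))
  expect_error(make_design(1, 1, 3, 2, 5), "invalid design")
  expect_error(make_design(1, 1, 5, 2, 3, area_sizes = c(4, 2, 1)),
               "increasing")
})

test_that("simulated trees are reproducible with labelled tips", {
  t1 <- simulate_tree(100, seed = 7)
  t2 <- simulate_tree(100, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_tree(50, seed = 3)
  expect_setequal(t3$tip.label, paste0("t", 1:50))
  expect_true(all(t3$edge.length > 0))
  expect_error(simulate_tree(1), ">= 2")
  # two-tip tree: PD of both tips is the whole tree
  t4 <- simulate_tree(2, seed = 1)
  expect_equal(faith_pd(t4$tip.label, t4), sum(t4$edge.length))
})

test_that("structureless parameters give identical taxon sets and flat STR", {
  d <- tiny_design(n_points = 3, n_times = 4)
  p <- simulation_params(pool_size = 20, abundance_sigma = 0,
                         spatial_decay = 0, temporal_turnover = 0,
                         temporal_sigma = 0, spatial_sigma = 0,
                         depth_mean = 2000, seed = 5)
  x <- simulate_communities(d, p, keep_composition = TRUE)
  comp <- attr(x, "composition")
  expect_true(all(abs(sweep(comp, 2, comp[1, ]) ) < 1e-12))
  sets <- apply(x$counts > 0, 1, function(r) paste(which(r),
                                                   collapse = ","))
  expect_length(unique(sets), 1L)
  surf <- build_accumulation_surface(x, d)
  expect_lt(abs(fit_power_law(surf, "time", "richness")$slope), 0.01)
})

test_that("full homogenization collapses within-plot spatial variation", {
  d <- tiny_design(n_points = 4, n_times = 3)
  p <- simulation_params(pool_size = 30, homogenization = 1,
                         depth_mean = 1000, seed = 9)
  x <- simulate_communities(d, p, keep_composition = TRUE)
  comp <- attr(x, "composition")
  meta <- x$samples
  for (tp in unique(meta$time)) {
    rows <- which(meta$time == tp)
    expect_true(all(abs(sweep(comp[rows, , drop = FALSE], 2,
                              comp[rows[1], ])) < 1e-12))
  }
  # pooling more identical points adds no expected richness: flat SAR
  surf <- build_accumulation_surface(x, d)
  expect_lt(abs(fit_power_law(surf, "area", "richness")$slope), 0.02)
})

test_that("per-sample depths match the requested mean on average", {
  d <- tiny_design(n_points = 3, n_times = 3)
  p <- simulation_params(pool_size = 40, depth_mean = 500, seed = 2)
  x <- simulate_communities(d, p)
  expect_lt(abs(mean(rowSums(x$counts)) - 500) / 500, 0.1)
  expect_true(all(x$counts == floor(x$counts)))
  expect_true(all(x$counts >= 0))
})

test_that("generators are byte-reproducible under a fixed seed", {
  d <- tiny_design(n_points = 3, n_times = 2)
  p <- simulation_params(pool_size = 15, seed = 42)
  expect_identical(simulate_communities(d, p)$counts,
                   simulate_communities(d, p)$counts)
  expect_identical(simulate_soil_table(d, seed = 3),
                   simulate_soil_table(d, seed = 3))
  expect_identical(
    assign_rrn_traits(c("a", "b"), c("g", "g"), c(g = 2), seed = 1),
    assign_rrn_traits(c("a", "b"), c("g", "g"), c(g = 2), seed = 1))
})

test_that("fitted temporal exponent rises with the turnover rate", {
  d <- tiny_design(n_points = 5, n_times = 8)
  meds <- vapply(c(0.05, 0.1, 0.2), function(tau) {
    ws <- vapply(1:20, function(i) {
      p <- simulation_params(pool_size = 80, depth_mean = 400,
                             temporal_turnover = tau,
                             seed = round(tau * 1000) + i)
      fit_star(build_accumulation_surface(simulate_communities(d, p),
                                          d))$w
    }, 0)
    median(ws)
  }, 0)
  expect_true(all(diff(meds) > 0))
})

test_that("direct surface simulation realizes the generative power law", {
  s <- simulate_star_surface(0.139, 0.366, -0.03, 5, noise_sd = 0,
                             area_sizes = 1, time_lengths = 1)
  expect_equal(s$richness, exp(5))
  # u = 0 makes the log surface separable in A and T
  s2 <- simulate_star_surface(0.2, 0.3, 0, 1, 0,
                              area_sizes = c(1, 4, 16),
                              time_lengths = 1:4)
  m <- matrix(log(s2$richness[order(s2$area_level, s2$time_months)]),
              nrow = 4)
  diffs <- apply(m, 1, diff)   # across areas, per time length
  expect_true(all(abs(sweep(diffs, 1, diffs[, 1])) < 1e-12))
  expect_error(simulate_star_surface(0.1, 0.2, 0, 1, 0,
                                     area_sizes = c(-1, 2)),
               "positive")
})

test_that("soil variance factor shrinks treated-plot dispersion", {
  d <- make_design(1, 2, 6, 5, 3)
  ds <- vapply(1:50, function(i) {
    soil <- simulate_soil_table(d, treatment_variance_factor = 0.5,
                                seed = i)
    hp <- heterogeneity_profile(soil, "P")
    sp <- hp[hp$mode == "spatial", ]
    cohens_d(sp$cv[sp$treatment == "cropping"],
             sp$cv[sp$treatment == "fallow"])$estimate
  }, 0)
  expect_lt(median(ds), 0)
  # factor 1: no systematic difference
  ds1 <- vapply(1:50, function(i) {
    soil <- simulate_soil_table(d, treatment_variance_factor = 1,
                                seed = 500 + i)
    hp <- heterogeneity_profile(soil, "P")
    sp <- hp[hp$mode == "spatial", ]
    mean(sp$cv[sp$treatment == "cropping"]) -
      mean(sp$cv[sp$treatment == "fallow"])
  }, 0)
  expect_lt(abs(median(ds1)), 0.05)
  expect_error(simulate_soil_table(d, property_sds = c(pH = -1)),
               "length|positive")
})

test_that("trait assignment respects group means and bounds", {
  tt <- assign_rrn_traits(paste0("t", 1:4), rep("g1", 4), c(g1 = 1),
                          jitter_sd = 0, seed = 1)
  expect_true(all(tt$copy_number == 1))
  tt2 <- assign_rrn_traits(paste0("t", 1:200),
                           rep(c("lo", "hi"), each = 100),
                           c(lo = 2, hi = 10), seed = 2)
  m <- tapply(tt2$copy_number, tt2$group, mean)
  expect_lt(m[["lo"]], m[["hi"]])
  expect_true(all(tt2$copy_number >= 1))
  expect_error(assign_rrn_traits("a", "nope", c(g = 2)), "unknown group")
})
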