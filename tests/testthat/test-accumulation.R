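test_that("Faith's PD matches hand-computed path sums on the toy tree", {
  tr <- toy_tree()
  expect_equal(faith_pd(c("A", "B", "C"), tr), 10)
  expect_equal(faith_pd("A", tr), 4)          # edges 1 + 3 to the root
  expect_equal(faith_pd(c("A", "B"), tr), 6)  # 1 + 2 + 3
  expect_equal(faith_pd(character(), tr), 0)
  expect_error(faith_pd("Z", tr), "not found")
  # rootless convention: spanning subtree below the MRCA only
  expect_equal(faith_pd(c("A", "B"), tr, include_root = FALSE), 3)
  expect_equal(faith_pd("A", tr, include_root = FALSE), 0)
})

test_that("PD agrees with picante and is monotone under inclusion", {
  skip_if_not_installed("picante")
  tr <- simulate_tree(40, seed = 11)
  set.seed(4)
  for (n in c(1, 5, 20, 40)) {
    taxa <- sample(tr$tip.label, n)
    cm <- matrix(0, 1, 40, dimnames = list("s", tr$tip.label))
    cm[1, taxa] <- 1
    expect_equal(faith_pd(taxa, tr),
                 picante::pd(cm, tr, include.root = TRUE)$PD)
  }
  sub <- sample(tr$tip.label, 10)
  expect_lte(faith_pd(sub[1:4], tr), faith_pd(sub, tr))
  expect_equal(faith_pd(tr$tip.label, tr), sum(tr$edge.length))
})

test_that("single-cell surface counts the observed taxa", {
  d <- tiny_design(n_points = 1, n_times = 1)
  x <- plot_community(d, matrix(c(0, 3, 1), 1, 3,
                                dimnames = list(NULL, c("a", "b", "c"))))
  surf <- build_accumulation_surface(x, d)
  expect_equal(nrow(surf), 1L)
  expect_equal(surf$richness, 2)
  expect_equal(surf$total_sequences, 4)
})

test_that("nested surface equals the exhaustive union oracle", {
  set.seed(77)
  for (rep in 1:200) {
    np <- sample(2:3, 1); nt <- sample(2:3, 1)
    d <- tiny_design(n_points = np, n_times = nt)
    x <- random_tiny_community(d, n_taxa = sample(3:6, 1))
    surf <- build_accumulation_surface(x, d)
    oracle <- oracle_surface(x$counts, x$samples, d)
    got <- matrix(surf$richness, nrow = nt)   # times x levels
    expect_identical(unname(t(got)), oracle)
  }
})

test_that("richness and PD are monotone along both nested axes", {
  d <- tiny_design(n_points = 4, n_times = 5)
  tr <- simulate_tree(30, seed = 3)
  p <- simulation_params(pool_size = 30, depth_mean = 150, seed = 8)
  x <- simulate_communities(d, p)
  surf <- build_accumulation_surface(x, d, tr)
  rich <- matrix(surf$richness, nrow = 5)
  pdm <- matrix(surf$pd, nrow = 5)
  expect_true(all(apply(rich, 2, diff) >= 0))  # over time
  expect_true(all(apply(rich, 1, diff) >= 0))  # over area
  expect_true(all(apply(pdm, 2, diff) >= 0))
  expect_true(all(apply(pdm, 1, diff) >= 0))
})

test_that("missing sample cells error by default and skip on request", {
  d <- tiny_design(n_points = 2, n_times = 2)
  meta <- d$samples[-1, ]
  counts <- matrix(1, 3, 2, dimnames = list(meta$sample_id, c("a", "b")))
  x <- community_matrix(counts, meta)
  expect_error(build_accumulation_surface(x, d), "missing samples")
  expect_warning(build_accumulation_surface(x, d, on_missing = "skip"),
                 "skipping")
  expect_error(build_accumulation_surface(x, d,
                                          temporal_method = "island"),
               "island_curve")
})

test_that("complete-nested curve averages windows and meets the nested terminus", {
  # single point, taxa sets {a}, {b}, {a} over three months
  d <- tiny_design(n_points = 1, n_times = 3)
  counts <- rbind(c(1, 0), c(0, 1), c(1, 0))
  colnames(counts) <- c("a", "b")
  x <- plot_community(d, counts)
  cn <- complete_nested_curve(x, d)
  expect_equal(cn$richness[cn$time_months == 1], mean(c(1, 1, 1)))
  expect_equal(cn$richness[cn$time_months == 2], 2)  # ({a,b}, {b,a})
  expect_equal(cn$n_windows[cn$time_months == 2], 2)
  nested <- build_accumulation_surface(x, d)
  expect_equal(cn$richness[cn$time_months == 3],
               nested$richness[nested$time_months == 3])
  expect_error(complete_nested_curve(
    x, tiny_design(n_points = 1, n_times = 1)), "at least 2")
})

test_that("temporal islands report per-survey totals", {
  tr <- toy_tree()
  sv <- list(
    list(duration = 5, counts = matrix(c(1, 0, 2), 1, 3,
                                       dimnames = list(NULL,
                                                       c("A", "B", "C")))),
    list(duration = 9, counts = matrix(c(1, 0, 2), 1, 3,
                                       dimnames = list(NULL,
                                                       c("A", "B", "C")))),
    list(duration = 2, counts = matrix(c(1, 1, 1), 1, 3,
                                       dimnames = list(NULL,
                                                       c("A", "B", "C")))))
  ic <- island_curve(sv, tree = tr)
  expect_equal(ic$richness, c(2, 2, 3))
  expect_equal(ic$duration, c(5, 9, 2))
  expect_equal(ic$pd[3], 10)
  expect_error(island_curve(sv[1]), "at least 2")
  expect_error(island_curve(list(sv[[1]],
                                 list(duration = 1,
                                      counts = matrix(0, 1, 1,
                                                      dimnames = list(
                                                        NULL, "A"))))),
               "empty survey")
})

test_that("rarefied richness matches the hypergeometric closed form", {
  cnt <- c(a = 5, b = 3, c = 2)
  exp_rich <- 3 - (choose(5, 5) + choose(7, 5) + choose(8, 5)) /
    choose(10, 5)
  out <- standardize_depth(cnt, 5, n_reps = 1000, seed = 1)
  expect_equal(out$richness_expected, exp_rich, tolerance = 1e-10)
  # Monte-Carlo mean within 3 standard errors of the closed form
  se <- 1 / sqrt(1000)  # richness sd per draw is < 1 here
  expect_lt(abs(out$richness_rarefied - exp_rich), 3 * se * 1)
  expect_lte(out$richness_rarefied, out$richness_observed)
  # subsampling at a scale's own depth changes nothing
  out2 <- standardize_depth(cnt, 10, n_reps = 5, seed = 2)
  expect_equal(out2$richness_rarefied, 3)
  expect_error(standardize_depth(cnt, 11), "exceeds")
})
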