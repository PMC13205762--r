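# Block-permutation significance tests and moving-window model families.

# consecutive blocks of `size`; a trailing remainder of 1-2 scales is kept
# as its own intact block.
block_partition <- function(n, size) {
  if (size < 1L) stopf("block_size must be >= 1")
  starts <- seq(1L, n, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

# permutation p-value, add-one estimator: p = (1 + m) / (1 + R)
perm_pvalue <- function(observed, null, tail = c("upper", "two_sided")) {
  tail <- match.arg(tail)
  m <- switch(tail,
              upper = sum(null >= observed),
              two_sided = sum(abs(null) >= abs(observed)))
  (1 + m) / (1 + length(null))
}

new_permutation_result <- function(statistic, observed, null, p_value,
                                   block_size, n_discarded = 0L,
                                   seed = NULL) {
  structure(list(statistic = statistic, observed = observed, null = null,
                 p_value = p_value, n_rand = length(null),
                 n_discarded = n_discarded, block_size = block_size,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test of %s: observed = %.4g, p = %.4g (R = %d%s, block = %d)\n",
    x$statistic, x$observed, x$p_value, x$n_rand,
    if (x$n_discarded > 0) sprintf(", %d degenerate discarded",
                                   x$n_discarded) else "",
    x$block_size))
  invisible(x)
}

#' Restricted block-permutation test of an interaction scaling model
#'
#' Assesses the significance of the fitted STAR/PTAR model and of its
#' exponents while respecting the serial dependence that the nested
#' construction induces. Temporally adjacent time points and spatially
#' neighbouring nested area increments are grouped into blocks of
#' \code{block_size} consecutive scales; per permutation the temporal
#' block order and the spatial block order are shuffled independently
#' (blocks moved as intact units), the accumulation surface is rebuilt
#' from the permuted construction order, and the model refit. Model
#' significance is the upper tail of the null \eqn{R^2} distribution;
#' exponent significance is two-sided on the absolute refitted exponent.
#' Degenerate null fits (a zero-diversity cell) are discarded and
#' counted.
#'
#' @param x a \code{\link{community_matrix}} for a single plot.
#' @param design the \code{sampling_design}.
#' @param response \code{"richness"} or \code{"pd"} (\code{"pd"} requires
#'   \code{tree}).
#' @param tree rooted tree (needed for \code{response = "pd"}).
#' @param exponent_targets which exponents to test (subset of
#'   \code{c("z", "w", "u")}).
#' @param n_rand number of random permutations (default 1000).
#' @param block_size scales per block (default 3).
#' @param seed integer seed.
#' @param on_missing passed to the surface builder.
#' @return list of \code{permutation_result} objects named
#'   \code{r_squared} plus each tested exponent, with the observed
#'   \code{star_fit} attached as attribute \code{"fit"}.
#' @export
block_permutation_test <- function(x, design,
                                   response = c("richness", "pd"),
                                   tree = NULL,
                                   exponent_targets = c("z", "w", "u"),
                                   n_rand = 1000L, block_size = 3L,
                                   seed = NULL,
                                   on_missing = c("error", "skip")) {
  response <- match.arg(response)
  exponent_targets <- match.arg(exponent_targets, several.ok = TRUE)
  if (response == "pd" && is.null(tree))
    stopf("response 'pd' requires a tree")
  ind <- plot_indicators(x, design, match.arg(on_missing))
  J <- dim(ind$M)[1L]; K <- dim(ind$M)[2L]
  tb <- block_partition(K, block_size)
  lb <- block_partition(J, block_size)
  if (length(tb) < 2L || length(lb) < 2L)
    stopf("cannot form 2 blocks of size %d on each axis (%d levels, %d times)",
          block_size, J, K)

  if (response == "pd") {
    M <- edge_indicators(ind$M, ind$taxa, tree)
    wts <- tree$edge.length
  } else {
    M <- ind$M; wts <- NULL
  }
  la <- rep(log(ind$areas), each = K)
  lt <- rep(log(seq_len(K)), times = J)
  X <- cbind(1, la, lt, la * lt)
  qx <- qr(X)

  fit_grid <- function(S) {
    if (any(S <= 0)) return(NULL)
    y <- log(as.vector(t(S)))
    beta <- qr.coef(qx, y)
    res <- qr.resid(qx, y)
    sst <- sum((y - mean(y))^2)
    c(b = unname(beta[1L]), z = unname(beta[2L]), w = unname(beta[3L]),
      u = unname(beta[4L]),
      r_squared = if (sst > 0) 1 - sum(res^2) / sst else 0)
  }

  obs <- fit_grid(surface_sum(M, wts))
  if (is.null(obs)) stopf("observed surface has an empty diversity cell")

  with_seed(seed, {
    nulls <- matrix(NA_real_, n_rand, 5L,
                    dimnames = list(NULL,
                                    c("b", "z", "w", "u", "r_squared")))
    discarded <- 0L
    for (r in seq_len(n_rand)) {
      lo <- unlist(lb[sample.int(length(lb))], use.names = FALSE)
      to <- unlist(tb[sample.int(length(tb))], use.names = FALSE)
      est <- fit_grid(surface_sum(M, wts, level_order = lo,
                                  time_order = to))
      if (is.null(est)) { discarded <- discarded + 1L; next }
      nulls[r, ] <- est
    }
    nulls <- nulls[!is.na(nulls[, "r_squared"]), , drop = FALSE]

    out <- list(r_squared = new_permutation_result(
      "r_squared", obs[["r_squared"]], nulls[, "r_squared"],
      perm_pvalue(obs[["r_squared"]], nulls[, "r_squared"], "upper"),
      block_size, discarded, seed))
    for (e in exponent_targets)
      out[[e]] <- new_permutation_result(
        e, obs[[e]], nulls[, e],
        perm_pvalue(obs[[e]], nulls[, e], "two_sided"),
        block_size, discarded, seed)
    fit <- structure(list(response = response, z = obs[["z"]],
                          w = obs[["w"]], u = obs[["u"]], b = obs[["b"]],
                          r_squared = obs[["r_squared"]], n = J * K,
                          area_unit = "m2", time_unit = "month"),
                     class = "star_fit")
    attr(out, "fit") <- fit
    out
  })
}

#' Permutation contrast of STAR versus PTAR exponents
#'
#' Tests whether a taxonomic (richness) exponent differs from its
#' phylogenetic (PD) counterpart on the same accumulation surface. The
#' null is built by swapping the richness/PD response labels block-wise
#' along the time axis (blocks of \code{block_size} consecutive time
#' scales flipped as units with probability 1/2), refitting both models
#' and recording the exponent difference; the p-value is two-sided.
#'
#' @param surface an \code{accumulation_surface} carrying both
#'   \code{richness} and \code{pd} columns.
#' @param exponent one of \code{"z"}, \code{"w"}, \code{"u"}.
#' @param n_rand number of permutations (>= 1).
#' @param block_size time scales per swap block (default 3).
#' @param seed integer seed.
#' @return a \code{permutation_result} for the difference
#'   (richness minus PD exponent).
#' @export
star_ptar_difference_test <- function(surface,
                                      exponent = c("z", "w", "u"),
                                      n_rand = 1000L, block_size = 3L,
                                      seed = NULL) {
  exponent <- match.arg(exponent)
  if (!"pd" %in% names(surface) || all(is.na(surface$pd)))
    stopf("surface carries no phylogenetic diversity response")
  if (n_rand < 1L) stopf("n_rand must be >= 1")
  ok <- stats::complete.cases(surface$area_m2, surface$time_months,
                              surface$richness, surface$pd)
  sf <- surface[ok, ]
  la <- log(sf$area_m2); lt <- log(sf$time_months)
  X <- cbind(1, la, lt, la * lt)
  qx <- qr(X)
  coef_idx <- c(z = 2L, w = 3L, u = 4L)[[exponent]]
  exp_of <- function(y) unname(qr.coef(qx, log(y))[coef_idx])

  d_obs <- exp_of(sf$richness) - exp_of(sf$pd)
  tvals <- sort(unique(sf$time_months))
  blocks <- block_partition(length(tvals), block_size)
  with_seed(seed, {
    d_null <- numeric(n_rand)
    for (r in seq_len(n_rand)) {
      ys <- sf$richness; yp <- sf$pd
      for (blk in blocks) {
        if (stats::runif(1) < 0.5) {
          rows <- sf$time_months %in% tvals[blk]
          tmp <- ys[rows]; ys[rows] <- yp[rows]; yp[rows] <- tmp
        }
      }
      d_null[r] <- exp_of(ys) - exp_of(yp)
    }
    new_permutation_result(
      sprintf("STAR-PTAR %s difference", exponent), d_obs, d_null,
      perm_pvalue(d_obs, d_null, "two_sided"), block_size, 0L, seed)
  })
}

#' Enumerate moving time windows
#'
#' All windows of the requested sizes over a series of \code{n_times}
#' time points: a window of size \eqn{s} can start at positions
#' \eqn{1 \dots n - s + 1}, so a 17-month series yields 13 windows of
#' size 5, 12 of size 6, and so on.
#'
#' @param n_times series length.
#' @param sizes integer vector of window sizes (each >= 2); sizes larger
#'   than \code{n_times} are dropped with a warning.
#' @param step start-position step (default 1).
#' @return data frame with columns \code{size} and \code{start}.
#' @export
enumerate_windows <- function(n_times, sizes, step = 1L) {
  sizes <- as.integer(sizes)
  if (any(sizes < 2L)) stopf("window sizes must be >= 2")
  too_big <- sizes > n_times
  if (any(too_big)) {
    warning(sprintf("window size(s) %s exceed the series length %d; dropped",
                    paste(sizes[too_big], collapse = ", "), n_times),
            call. = FALSE)
    sizes <- sizes[!too_big]
  }
  if (length(sizes) == 0L)
    return(data.frame(size = integer(), start = integer()))
  out <- do.call(rbind, lapply(sizes, function(s) {
    data.frame(size = s, start = seq(1L, n_times - s + 1L, by = step))
  }))
  rownames(out) <- NULL
  out
}

#' Fit interaction models over all moving windows
#'
#' Rebuilds the nested accumulation surface within every time window of
#' the requested sizes (re-anchored at the window start) and fits the
#' interaction model per window and plot, for richness and -- when a tree
#' is supplied -- phylogenetic diversity. The resulting family of
#' exponents feeds \code{\link{lmm_effect_size}}.
#'
#' @param x a \code{\link{community_matrix}}; may contain several plots.
#' @param design the \code{sampling_design}.
#' @param tree optional rooted tree; adds the PD response.
#' @param sizes window sizes in months (default 5 to 14).
#' @param step window start step (default 1).
#' @param on_missing passed to the surface builder.
#' @return data frame of class \code{"window_family"}: one row per
#'   (plot, response, window) with columns \code{site},
#'   \code{treatment}, \code{plot_id}, \code{response},
#'   \code{window_size}, \code{ystart}, \code{z}, \code{w}, \code{u},
#'   \code{b}, \code{r_squared}, \code{ok}, \code{reason}.
#' @export
fit_window_family <- function(x, design, tree = NULL, sizes = 5:14,
                              step = 1L, on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  K <- length(design$time_points)
  if (K < max(sizes))
    warning("series shorter than the largest window size; large windows dropped",
            call. = FALSE)
  wins <- enumerate_windows(K, sizes, step)
  plots <- plot_table(x)
  rows <- list()
  for (i in seq_len(nrow(plots))) {
    plt <- subset_plot(x, plots$site[i], plots$treatment[i])
    ind <- plot_indicators(plt, design, on_missing)
    responses <- list(richness = list(M = ind$M, w = NULL))
    if (!is.null(tree))
      responses$pd <- list(M = edge_indicators(ind$M, ind$taxa, tree),
                           w = tree$edge.length)
    la_full <- log(ind$areas)
    qx_cache <- list()
    for (resp in names(responses)) {
      Mr <- responses[[resp]]$M; wr <- responses[[resp]]$w
      for (r in seq_len(nrow(wins))) {
        s <- wins$size[r]; y0 <- wins$start[r]
        key <- as.character(s)
        if (is.null(qx_cache[[key]])) {
          la <- rep(la_full, each = s)
          lt <- rep(log(seq_len(s)), times = length(la_full))
          qx_cache[[key]] <- qr(cbind(1, la, lt, la * lt))
        }
        S <- surface_sum(Mr[, y0:(y0 + s - 1L), , drop = FALSE], wr)
        row <- data.frame(site = plots$site[i],
                          treatment = plots$treatment[i],
                          plot_id = paste(plots$site[i],
                                          plots$treatment[i], sep = "."),
                          response = resp, window_size = s, ystart = y0,
                          z = NA_real_, w = NA_real_, u = NA_real_,
                          b = NA_real_, r_squared = NA_real_, ok = FALSE,
                          reason = NA_character_,
                          stringsAsFactors = FALSE)
        if (any(S <= 0)) {
          row$reason <- "empty diversity cell"
        } else {
          qx <- qx_cache[[key]]
          y <- log(as.vector(t(S)))
          beta <- qr.coef(qx, y)
          if (anyNA(beta)) {
            row$reason <- "rank-deficient window"
          } else {
            res <- qr.resid(qx, y)
            sst <- sum((y - mean(y))^2)
            row$b <- unname(beta[1L]); row$z <- unname(beta[2L])
            row$w <- unname(beta[3L]); row$u <- unname(beta[4L])
            row$r_squared <- if (sst > 0) 1 - sum(res^2) / sst else 0
            row$ok <- TRUE
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("window_family", "data.frame")
  out
}
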