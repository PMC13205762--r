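#' Parameters of the synthetic community generator
#'
#' Collects the knobs of the generative model used by
#' \code{\link{simulate_communities}}: a log-normal regional species
#' abundance pool, a Gaussian-process spatial field whose correlation
#' decays exponentially with distance between points, Markov replacement
#' of pool members over time, and multinomial read sampling.
#'
#' \code{homogenization} emulates the loss of environmental heterogeneity
#' under intensive monoculture: within the designated treatment it shrinks
#' both the between-point spatial field and the temporal variability
#' (taxon replacement and month-to-month abundance fluctuation) by the
#' factor \code{1 - homogenization}. At \code{homogenization = 1} all
#' points of a treated plot share one composition at each time point.
#'
#' @param pool_size number of taxa in the regional pool (>= 1).
#' @param abundance_sigma log-normal shape of pool abundances (sd of log
#'   abundance); 0 gives an even pool.
#' @param spatial_decay per-metre decay rate of between-point similarity
#'   (>= 0); 0 removes all spatial structure.
#' @param temporal_turnover per-month probability that an active taxon is
#'   replaced by one from the inactive reservoir, in [0, 1].
#' @param homogenization in [0, 1]; fraction by which spatial and temporal
#'   compositional variability is shrunk in the treated treatment.
#' @param depth_mean expected sequencing reads per sample (>= 1).
#' @param spatial_sigma sd of the taxon-wise spatial log-abundance field.
#' @param temporal_sigma sd of plot-level month-to-month log-abundance
#'   fluctuations.
#' @param active_fraction fraction of the pool active (present in the
#'   local community) at any one time, in (0, 1].
#' @param treated treatment label to which \code{homogenization} applies;
#'   default: the last treatment of the design (the "cropping" arm), or
#'   the only treatment if there is just one.
#' @param seed integer seed; the generator is byte-reproducible given the
#'   seed.
#'
#' @return an object of class \code{"simulation_params"}.
#' @export
simulation_params <- function(pool_size = 600L, abundance_sigma = 1.5,
                              spatial_decay = 0.15,
                              temporal_turnover = 0.08,
                              homogenization = 0, depth_mean = 2000,
                              spatial_sigma = 1, temporal_sigma = 0.4,
                              active_fraction = 0.6, treated = NULL,
                              seed = NULL) {
  pool_size <- as.integer(pool_size)
  if (pool_size < 1L) stopf("pool_size must be >= 1")
  if (depth_mean < 1) stopf("depth_mean must be >= 1")
  for (p in c(temporal_turnover, homogenization))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  if (spatial_decay < 0) stopf("spatial_decay must be >= 0")
  if (abundance_sigma < 0 || spatial_sigma < 0 || temporal_sigma < 0)
    stopf("sigma parameters must be >= 0")
  if (active_fraction <= 0 || active_fraction > 1)
    stopf("active_fraction must lie in (0, 1]")
  structure(list(pool_size = pool_size, abundance_sigma = abundance_sigma,
                 spatial_decay = spatial_decay,
                 temporal_turnover = temporal_turnover,
                 homogenization = homogenization, depth_mean = depth_mean,
                 spatial_sigma = spatial_sigma,
                 temporal_sigma = temporal_sigma,
                 active_fraction = active_fraction, treated = treated,
                 seed = seed),
            class = "simulation_params")
}

#' Simulate a random rooted phylogeny
#'
#' Random topology (via \code{\link[ape]{rtree}}) with exponential branch
#' lengths; tips are labelled \code{t1..tn}. The topology model is
#' immaterial downstream -- the tree only supplies branch lengths for
#' Faith's phylogenetic diversity.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; the same seed yields a byte-identical Newick
#'   string.
#' @param rate rate of the exponential branch-length distribution.
#' @return a rooted \code{\link[ape]{phylo}} object with positive branch
#'   lengths.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, rate = 1) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2L) stopf("n_taxa must be >= 2")
  with_seed(seed, {
    ape::rtree(n_taxa, rooted = TRUE,
               br = function(n) stats::rexp(n, rate = rate) + 1e-6)
  })
}

#' Simulate nested spatiotemporal community count data
#'
#' Draws taxon counts for every sample of a \code{\link{make_design}}
#' design from a mechanistic model that exhibits species-area and
#' species-time accumulation: a shared log-normal pool, an exponentially
#' distance-correlated spatial field per plot, Markov taxon replacement
#' plus month-level abundance fluctuation over time, and multinomial read
#' sampling at Poisson-distributed depth.
#'
#' With \code{spatial_decay = 0} and \code{temporal_turnover = 0} (and
#' \code{temporal_sigma = 0}) the expected composition is identical across
#' points and months. Treated-plot heterogeneity shrinks with
#' \code{homogenization} (see \code{\link{simulation_params}}).
#'
#' @param design a \code{sampling_design}.
#' @param params a \code{\link{simulation_params}} object.
#' @param keep_composition if \code{TRUE}, attach the per-sample expected
#'   relative-abundance matrix as attribute \code{"composition"}.
#' @return a \code{\link{community_matrix}} whose taxon ids \code{t1..tn}
#'   match the tips of \code{\link{simulate_tree}(params$pool_size)}.
#' @export
simulate_communities <- function(design, params = simulation_params(),
                                 keep_composition = FALSE) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(params, "simulation_params"))
  n_taxa <- params$pool_size
  taxa <- paste0("t", seq_len(n_taxa))
  pts <- design$points
  n_pts <- nrow(pts)
  n_times <- length(design$time_points)
  treated <- params$treated %||%
    design$treatments[length(design$treatments)]

  with_seed(params$seed, {
    base <- params$abundance_sigma * stats::rnorm(n_taxa)
    d_mat <- as.matrix(stats::dist(pts[, c("x", "y")]))

    out_counts <- list(); out_meta <- list(); out_comp <- list()
    for (site in design$sites) {
      for (trt in design$treatments) {
        damp <- if (trt == treated) 1 - params$homogenization else 1
        # spatial field: rows = taxa, cols = points, cor exp(-decay * d)
        if (params$spatial_decay > 0 && params$spatial_sigma > 0 &&
            n_pts > 1L) {
          corr <- exp(-params$spatial_decay * d_mat)
          diag(corr) <- diag(corr) + 1e-10
          g <- matrix(stats::rnorm(n_taxa * n_pts), n_taxa, n_pts) %*%
            chol(corr) * params$spatial_sigma
        } else {
          g <- matrix(stats::rnorm(n_taxa) * params$spatial_sigma,
                      n_taxa, n_pts)
        }
        g <- g * damp

        n_active <- max(1L, round(params$active_fraction * n_taxa))
        active <- seq_len(n_taxa) %in% sample.int(n_taxa, n_active)
        turnover <- params$temporal_turnover * damp

        for (tp in design$time_points) {
          if (tp > 1L && turnover > 0 && n_active < n_taxa) {
            leave <- which(active)[stats::runif(n_active) < turnover]
            if (length(leave)) {
              pool_in <- which(!active)
              join <- pool_in[sample.int(length(pool_in),
                                         min(length(leave),
                                             length(pool_in)))]
              active[leave[seq_along(join)]] <- FALSE
              active[join] <- TRUE
            }
          }
          e_t <- stats::rnorm(n_taxa) * params$temporal_sigma * damp
          lam <- exp(base + e_t + g)       # taxa x points
          lam[!active, ] <- 0
          comp <- sweep(lam, 2L, colSums(lam), "/")
          depth <- stats::rpois(n_pts, params$depth_mean)
          cnt <- vapply(seq_len(n_pts), function(p)
            stats::rmultinom(1L, depth[p], comp[, p])[, 1L],
            numeric(n_taxa))
          ids <- sprintf("%s.%s.%s.t%02d", site, trt, pts$point, tp)
          m <- t(cnt); rownames(m) <- ids; colnames(m) <- taxa
          out_counts[[length(out_counts) + 1L]] <- m
          out_meta[[length(out_meta) + 1L]] <- data.frame(
            sample_id = ids, site = site, treatment = trt,
            point = pts$point, time = tp, stringsAsFactors = FALSE)
          if (keep_composition) {
            cm <- t(comp); rownames(cm) <- ids; colnames(cm) <- taxa
            out_comp[[length(out_comp) + 1L]] <- cm
          }
        }
      }
    }
    counts <- do.call(rbind, out_counts)
    meta <- do.call(rbind, out_meta)
    meta <- meta[match(design$samples$sample_id, meta$sample_id), ]
    counts <- counts[design$samples$sample_id, , drop = FALSE]
    x <- community_matrix(counts, meta)
    if (keep_composition)
      attr(x, "composition") <- do.call(rbind,
        out_comp)[design$samples$sample_id, , drop = FALSE]
    x
  })
}

#' Simulate an accumulation surface directly from the interaction model
#'
#' Generates \eqn{\ln S = z \ln A + w \ln T + u \ln A \ln T + b +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}, over the grid of the
#' supplied area sizes and time lengths, reporting \eqn{S} on the natural
#' scale. Useful as an exact fixture: with \code{noise_sd = 0},
#' \code{\link{fit_star}} recovers the injected exponents to numerical
#' precision.
#'
#' @param z,w,u,b spatial exponent, temporal exponent, interaction term,
#'   intercept.
#' @param noise_sd Gaussian noise sd on the log scale (>= 0).
#' @param area_sizes,time_lengths positive grid axes (m^2, months).
#' @param seed integer seed for the noise.
#' @param pd_coef optional list with elements \code{z, w, u, b}: when
#'   given, a \code{pd} response column is generated from those
#'   coefficients (same noise sd) alongside richness.
#' @return an \code{accumulation_surface} data frame with columns
#'   \code{area_level}, \code{area_m2}, \code{time_months},
#'   \code{richness} (and \code{pd} if requested).
#' @export
simulate_star_surface <- function(z, w, u, b, noise_sd = 0,
                                  area_sizes = 4 ^ (0:4),
                                  time_lengths = 1:17, seed = NULL,
                                  pd_coef = NULL) {
  if (any(area_sizes <= 0) || any(time_lengths <= 0))
    stopf("area sizes and time lengths must be positive")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  grid <- expand.grid(time_months = time_lengths, area_m2 = area_sizes,
                      KEEP.OUT.ATTRS = FALSE)
  la <- log(grid$area_m2); lt <- log(grid$time_months)
  with_seed(seed, {
    ln_s <- z * la + w * lt + u * la * lt + b +
      stats::rnorm(nrow(grid), sd = noise_sd)
    out <- data.frame(
      area_level = match(grid$area_m2, sort(unique(area_sizes))),
      area_m2 = grid$area_m2, time_months = grid$time_months,
      richness = exp(ln_s))
    if (!is.null(pd_coef)) {
      ln_pd <- pd_coef$z * la + pd_coef$w * lt + pd_coef$u * la * lt +
        pd_coef$b + stats::rnorm(nrow(grid), sd = noise_sd)
      out$pd <- exp(ln_pd)
    }
    as_accumulation_surface(out, temporal_method = "nested")
  })
}

#' Simulate a soil-property table with treatment-dependent heterogeneity
#'
#' Each property varies around a site-specific mean with point-level
#' (spatial) and month-level (temporal) Gaussian deviations plus residual
#' noise. For the designated treatment the spatial and temporal deviations
#' are multiplied by \code{treatment_variance_factor}, so a factor below 1
#' reduces that treatment's spatial and temporal coefficients of
#' variation, emulating homogenization of the soil environment.
#'
#' @param design a \code{sampling_design}.
#' @param property_means named numeric vector of property means (units as
#'   measured); defaults to typical marginal-soil values for pH, moisture,
#'   total carbon, total nitrogen, available P, nitrate and ammonium.
#' @param property_sds named numeric vector of positive deviation sds, one
#'   per property; defaults to 10\% of the mean.
#' @param treatment_variance_factor positive multiplier of spatial and
#'   temporal deviations in the treated plots.
#' @param treated treatment label receiving the factor (default: last
#'   treatment).
#' @param seed integer seed.
#' @return data frame with columns \code{sample_id}, \code{site},
#'   \code{treatment}, \code{point}, \code{time}, and one column per
#'   property.
#' @export
simulate_soil_table <- function(design,
                                property_means = c(pH = 6.5,
                                                   moisture = 20,
                                                   TC = 1.2, TN = 0.10,
                                                   P = 10, NO3 = 5,
                                                   NH4 = 4),
                                property_sds = NULL,
                                treatment_variance_factor = 1,
                                treated = NULL, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  if (treatment_variance_factor <= 0)
    stopf("treatment_variance_factor must be > 0")
  if (is.null(property_sds)) property_sds <- 0.1 * abs(property_means)
  if (any(property_sds <= 0)) stopf("property sds must be positive")
  stopifnot(length(property_sds) == length(property_means))
  treated <- treated %||% design$treatments[length(design$treatments)]

  smp <- design$samples
  out <- smp
  n_pts <- nrow(design$points); n_times <- length(design$time_points)
  with_seed(seed, {
    for (k in seq_along(property_means)) {
      mu <- property_means[k]; sdev <- property_sds[k]
      vals <- numeric(nrow(smp))
      for (site in design$sites) {
        site_mu <- mu * (1 + 0.1 * stats::rnorm(1))
        for (trt in design$treatments) {
          fac <- if (trt == treated) treatment_variance_factor else 1
          sp_dev <- stats::rnorm(n_pts, sd = sdev) * fac
          tm_dev <- stats::rnorm(n_times, sd = sdev) * fac
          idx <- which(smp$site == site & smp$treatment == trt)
          pi <- match(smp$point[idx], design$points$point)
          ti <- match(smp$time[idx], design$time_points)
          vals[idx] <- site_mu + sp_dev[pi] + tm_dev[ti] +
            stats::rnorm(length(idx), sd = sdev / 4)
        }
      }
      out[[names(property_means)[k]]] <- vals
    }
  })
  rownames(out) <- NULL
  out
}

#' Assign rrn copy-number traits to taxa by group
#'
#' Gives every taxon a positive 16S rRNA operon (rrn) copy number drawn
#' near its group's mean (log-normal jitter, floored at 1 copy). Groups
#' typically represent phyla with distinct growth strategies.
#'
#' @param taxon_ids character vector of taxon ids.
#' @param groups character vector, same length, naming each taxon's group;
#'   every value must appear in \code{names(group_means)}.
#' @param group_means named numeric vector of per-group mean copy numbers
#'   (>= 1).
#' @param jitter_sd sd of the log-normal jitter; 0 assigns the group mean
#'   exactly.
#' @param seed integer seed.
#' @return data frame of class \code{"trait_table"} with columns
#'   \code{taxon}, \code{group}, \code{copy_number}, \code{match_mode}
#'   (always \code{"simulated"} here).
#' @export
assign_rrn_traits <- function(taxon_ids, groups, group_means,
                              jitter_sd = 0.1, seed = NULL) {
  if (length(taxon_ids) != length(groups))
    stopf("taxon_ids and groups must have equal length")
  if (any(group_means < 1)) stopf("copy numbers must be >= 1")
  unknown <- setdiff(unique(groups), names(group_means))
  if (length(unknown))
    stopf("unknown group label(s): %s", paste(unknown, collapse = ", "))
  with_seed(seed, {
    copies <- group_means[groups] *
      exp(stats::rnorm(length(groups), sd = jitter_sd))
    copies <- pmax(1, copies)
    structure(data.frame(taxon = taxon_ids, group = groups,
                         copy_number = as.numeric(copies),
                         match_mode = "simulated",
                         stringsAsFactors = FALSE),
              class = c("trait_table", "data.frame"))
  })
}

#' Simulate occurrence data from the Sloan neutral sampling model
#'
#' For each local community, per-taxon relative abundances are drawn from
#' the neutral stationary Beta distribution
#' \eqn{x_i \sim Beta(N m p_i, N m (1 - p_i))}; a taxon is observed when
#' its local abundance exceeds the detection limit \eqn{d = 1/N} (the
#' model's own sampling mechanism), contributing \eqn{round(N x_i)}
#' reads, so \code{\link{fit_ncm}} applied to the counts recovers the
#' migration rate \eqn{m}.
#'
#' @param n_samples number of local communities.
#' @param n_taxa number of taxa in the source pool.
#' @param m migration rate in (0, 1].
#' @param N reads per sample (community size).
#' @param abundance_sigma log-normal shape of source-pool abundances.
#' @param seed integer seed.
#' @return counts matrix, samples x taxa.
#' @export
simulate_ncm_data <- function(n_samples, n_taxa, m, N,
                              abundance_sigma = 1.5, seed = NULL) {
  if (m <= 0 || m > 1) stopf("m must lie in (0, 1]")
  with_seed(seed, {
    p <- exp(abundance_sigma * stats::rnorm(n_taxa))
    p <- p / sum(p)
    a <- N * m * p; b <- N * m * (1 - p)
    x <- matrix(stats::rbeta(n_samples * n_taxa, rep(a, each = n_samples),
                             rep(b, each = n_samples)),
                n_samples, n_taxa)
    cnt <- round(N * x)
    cnt[x < 1 / N] <- 0
    dimnames(cnt) <- list(paste0("s", seq_len(n_samples)),
                          paste0("t", seq_len(n_taxa)))
    cnt
  })
}
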