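# Shared fixtures: toy trees, tiny designs and a brute-force union oracle.

toy_tree <- function() ape::read.tree(text = "((A:1,B:2):3,C:4);")

# design with one point per area level, so level j pools points 1..j
tiny_design <- function(n_points = 3, n_times = 3, n_sites = 1,
                        n_treatments = 1) {
  make_design(n_sites, n_treatments, n_points, n_times,
              n_area_levels = n_points)
}

# community matrix from an explicit counts matrix (samples x taxa) keyed
# by the design's sample ids for one plot
plot_community <- function(design, counts) {
  meta <- design$samples[design$samples$site == design$sites[1] &
                           design$samples$treatment ==
                           design$treatments[1], ]
  stopifnot(nrow(counts) == nrow(meta))
  rownames(counts) <- meta$sample_id
  community_matrix(counts, meta)
}

# exhaustive set-union oracle for the nested accumulation surface
oracle_surface <- function(counts, meta, design) {
  sets <- lapply(design$area_levels, `[[`, "points")
  times <- design$time_points
  out <- matrix(0, length(sets), length(times))
  for (j in seq_along(sets)) for (k in seq_along(times)) {
    rows <- meta$point %in% sets[[j]] & meta$time %in% times[1:k]
    sub <- counts[rows, , drop = FALSE]
    out[j, k] <- sum(colSums(sub) > 0)
  }
  out
}

# random small community for a tiny design
random_tiny_community <- function(design, n_taxa, lambda = 0.8) {
  meta <- design$samples
  counts <- matrix(stats::rpois(nrow(meta) * n_taxa, lambda),
                   nrow(meta), n_taxa,
                   dimnames = list(meta$sample_id,
                                   paste0("x", seq_len(n_taxa))))
  community_matrix(counts, meta)
}

# synthetic moving-window exponent family with an injected treatment shift
synthetic_family <- function(shift, sd = 0.1, sizes = 5:9, n_start = 6,
                             treatments = c("ctrl", "treat"),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(window_size = sizes, ystart = seq_len(n_start),
                      treatment = treatments, stringsAsFactors = FALSE)
  base <- 0.3 + stats::rnorm(nrow(grid), sd = sd)
  val <- base + ifelse(grid$treatment == treatments[2], shift, 0)
  data.frame(site = "s1", treatment = grid$treatment,
             plot_id = paste0("s1.", grid$treatment),
             response = "richness", window_size = grid$window_size,
             ystart = grid$ystart, z = val, w = val, u = -val / 5,
             b = 1, r_squared = 0.99, ok = TRUE, reason = NA,
             stringsAsFactors = FALSE)
}
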