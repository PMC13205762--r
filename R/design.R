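#' Construct a nested spatiotemporal sampling design
#'
#' Describes a cross-shaped nested sampling layout: a set of sites, each
#' holding one plot per treatment, each plot sampled at \code{n_points}
#' fixed points on every one of \code{n_times} occasions. Points are
#' arranged on two perpendicular transects through the plot centre (a
#' "cross" design) and grouped into nested area levels of strictly
#' increasing size: level \eqn{j}'s point set always contains level
#' \eqn{j-1}'s, so pooling points up to level \eqn{j} emulates sampling a
#' larger area.
#'
#' The default level membership assigns the points closest to the plot
#' centre to the smallest area and grows cumulatively: the cumulative point
#' counts are \code{round(seq(1, n_points, length.out = n_area_levels))}.
#' Default nominal area sizes form the geometric series
#' \eqn{4^{0}, 4^{1}, \dots} m\eqn{^2}; both can be overridden.
#'
#' @param n_sites number of sites.
#' @param n_treatments number of treatments per site (each site x treatment
#'   combination is one plot).
#' @param n_points sampling points per plot.
#' @param n_times number of sampling occasions (months, indexed 1-based).
#' @param n_area_levels number of nested spatial levels; must not exceed
#'   \code{n_points}.
#' @param area_sizes optional numeric vector of nominal area sizes in
#'   m\eqn{^2}, strictly increasing, length \code{n_area_levels}.
#' @param level_counts optional strictly increasing integer vector of
#'   cumulative point counts per level, ending at \code{n_points}.
#' @param site_labels,treatment_labels optional character labels. Defaults
#'   name two sites \code{"sandy_loam"}/\code{"clay_loam"} and two
#'   treatments \code{"fallow"}/\code{"cropping"}.
#' @param point_spacing spacing between neighbouring points along a
#'   transect arm, metres.
#'
#' @return An object of class \code{"sampling_design"}: a list with
#'   elements \code{sites}, \code{treatments}, \code{points} (data frame
#'   with \code{point}, \code{x}, \code{y}), \code{area_levels} (list of
#'   \code{level}, \code{area_m2}, \code{points}), \code{time_points}, and
#'   \code{samples}, a data frame keying every (site, treatment, point,
#'   time) combination.
#'
#' @examples
#' d <- make_design(2, 2, 21, 17, 5)
#' nrow(d$samples)  # 1428
#' @export
make_design <- function(n_sites = 2L, n_treatments = 2L, n_points = 21L,
                        n_times = 17L, n_area_levels = 5L,
                        area_sizes = NULL, level_counts = NULL,
                        site_labels = NULL, treatment_labels = NULL,
                        point_spacing = 1) {
  n_sites <- as.integer(n_sites); n_treatments <- as.integer(n_treatments)
  n_points <- as.integer(n_points); n_times <- as.integer(n_times)
  n_area_levels <- as.integer(n_area_levels)
  if (min(n_sites, n_treatments, n_points, n_times, n_area_levels) < 1L)
    stopf("all design dimensions must be >= 1")
  if (n_area_levels > n_points)
    stopf("invalid design: n_area_levels (%d) exceeds n_points (%d)",
          n_area_levels, n_points)

  if (is.null(site_labels))
    site_labels <- if (n_sites == 2L) c("sandy_loam", "clay_loam") else
      paste0("site", seq_len(n_sites))
  if (is.null(treatment_labels))
    treatment_labels <- if (n_treatments == 2L) c("fallow", "cropping") else
      paste0("treatment", seq_len(n_treatments))
  stopifnot(length(site_labels) == n_sites,
            length(treatment_labels) == n_treatments)

  points <- cross_layout(n_points, point_spacing)

  if (is.null(level_counts)) {
    level_counts <- unique(as.integer(round(
      seq(1, n_points, length.out = n_area_levels))))
  }
  level_counts <- as.integer(level_counts)
  if (length(level_counts) != n_area_levels ||
      any(diff(level_counts) <= 0L) ||
      level_counts[1L] < 1L || level_counts[n_area_levels] > n_points)
    stopf("level_counts must be strictly increasing, within 1..n_points, length n_area_levels")

  if (is.null(area_sizes)) area_sizes <- 4 ^ (seq_len(n_area_levels) - 1)
  if (length(area_sizes) != n_area_levels || any(diff(area_sizes) <= 0) ||
      any(area_sizes <= 0))
    stopf("area_sizes must be positive, strictly increasing, length n_area_levels")

  area_levels <- lapply(seq_len(n_area_levels), function(j) {
    list(level = j, area_m2 = area_sizes[j],
         points = points$point[seq_len(level_counts[j])])
  })

  samples <- expand.grid(time = seq_len(n_times), point = points$point,
                         treatment = treatment_labels, site = site_labels,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("site", "treatment", "point", "time")]
  samples$sample_id <- sprintf("%s.%s.%s.t%02d", samples$site,
                               samples$treatment, samples$point,
                               samples$time)
  rownames(samples) <- NULL

  structure(list(sites = site_labels, treatments = treatment_labels,
                 points = points, area_levels = area_levels,
                 time_points = seq_len(n_times), samples = samples),
            class = "sampling_design")
}

# Points on two perpendicular transects through the origin, ordered by
# distance from the centre so that cumulative level membership corresponds
# to growing radius.
cross_layout <- function(n_points, spacing = 1) {
  xs <- numeric(n_points); ys <- numeric(n_points)
  if (n_points > 1L) {
    k <- 1L; r <- 1L
    arms <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    while (k < n_points) {
      for (a in arms) {
        if (k >= n_points) break
        k <- k + 1L
        xs[k] <- a[1] * r * spacing
        ys[k] <- a[2] * r * spacing
      }
      r <- r + 1L
    }
  }
  data.frame(point = sprintf("p%02d", seq_len(n_points)), x = xs, y = ys,
             stringsAsFactors = FALSE)
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("Nested spatiotemporal sampling design\n")
  cat(sprintf("  sites:       %s\n", paste(x$sites, collapse = ", ")))
  cat(sprintf("  treatments:  %s\n", paste(x$treatments, collapse = ", ")))
  cat(sprintf("  points/plot: %d in %d nested area levels (%s m^2)\n",
              nrow(x$points), length(x$area_levels),
              paste(vapply(x$area_levels, `[[`, 0, "area_m2"),
                    collapse = ", ")))
  cat(sprintf("  time points: %d\n", length(x$time_points)))
  cat(sprintf("  samples:     %d\n", nrow(x$samples)))
  invisible(x)
}

# point sets added at each level (level j's points minus level j-1's)
level_increments <- function(design) {
  sets <- lapply(design$area_levels, `[[`, "points")
  out <- vector("list", length(sets))
  out[[1L]] <- sets[[1L]]
  for (j in seq_along(sets)[-1L])
    out[[j]] <- setdiff(sets[[j]], sets[[j - 1L]])
  out
}
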