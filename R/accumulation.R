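#' Faith's phylogenetic diversity of a taxon set
#'
#' Sum of branch lengths on the union of root-to-tip paths of the set.
#' The default convention is root-inclusive (branches from the tips all
#' the way to the tree root are counted, matching common
#' \pkg{picante} usage), so \code{faith_pd} of all tips equals the total
#' branch length of the tree. With \code{include_root = FALSE} only the
#' spanning subtree below the set's most recent common ancestor is
#' summed, and sets of fewer than two tips have PD 0.
#'
#' @param taxa character vector of tip labels; the empty set has PD 0.
#' @param tree rooted \code{phylo} tree with branch lengths.
#' @param include_root logical; see Details.
#' @return a single non-negative PD value in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
#' faith_pd(c("A", "B", "C"), tr)  # 10
#' faith_pd("A", tr)               # 4
#' faith_pd(c("A", "B"), tr)       # 6
#' @export
faith_pd <- function(taxa, tree, include_root = TRUE) {
  if (length(taxa) == 0L) return(0)
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx))
    stopf("taxa not found in tree: %s",
          paste(utils::head(taxa[is.na(idx)], 5), collapse = ", "))
  paths <- tip_edge_paths(tree)
  edges <- unique(unlist(paths[idx], use.names = FALSE))
  if (!include_root) {
    if (length(taxa) < 2L) return(0)
    # drop the shared stem above the MRCA of the set
    shared <- Reduce(intersect, paths[idx])
    edges <- setdiff(edges, shared)
  }
  sum(tree$edge.length[edges])
}

# edge indices on the path from each tip to the root; cached on the tree
# environment is avoided for purity -- cost is linear and calls are few.
tip_edge_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  incoming <- rep(NA_integer_, n_tip + tree$Nnode)
  incoming[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  lapply(seq_len(n_tip), function(tip) {
    v <- tip; out <- integer()
    while (!is.na(incoming[v])) {
      out <- c(out, incoming[v])
      v <- parent[v]
    }
    out
  })
}

# ---------------------------------------------------------------------------
# indicator machinery shared by the surface builder and permutation tests

# per-(level-increment, time) presence indicators for one plot.
# Returns list(M = J x K x D logical array over taxa, totals = J x K reads,
# taxa, areas, times).
plot_indicators <- function(x, design, on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  meta <- x$samples
  plotids <- unique(meta[, c("site", "treatment")])
  if (nrow(plotids) != 1L)
    stopf("expected samples from a single plot, got %d plots",
          nrow(plotids))
  incs <- level_increments(design)
  times <- design$time_points
  J <- length(incs); K <- length(times)
  taxa <- colnames(x$counts)
  pres <- x$counts > 0

  M <- array(FALSE, dim = c(J, K, length(taxa)))
  totals <- matrix(0, J, K)
  for (j in seq_len(J)) {
    in_inc <- meta$point %in% incs[[j]]
    for (k in seq_len(K)) {
      rows <- which(in_inc & meta$time == times[k])
      if (length(rows) == 0L) {
        if (on_missing == "error")
          stopf("missing samples for level increment %d at time %d", j,
                times[k])
        warning(sprintf("skipping empty cell: increment %d, time %d", j,
                        times[k]), call. = FALSE)
        next
      }
      sub <- pres[rows, , drop = FALSE]
      M[j, k, ] <- colSums(sub) > 0
      totals[j, k] <- sum(x$counts[rows, , drop = FALSE])
    }
  }
  list(M = M, totals = totals, taxa = taxa,
       areas = vapply(design$area_levels, `[[`, 0, "area_m2"),
       times = times, site = plotids$site[1L],
       treatment = plotids$treatment[1L])
}

# map taxon indicators to tree-edge indicators: cell covers an edge iff
# any present taxon's root path uses it.
edge_indicators <- function(M, taxa, tree) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stopf("taxa absent from tree: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  paths <- tip_edge_paths(tree)
  n_edge <- nrow(tree$edge)
  inc <- matrix(0, length(taxa), n_edge)
  tip_idx <- match(taxa, tree$tip.label)
  for (i in seq_along(taxa)) inc[i, paths[[tip_idx[i]]]] <- 1
  d <- dim(M)
  flat <- matrix(M, d[1L] * d[2L], d[3L])
  cov <- (flat %*% inc) > 0
  array(cov, dim = c(d[1L], d[2L], n_edge))
}

# cumulative-union surface: S[j,k] = sum of weights over the union of
# indicator sets at (level order positions 1..j) x (time order 1..k).
surface_sum <- function(M, weights = NULL, level_order = NULL,
                        time_order = NULL) {
  d <- dim(M); J <- d[1L]; K <- d[2L]; D <- d[3L]
  if (!is.null(level_order) || !is.null(time_order))
    M <- M[level_order %||% seq_len(J), time_order %||% seq_len(K), ,
           drop = FALSE]
  S <- matrix(0, J, K)
  acc_level <- matrix(FALSE, K, D)
  for (j in seq_len(J)) {
    acc_level <- acc_level | matrix(M[j, , ], K, D)
    acc <- rep(FALSE, D)
    for (k in seq_len(K)) {
      acc <- acc | acc_level[k, ]
      S[j, k] <- if (is.null(weights)) sum(acc) else sum(weights[acc])
    }
  }
  S
}

# 2-D prefix sums (for pooled read totals)
prefix_sum2 <- function(m) {
  m <- apply(m, 2L, cumsum)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  t(apply(m, 1L, cumsum))
}

# ---------------------------------------------------------------------------

as_accumulation_surface <- function(df, site = NA_character_,
                                    treatment = NA_character_,
                                    temporal_method = "nested") {
  structure(as.data.frame(df),
            site = site, treatment = treatment,
            temporal_method = temporal_method,
            class = c("accumulation_surface", "data.frame"))
}

#' Build a nested spatiotemporal accumulation surface
#'
#' For one plot's samples, computes the cumulative taxon richness (and,
#' when a tree is supplied, Faith's phylogenetic diversity) of the union
#' of all taxa observed over points belonging to nested area levels
#' \eqn{1..j} and time points \eqn{1..k}, for every level \eqn{j} and time
#' length \eqn{k}. Taxa found in the smallest area are augmented by the
#' new taxa of each successively larger area, and likewise along the time
#' axis from the initial survey onward, so richness and PD are monotone
#' non-decreasing along both axes.
#'
#' \code{temporal_method = "complete_nested"} replaces the nested time
#' axis by the mean over all consecutive windows of each length (see
#' \code{\link{complete_nested_curve}}); temporal islands are handled by
#' \code{\link{island_curve}} and are rejected here.
#'
#' @param x a \code{\link{community_matrix}} restricted to one plot (see
#'   \code{\link{subset_plot}}).
#' @param design the \code{sampling_design} describing area levels and
#'   time points.
#' @param tree optional rooted \code{phylo} tree covering all taxa; adds a
#'   \code{pd} column.
#' @param temporal_method \code{"nested"} (default) or
#'   \code{"complete_nested"}.
#' @param on_missing \code{"error"} (default) to fail on a missing
#'   (point, time) cell, \code{"skip"} to drop it with a warning.
#' @param include_root passed to \code{\link{faith_pd}}.
#' @return an \code{accumulation_surface} data frame with columns
#'   \code{site}, \code{treatment}, \code{area_level}, \code{area_m2},
#'   \code{time_months}, \code{richness}, \code{pd} (if tree given),
#'   \code{total_sequences}.
#' @export
build_accumulation_surface <- function(x, design, tree = NULL,
                                       temporal_method = c(
                                         "nested", "complete_nested"),
                                       on_missing = c("error", "skip"),
                                       include_root = TRUE) {
  if (is.character(temporal_method) &&
      length(temporal_method) == 1L &&
      !temporal_method %in% c("nested", "complete_nested")) {
    if (temporal_method == "island")
      stopf("temporal islands need per-survey input; use island_curve()")
    stopf("unknown temporal_method: %s", temporal_method)
  }
  temporal_method <- match.arg(temporal_method)
  ind <- plot_indicators(x, design, on_missing)
  if (temporal_method == "complete_nested")
    return(complete_nested_from_indicators(ind, tree, include_root))

  S <- surface_sum(ind$M)
  totals <- prefix_sum2(ind$totals)
  J <- length(ind$areas); K <- length(ind$times)
  out <- data.frame(
    site = ind$site, treatment = ind$treatment,
    area_level = rep(seq_len(J), each = K),
    area_m2 = rep(ind$areas, each = K),
    time_months = rep(seq_len(K), times = J),
    richness = as.vector(t(S)),
    total_sequences = as.vector(t(totals)),
    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    Me <- edge_indicators(ind$M, ind$taxa, tree)
    PD <- surface_sum(Me, weights = tree$edge.length)
    if (!include_root) {
      # subtract the shared stem per cell: recompute exactly via sets
      PD <- pd_exact_surface(ind, tree, include_root = FALSE)
    }
    out$pd <- as.vector(t(PD))
    out <- out[, c("site", "treatment", "area_level", "area_m2",
                   "time_months", "richness", "pd", "total_sequences")]
  }
  as_accumulation_surface(out, ind$site, ind$treatment, "nested")
}

# slow exact path used only for the non-default rootless PD convention
pd_exact_surface <- function(ind, tree, include_root = FALSE) {
  J <- dim(ind$M)[1L]; K <- dim(ind$M)[2L]
  PD <- matrix(0, J, K)
  for (j in seq_len(J)) for (k in seq_len(K)) {
    sel <- apply(ind$M[seq_len(j), seq_len(k), , drop = FALSE], 3L, any)
    PD[j, k] <- faith_pd(ind$taxa[sel], tree, include_root = include_root)
  }
  PD
}

complete_nested_from_indicators <- function(ind, tree = NULL,
                                            include_root = TRUE) {
  J <- dim(ind$M)[1L]; K <- dim(ind$M)[2L]
  need_pd <- !is.null(tree)
  Me <- if (need_pd) edge_indicators(ind$M, ind$taxa, tree) else NULL
  rows <- list()
  for (Tlen in seq_len(K)) {
    starts <- seq_len(K - Tlen + 1L)
    rich <- matrix(0, J, length(starts))
    pd <- if (need_pd) matrix(0, J, length(starts)) else NULL
    for (s in seq_along(starts)) {
      win <- starts[s]:(starts[s] + Tlen - 1L)
      sub <- ind$M[, win, , drop = FALSE]
      rich[, s] <- surface_sum(sub)[, Tlen]
      if (need_pd)
        pd[, s] <- surface_sum(Me[, win, , drop = FALSE],
                               weights = tree$edge.length)[, Tlen]
    }
    rows[[Tlen]] <- data.frame(
      site = ind$site, treatment = ind$treatment,
      area_level = seq_len(J), area_m2 = ind$areas,
      time_months = Tlen, richness = rowMeans(rich),
      n_windows = length(starts), stringsAsFactors = FALSE)
    if (need_pd) rows[[Tlen]]$pd <- rowMeans(pd)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$area_level, out$time_months), ]
  rownames(out) <- NULL
  as_accumulation_surface(out, ind$site, ind$treatment, "complete_nested")
}

#' Complete-nested temporal accumulation curve
#'
#' Mean cumulative diversity over every consecutive time window of each
#' length: for window length \eqn{T} in a \eqn{K}-month series there are
#' \eqn{K - T + 1} windows, and the reported value is the mean cumulative
#' richness (and PD) across them, per nested area level. At \eqn{T = K}
#' the single window coincides with the nested construction's terminal
#' value.
#'
#' @inheritParams build_accumulation_surface
#' @return an \code{accumulation_surface} data frame (complete-nested
#'   flavour) with a \code{n_windows} column.
#' @export
complete_nested_curve <- function(x, design, tree = NULL,
                                  on_missing = c("error", "skip"),
                                  include_root = TRUE) {
  if (length(design$time_points) < 2L)
    stopf("complete-nested curves need at least 2 time points")
  ind <- plot_indicators(x, design, match.arg(on_missing))
  complete_nested_from_indicators(ind, tree, include_root)
}

#' Temporal-island diversity points
#'
#' Each survey (a "temporal island") of a given duration contributes one
#' point: the total richness (and PD) observed anywhere within it,
#' plotted against its duration.
#'
#' @param surveys list of surveys, each a list with elements
#'   \code{duration} (months, > 0) and \code{counts} (matrix samples x
#'   taxa, or a \code{community_matrix}).
#' @param tree optional tree for Faith's PD.
#' @param include_root passed to \code{\link{faith_pd}}.
#' @return data frame with one row per survey: \code{duration},
#'   \code{richness}, optionally \code{pd}.
#' @export
island_curve <- function(surveys, tree = NULL, include_root = TRUE) {
  if (length(surveys) < 2L) stopf("need at least 2 surveys")
  rows <- lapply(surveys, function(sv) {
    cnt <- if (inherits(sv$counts, "community_matrix")) sv$counts$counts
           else as.matrix(sv$counts)
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
    if (nrow(cnt) == 0L || sum(cnt) == 0) stopf("empty survey")
    present <- colnames(cnt)[colSums(cnt) > 0]
    out <- data.frame(duration = sv$duration,
                      richness = length(present))
    if (!is.null(tree)) out$pd <- faith_pd(present, tree, include_root)
    out
  })
  do.call(rbind, rows)
}

#' Depth-standardized diversity per scale
#'
#' Rarefies each scale's pooled counts to a common sequencing depth so
#' that diversity can be compared across spatial or temporal scales
#' without passive-sampling artefacts. Reports the mean richness (and PD)
#' over repeated subsamples drawn without replacement, alongside the
#' closed-form (hypergeometric) expected rarefied richness of
#' \code{\link[vegan]{rarefy}}.
#'
#' @param pooled_counts matrix of pooled counts, one row per scale
#'   (rownames = scale labels), columns = taxa; a single named vector is
#'   treated as one scale.
#' @param target_depth number of reads to subsample per scale; must not
#'   exceed any scale's pooled total.
#' @param n_reps number of random subsamples averaged (default 100).
#' @param tree optional tree: adds mean rarefied Faith's PD.
#' @param include_root passed to \code{\link{faith_pd}}.
#' @param seed integer seed.
#' @return data frame with columns \code{scale}, \code{pooled_depth},
#'   \code{richness_observed}, \code{richness_rarefied},
#'   \code{richness_expected}, and \code{pd_rarefied} when a tree is
#'   given.
#' @export
standardize_depth <- function(pooled_counts, target_depth, n_reps = 100L,
                              tree = NULL, include_root = TRUE,
                              seed = NULL) {
  if (is.null(dim(pooled_counts)))
    pooled_counts <- matrix(pooled_counts, nrow = 1L,
                            dimnames = list("scale1",
                                            names(pooled_counts)))
  pooled_counts <- as.matrix(pooled_counts)
  depths <- rowSums(pooled_counts)
  if (any(target_depth > depths))
    stopf("target_depth %g exceeds pooled depth of scale(s): %s",
          target_depth,
          paste(rownames(pooled_counts)[target_depth > depths],
                collapse = ", "))
  taxa <- colnames(pooled_counts)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(pooled_counts)), function(i) {
      cnt <- pooled_counts[i, ]
      # vegan warns when the smallest pooled count exceeds 1; pooled
      # scale totals are still valid count data, so silence it
      expected <- as.numeric(suppressWarnings(
        vegan::rarefy(cnt, target_depth)))
      rich <- numeric(n_reps)
      pdv <- if (!is.null(tree)) numeric(n_reps) else NULL
      for (r in seq_len(n_reps)) {
        sub <- as.numeric(suppressWarnings(
          vegan::rrarefy(cnt, target_depth)))
        present <- taxa[sub > 0]
        rich[r] <- length(present)
        if (!is.null(tree))
          pdv[r] <- faith_pd(present, tree, include_root)
      }
      out <- data.frame(scale = rownames(pooled_counts)[i],
                        pooled_depth = depths[i],
                        richness_observed = sum(cnt > 0),
                        richness_rarefied = mean(rich),
                        richness_expected = expected,
                        stringsAsFactors = FALSE)
      if (!is.null(tree)) out$pd_rarefied <- mean(pdv)
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
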