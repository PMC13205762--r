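# rrn copy-number traits, environmental heterogeneity and stability.

rank_order <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Match taxa against an rrn copy-number reference
#'
#' Assigns each query taxon an estimated 16S rRNA operon (rrn) copy
#' number from a reference of rank-labelled taxa (an rrnDB-style export).
#' Matching starts at the query's lowest named rank: every reference
#' record whose lineage carries that name (the record itself or any of
#' its child taxa) contributes, and the assigned value is their mean
#' (\code{match_mode = "child-mean"}). If no record matches, the search
#' ascends the query's lineage rank by rank and uses the mean over the
#' parent taxon's records (\code{match_mode = "parent-mean"}). Taxa
#' unmatched at every rank are flagged \code{match_mode = "none"} with a
#' missing copy number and are excluded by downstream weighting.
#'
#' @param taxonomy data frame with a \code{taxon} id column plus lineage
#'   columns among \code{domain, phylum, class, order, family, genus,
#'   species} (NA where unresolved).
#' @param reference data frame with columns \code{rank}, \code{name},
#'   \code{copy_number} and the same lineage columns locating each record
#'   (NA below the record's rank).
#' @return data frame of class \code{"trait_table"}: \code{taxon},
#'   \code{copy_number}, \code{matched_rank}, \code{match_mode}.
#' @export
match_rrn <- function(taxonomy, reference) {
  if (is.null(reference) || nrow(reference) == 0L)
    stopf("empty trait reference")
  if (!all(c("rank", "name", "copy_number") %in% names(reference)))
    stopf("reference needs columns rank, name, copy_number")
  ranks <- intersect(rank_order, names(taxonomy))
  if (length(ranks) == 0L) stopf("taxonomy has no recognised rank columns")

  rows <- lapply(seq_len(nrow(taxonomy)), function(i) {
    lowest <- lowest_named_rank(taxonomy[i, ], ranks)
    for (r in rev(ranks)) {           # lowest rank first
      nm <- taxonomy[[r]][i]
      if (is.na(nm) || !nzchar(nm)) next
      if (!r %in% names(reference)) next
      hit <- which(!is.na(reference[[r]]) & reference[[r]] == nm)
      if (length(hit)) {
        mode <- if (identical(r, lowest)) "child-mean" else "parent-mean"
        return(data.frame(taxon = taxonomy$taxon[i],
                          copy_number = mean(reference$copy_number[hit]),
                          matched_rank = r, match_mode = mode,
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(taxon = taxonomy$taxon[i], copy_number = NA_real_,
               matched_rank = NA_character_, match_mode = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

lowest_named_rank <- function(row, ranks) {
  for (r in rev(ranks))
    if (!is.na(row[[r]]) && nzchar(row[[r]])) return(r)
  NA_character_
}

#' Community-weighted mean rrn copy number
#'
#' Abundance-weighted mean of per-taxon rrn copy numbers for one sample:
#' \eqn{\sum_i S_i n_i / \sum_i S_i}, where \eqn{S_i} is the sequence
#' count and \eqn{n_i} the estimated copy number of taxon \eqn{i}. Taxa
#' without a trait value are excluded from both numerator and
#' denominator (renormalization). The result always lies between the
#' smallest and largest contributing copy number.
#'
#' @param counts named numeric vector of taxon counts for one sample.
#' @param traits a \code{trait_table} (columns \code{taxon},
#'   \code{copy_number}) or a named numeric vector of copy numbers.
#' @return the community-level rrn copy number (single numeric).
#' @examples
#' community_rrn(c(a = 3, b = 1), c(a = 2, b = 4))  # 2.5
#' @export
community_rrn <- function(counts, traits) {
  if (inherits(traits, "data.frame")) {
    tv <- traits$copy_number
    names(tv) <- traits$taxon
  } else tv <- traits
  n <- tv[names(counts)]
  keep <- !is.na(n) & counts > 0
  if (!any(keep)) stopf("no counted taxon has a trait value")
  sum(counts[keep] * n[keep]) / sum(counts[keep])
}

#' Coefficient of variation as a heterogeneity measure
#'
#' Spatial mode: sample sd over mean across points at one time point.
#' Temporal mode: detrended CV -- the sd of the residuals of an ordinary
#' linear regression of the series on time, divided by the series mean,
#' so an exactly linear trend has zero temporal heterogeneity.
#'
#' @param values numeric vector (n >= 2) of property values.
#' @param mode \code{"spatial"} or \code{"temporal"}.
#' @param time numeric time axis for temporal mode (defaults to the
#'   integer index).
#' @return a single non-negative CV (dimensionless).
#' @export
heterogeneity_cv <- function(values, mode = c("spatial", "temporal"),
                             time = NULL) {
  mode <- match.arg(mode)
  if (length(values) < 2L) stopf("need at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("mean is zero; CV undefined")
  if (mode == "spatial") return(stats::sd(values) / m)
  time <- time %||% seq_along(values)
  res <- stats::residuals(stats::lm(values ~ time))
  stats::sd(res) / m
}

#' Temporal stability of a richness series
#'
#' Inverse coefficient of variation, mean / sd, of richness across the
#' time series. A constant series has no variability; the result is then
#' flagged infinite.
#'
#' @param series numeric richness series (n >= 2).
#' @return a single stability value (\code{Inf}, with a warning, for a
#'   constant series).
#' @export
temporal_stability <- function(series) {
  if (length(series) < 2L) stopf("need at least 2 values")
  s <- stats::sd(series)
  if (s == 0) {
    warning("zero variability: infinite temporal stability", call. = FALSE)
    return(Inf)
  }
  mean(series) / s
}

#' Spatial and temporal heterogeneity profile of soil properties
#'
#' For each plot and property: the spatial CV across points at every time
#' point, and the detrended temporal CV of every point's series.
#'
#' @param soil data frame from \code{\link{simulate_soil_table}} (or the
#'   same layout read from file): sample metadata columns plus one column
#'   per property.
#' @param properties character vector of property column names; default:
#'   every non-metadata column.
#' @return data frame with columns \code{site}, \code{treatment},
#'   \code{property}, \code{mode} (\code{spatial}/\code{temporal}),
#'   \code{unit} (time point or sampling point), \code{cv}.
#' @export
heterogeneity_profile <- function(soil, properties = NULL) {
  meta_cols <- c("sample_id", "site", "treatment", "point", "time")
  properties <- properties %||% setdiff(names(soil), meta_cols)
  rows <- list()
  for (site in unique(soil$site)) for (trt in unique(soil$treatment)) {
    sub <- soil[soil$site == site & soil$treatment == trt, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (pr in properties) {
      for (tp in unique(sub$time)) {
        v <- sub[[pr]][sub$time == tp]
        if (length(v) >= 2L && mean(v) != 0)
          rows[[length(rows) + 1L]] <- data.frame(
            site = site, treatment = trt, property = pr,
            mode = "spatial", unit = as.character(tp),
            cv = heterogeneity_cv(v, "spatial"),
            stringsAsFactors = FALSE)
      }
      for (pt in unique(sub$point)) {
        sel <- sub$point == pt
        v <- sub[[pr]][sel][order(sub$time[sel])]
        if (length(v) >= 2L && mean(v) != 0)
          rows[[length(rows) + 1L]] <- data.frame(
            site = site, treatment = trt, property = pr,
            mode = "temporal", unit = pt,
            cv = heterogeneity_cv(v, "temporal"),
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
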