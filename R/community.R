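#' Community count matrix with spatiotemporal sample metadata
#'
#' Bundles a non-negative integer count matrix (samples x taxa) with the
#' site / treatment / point / time metadata of each sample. Taxon ids are
#' the column names and must match tree tip labels whenever phylogenetic
#' diversity is requested downstream.
#'
#' @param counts numeric matrix, samples in rows (rownames = sample ids),
#'   taxa in columns (colnames = taxon ids), entries non-negative.
#' @param metadata data frame with columns \code{sample_id}, \code{site},
#'   \code{treatment}, \code{point}, \code{time}; one row per sample, in
#'   any order (matched to \code{counts} by \code{sample_id}).
#'
#' @return An object of class \code{"community_matrix"}: list with
#'   \code{counts} and \code{samples}.
#' @export
community_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry sample ids as rownames and taxon ids as colnames")
  if (any(counts < 0)) stopf("counts must be non-negative")
  need <- c("sample_id", "site", "treatment", "point", "time")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stopf("metadata sample ids must be unique")
  unknown <- setdiff(rownames(counts), metadata$sample_id)
  if (length(unknown))
    stopf("samples without metadata: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), need]
  rownames(metadata) <- NULL
  structure(list(counts = counts, samples = metadata),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  sites: %s | treatments: %s | times: %d\n",
              paste(unique(x$samples$site), collapse = ", "),
              paste(unique(x$samples$treatment), collapse = ", "),
              length(unique(x$samples$time))))
  invisible(x)
}

#' Subset a community matrix to one plot (site x treatment)
#'
#' @param x a \code{community_matrix}.
#' @param site,treatment labels identifying the plot.
#' @param drop_empty drop taxa with zero total count in the subset.
#' @return a \code{community_matrix} restricted to the plot's samples.
#' @export
subset_plot <- function(x, site, treatment, drop_empty = FALSE) {
  keep <- x$samples$site == site & x$samples$treatment == treatment
  if (!any(keep)) stopf("no samples for plot %s / %s", site, treatment)
  counts <- x$counts[keep, , drop = FALSE]
  if (drop_empty) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  community_matrix(counts, x$samples[keep, , drop = FALSE])
}

# all (site, treatment) plots present in a community matrix
plot_table <- function(x) {
  unique(x$samples[, c("site", "treatment")])
}
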