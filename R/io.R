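# Reading and writing the pipeline's plain-text formats (TSV, Newick,
# YAML). Community tables are stored taxa-as-rows x samples-as-columns.

#' Write / read a community count table
#'
#' TSV with taxa as rows and samples as columns; the first column
#' (\code{taxon_id}) holds taxon ids. An optional BIOM-style comment
#' header line is tolerated on read.
#'
#' @param x a \code{\link{community_matrix}}.
#' @param path output TSV path.
#' @return \code{write_community_table}: the path, invisibly.
#' @export
write_community_table <- function(x, path) {
  tab <- t(x$counts)
  df <- data.frame(taxon_id = rownames(tab), tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_table
#' @param counts_path community table TSV (taxa x samples).
#' @param metadata_path sample metadata TSV with columns
#'   \code{sample_id, site, treatment, point, time}.
#' @return \code{read_community_table}: a \code{community_matrix}.
#' @export
read_community_table <- function(counts_path, metadata_path) {
  first <- readLines(counts_path, n = 1L)
  skip <- if (startsWith(first, "#") &&
              !startsWith(first, "#OTU") && !startsWith(first, "#taxon"))
    1L else 0L
  tab <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                           skip = skip, check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  taxa <- as.character(tab[[1L]])
  counts <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(counts) <- taxa
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  community_matrix(counts, meta)
}

#' @rdname write_community_table
#' @export
write_metadata <- function(x, path) {
  utils::write.table(x$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an accumulation surface as TSV
#'
#' @param surface an \code{accumulation_surface}.
#' @param path output path.
#' @export
write_surface <- function(surface, path) {
  utils::write.table(as.data.frame(surface), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble an analysis configuration
#'
#' Either supply file paths (\code{community}, \code{metadata},
#' \code{tree}, optional \code{soil} and \code{traits}) or leave them
#' NULL to run in synthetic mode, in which case \code{synthetic} holds
#' the design dimensions and generator parameters. Exactly one of the
#' two modes is active.
#'
#' @param community,metadata,tree,soil,traits input file paths (or NULL).
#' @param synthetic list of synthetic-mode settings: design dimensions
#'   (\code{n_sites}, \code{n_treatments}, \code{n_points},
#'   \code{n_times}, \code{n_area_levels}) and any
#'   \code{\link{simulation_params}} fields.
#' @param temporal_method \code{"nested"} or \code{"complete_nested"}.
#' @param window_sizes moving-window sizes (months).
#' @param n_rand,block_size permutation settings.
#' @param area_factor,time_factor unit conversion for reported
#'   equivalence ratios (defaults: m^2 -> km^2, months -> yr).
#' @param outdir output directory for \code{\link{write_report}}.
#' @param seed root seed; every stochastic stage derives its own
#'   sub-stream from it.
#' @return a list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(community = NULL, metadata = NULL,
                            tree = NULL, soil = NULL, traits = NULL,
                            synthetic = list(), temporal_method = "nested",
                            window_sizes = 5:14, n_rand = 1000L,
                            block_size = 3L, area_factor = 1e6,
                            time_factor = 12, outdir = NULL, seed = 1L) {
  file_mode <- !is.null(community)
  if (file_mode && (is.null(metadata)))
    stopf("file mode needs both community and metadata paths")
  if (file_mode && length(synthetic))
    stopf("exactly one of file inputs or synthetic mode may be active")
  syn_defaults <- list(n_sites = 2L, n_treatments = 2L, n_points = 21L,
                       n_times = 17L, n_area_levels = 5L)
  synthetic <- utils::modifyList(syn_defaults, synthetic)
  structure(list(community = community, metadata = metadata, tree = tree,
                 soil = soil, traits = traits, synthetic = synthetic,
                 file_mode = file_mode,
                 temporal_method = temporal_method,
                 window_sizes = window_sizes, n_rand = as.integer(n_rand),
                 block_size = as.integer(block_size),
                 area_factor = area_factor, time_factor = time_factor,
                 outdir = outdir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file with any \code{analysis_config} fields.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Read and cross-validate pipeline inputs
#'
#' Loads the community table, metadata, tree and optional soil / trait
#' tables named in a config, checks that every sample has metadata and
#' -- when a tree is present -- that the tree covers every taxon, and
#' reconstructs a \code{sampling_design} from the metadata (nesting
#' defaults as in \code{\link{make_design}}).
#'
#' @param config an \code{analysis_config} in file mode.
#' @return list with \code{community}, \code{design}, \code{tree},
#'   \code{soil}, \code{traits}.
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!config$file_mode) stopf("config is in synthetic mode")
  for (p in c(config$community, config$metadata, config$tree,
              config$soil, config$traits))
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s",
                                              p)
  x <- read_community_table(config$community, config$metadata)
  tree <- if (!is.null(config$tree)) ape::read.tree(config$tree) else NULL
  if (!is.null(tree)) {
    missing <- setdiff(colnames(x$counts), tree$tip.label)
    if (length(missing))
      stopf("taxa absent from tree: %s%s",
            paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10)
              sprintf(" (+%d more)", length(missing) - 10) else "")
  }
  meta <- x$samples
  design <- make_design(
    n_sites = length(unique(meta$site)),
    n_treatments = length(unique(meta$treatment)),
    n_points = length(unique(meta$point)),
    n_times = length(unique(meta$time)),
    n_area_levels = min(config$synthetic$n_area_levels,
                        length(unique(meta$point))),
    site_labels = unique(meta$site),
    treatment_labels = unique(meta$treatment))
  # carry the file's own point, time and sample labels
  design$time_points <- sort(unique(meta$time))
  design$points$point <- sort(unique(meta$point))
  design$area_levels <- lapply(design$area_levels, function(al) {
    al$points <- design$points$point[seq_along(al$points)]
    al
  })
  soil <- if (!is.null(config$soil))
    utils::read.table(config$soil, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  traits <- if (!is.null(config$traits))
    utils::read.table(config$traits, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  list(community = x, design = design, tree = tree, soil = soil,
       traits = traits)
}

# non-clobbering output path: file.tsv, file_2.tsv, file_3.tsv, ...
versioned_path <- function(path) {
  if (!file.exists(path)) return(path)
  stem <- tools::file_path_sans_ext(path)
  ext <- tools::file_ext(path)
  i <- 2L
  repeat {
    cand <- sprintf("%s_%d.%s", stem, i, ext)
    if (!file.exists(cand)) return(cand)
    i <- i + 1L
  }
}
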