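#' Run the full spatiotemporal scaling analysis
#'
#' Orchestrates every stage on either synthetic or file inputs: nested
#' accumulation surfaces per plot (richness and PD), single-variable
#' power-law fits (SAR/PAR/STR/PTR), interaction model fits (STAR/PTAR)
#' with restricted block-permutation significance, time-space
#' equivalence ratios in native and converted units, moving-window
#' families with mixed-model / lnRR / Cohen's d treatment and site
#' contrasts, soil heterogeneity profiles with treatment effect sizes,
#' community rrn trait means and their rank correlations with scaling
#' rates, per-time-point neutral-model fits with treatment contrasts,
#' and temporal stability. The whole run is deterministic given the
#' config seed.
#'
#' @param config an \code{\link{analysis_config}}.
#' @param quiet suppress per-stage progress messages.
#' @return a list of class \code{"starscale_results"}; see
#'   \code{\link{write_report}} for the serialized layout.
#' @export
run_pipeline <- function(config = analysis_config(), quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt),
                    format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  seed <- config$seed
  if (config$file_mode) {
    say("reading inputs")
    inp <- read_inputs(config)
    design <- inp$design; x <- inp$community; tree <- inp$tree
    soil <- inp$soil; traits <- inp$traits
  } else {
    syn <- config$synthetic
    say("synthesizing design (%d x %d x %d x %d, %d levels)",
        syn$n_sites, syn$n_treatments, syn$n_points, syn$n_times,
        syn$n_area_levels)
    design <- make_design(syn$n_sites, syn$n_treatments, syn$n_points,
                          syn$n_times, syn$n_area_levels)
    par_fields <- intersect(names(syn), names(formals(simulation_params)))
    params <- do.call(simulation_params, syn[par_fields])
    params$seed <- substream_seed(seed, "communities")
    tree <- simulate_tree(params$pool_size,
                          seed = substream_seed(seed, "tree"))
    say("simulating communities (%d taxa, %d samples)",
        params$pool_size, nrow(design$samples))
    x <- simulate_communities(design, params)
    soil <- simulate_soil_table(
      design,
      treatment_variance_factor = syn$soil_variance_factor %||% 0.6,
      seed = substream_seed(seed, "soil"))
    groups <- paste0("g", 1 + (seq_len(params$pool_size) %% 5))
    traits <- assign_rrn_traits(
      colnames(x$counts), groups,
      stats::setNames(c(1.5, 2.5, 4, 6, 9), paste0("g", 1:5)),
      seed = substream_seed(seed, "traits"))
  }

  plots <- plot_table(x)
  plots$plot_id <- paste(plots$site, plots$treatment, sep = ".")

  say("building accumulation surfaces (%d plots, %s temporal method)",
      nrow(plots), config$temporal_method)
  surfaces <- list(); star_fits <- list(); power_fits <- list()
  perm_tests <- list(); ratios <- list(); stability <- list()
  responses <- if (is.null(tree)) "richness" else c("richness", "pd")
  for (i in seq_len(nrow(plots))) {
    pid <- plots$plot_id[i]
    plt <- subset_plot(x, plots$site[i], plots$treatment[i])
    surf <- build_accumulation_surface(
      plt, design, tree, temporal_method = config$temporal_method)
    surfaces[[pid]] <- surf
    for (resp in responses) {
      for (pred in c("area", "time")) {
        pf <- fit_power_law(surf, pred, resp)
        power_fits[[length(power_fits) + 1L]] <- data.frame(
          plot_id = pid, site = plots$site[i],
          treatment = plots$treatment[i], model = pf$model,
          response = resp, slope = pf$slope, intercept = pf$intercept,
          r_squared = pf$r_squared, n = pf$n_points,
          stringsAsFactors = FALSE)
      }
      pt <- block_permutation_test(
        plt, design, response = resp, tree = tree,
        n_rand = config$n_rand, block_size = config$block_size,
        seed = substream_seed(seed, "permutation"))
      fit <- attr(pt, "fit")
      perm_tests[[length(perm_tests) + 1L]] <- data.frame(
        plot_id = pid, response = resp,
        statistic = vapply(pt, `[[`, "", "statistic"),
        observed = vapply(pt, `[[`, 0, "observed"),
        p_value = vapply(pt, `[[`, 0, "p_value"),
        n_rand = vapply(pt, `[[`, 0L, "n_rand"),
        stringsAsFactors = FALSE)
      ratio <- equivalence_ratio(fit)
      conv <- rescale_units(fit, config$area_factor, config$time_factor,
                            area_unit = "km2", time_unit = "yr")
      star_fits[[length(star_fits) + 1L]] <- data.frame(
        plot_id = pid, site = plots$site[i],
        treatment = plots$treatment[i], response = resp,
        z = fit$z, w = fit$w, u = fit$u, b = fit$b,
        r_squared = fit$r_squared,
        p_model = pt$r_squared$p_value, p_z = pt$z$p_value,
        p_w = pt$w$p_value, p_u = pt$u$p_value,
        stringsAsFactors = FALSE)
      ratios[[length(ratios) + 1L]] <- data.frame(
        plot_id = pid, response = resp,
        ratio_m2_per_month = ratio$value,
        ratio_km2_per_yr = equivalence_ratio(conv)$value,
        stringsAsFactors = FALSE)
    }
    rich_series <- vapply(sort(unique(plt$samples$time)), function(tp)
      sum(colSums(plt$counts[plt$samples$time == tp, ,
                             drop = FALSE]) > 0), 0)
    stability[[length(stability) + 1L]] <- data.frame(
      plot_id = pid,
      stability = if (stats::sd(rich_series) == 0) Inf else
        temporal_stability(rich_series),
      stringsAsFactors = FALSE)
  }
  star_fits <- do.call(rbind, star_fits)
  power_fits <- do.call(rbind, power_fits)
  perm_tests <- do.call(rbind, perm_tests)
  ratios <- do.call(rbind, ratios)
  stability <- do.call(rbind, stability)

  say("fitting moving-window families (sizes %s)",
      paste(range(config$window_sizes), collapse = "-"))
  family <- fit_window_family(x, design, tree,
                              sizes = config$window_sizes)

  effects <- list()
  add_effect <- function(label, es) {
    effects[[length(effects) + 1L]] <<- data.frame(
      contrast = label, method = es$method, estimate = es$estimate,
      se = es$se, p_value = es$p_value,
      structure_used = es$structure_used %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  for (resp in responses) {
    fam <- family[family$response == resp & family$ok, ]
    for (fx in c("treatment", "site")) {
      if (length(unique(plots[[fx]])) != 2L) next
      for (e in c("z", "w", "u")) {
        es <- lmm_effect_size(family, exponent = e, response = resp,
                              fixed = fx, abs_value = (e == "u"))
        add_effect(sprintf("%s:%s:%s", fx, resp, e), es)
      }
      grp <- split(abs(fam$w), fam[[fx]])
      if (length(grp) == 2L) {
        add_effect(sprintf("%s:%s:w", fx, resp),
                   ln_response_ratio(grp[[2L]], grp[[1L]]))
        add_effect(sprintf("%s:%s:w", fx, resp),
                   cohens_d(grp[[2L]], grp[[1L]]))
      }
    }
  }
  effects <- if (length(effects)) do.call(rbind, effects) else NULL

  hetero <- NULL; soil_effects <- NULL
  if (!is.null(soil)) {
    say("profiling soil heterogeneity")
    hetero <- heterogeneity_profile(soil)
    if (length(unique(hetero$treatment)) == 2L) {
      trts <- unique(hetero$treatment)
      rows <- list()
      for (pr in unique(hetero$property)) for (md in c("spatial",
                                                       "temporal")) {
        a <- hetero$cv[hetero$property == pr & hetero$mode == md &
                         hetero$treatment == trts[2L]]
        b <- hetero$cv[hetero$property == pr & hetero$mode == md &
                         hetero$treatment == trts[1L]]
        if (length(a) >= 2L && length(b) >= 2L) {
          es <- tryCatch(cohens_d(a, b), error = function(e) NULL)
          if (!is.null(es))
            rows[[length(rows) + 1L]] <- data.frame(
              property = pr, mode = md,
              contrast = paste(trts[2L], "vs", trts[1L]),
              cohens_d = es$estimate, p_value = es$p_value,
              stringsAsFactors = FALSE)
        }
      }
      soil_effects <- if (length(rows)) do.call(rbind, rows) else NULL
    }
  }

  rrn <- NULL; rrn_cor <- NULL
  if (!is.null(traits)) {
    say("computing community rrn copy numbers")
    rrn <- data.frame(
      sample_id = rownames(x$counts),
      community_rrn = vapply(seq_len(nrow(x$counts)), function(i)
        community_rrn(x$counts[i, ], traits), 0),
      stringsAsFactors = FALSE)
    rrn <- merge(rrn, x$samples, by = "sample_id")
    plot_rrn <- stats::aggregate(
      community_rrn ~ site + treatment, data = rrn, FUN = mean)
    plot_rrn$plot_id <- paste(plot_rrn$site, plot_rrn$treatment,
                              sep = ".")
    rr <- star_fits[star_fits$response == "richness", ]
    tab <- merge(rr, plot_rrn[, c("plot_id", "community_rrn")],
                 by = "plot_id")
    if (nrow(tab) >= 4L)
      rrn_cor <- tryCatch(
        spearman_fdr(tab[, c("z", "w")],
                     tab[, "community_rrn", drop = FALSE]),
        error = function(e) NULL)
    rrn <- plot_rrn
  }

  ncm_fits <- NULL; ncm_effects <- NULL
  say("fitting neutral community models per time point")
  nrows <- list()
  for (i in seq_len(nrow(plots))) {
    plt <- subset_plot(x, plots$site[i], plots$treatment[i])
    for (tp in sort(unique(plt$samples$time))) {
      cnt <- plt$counts[plt$samples$time == tp, , drop = FALSE]
      fit <- tryCatch(fit_ncm(cnt), error = function(e) NULL)
      if (!is.null(fit))
        nrows[[length(nrows) + 1L]] <- data.frame(
          plot_id = plots$plot_id[i], site = plots$site[i],
          treatment = plots$treatment[i], timepoint = tp, m = fit$m,
          Nm = fit$Nm, r_squared = fit$r_squared,
          n_taxa = fit$n_taxa, stringsAsFactors = FALSE)
    }
  }
  if (length(nrows)) {
    ncm_fits <- do.call(rbind, nrows)
    if (length(unique(ncm_fits$treatment)) == 2L) {
      erows <- lapply(unique(ncm_fits$site), function(site) {
        sub <- ncm_fits[ncm_fits$site == site, ]
        es <- tryCatch(ncm_treatment_effect(sub),
                       error = function(e) NULL)
        if (is.null(es)) return(NULL)
        data.frame(site = site, estimate = es$estimate,
                   p_value = es$p_value, stringsAsFactors = FALSE)
      })
      ncm_effects <- do.call(rbind, erows)
    }
  }

  say("done")
  structure(list(config = config, design = design, plots = plots,
                 surfaces = surfaces, power_fits = power_fits,
                 star_fits = star_fits, perm_tests = perm_tests,
                 equivalence_ratios = ratios, window_family = family,
                 effects = effects, heterogeneity = hetero,
                 soil_effects = soil_effects, rrn = rrn,
                 rrn_correlations = rrn_cor, ncm_fits = ncm_fits,
                 ncm_effects = ncm_effects, stability = stability,
                 log = log_lines),
            class = "starscale_results")
}

#' @export
print.starscale_results <- function(x, ...) {
  cat("starscale results\n")
  cat(sprintf("  plots: %d | STAR/PTAR fits: %d | window fits: %d\n",
              nrow(x$plots), nrow(x$star_fits),
              sum(x$window_family$ok)))
  if (!is.null(x$star_fits)) {
    agg <- stats::aggregate(cbind(z, w, u, r_squared) ~ response,
                            data = x$star_fits, FUN = mean)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize pipeline results
#'
#' Writes tidy TSV tables, a machine-readable JSON summary and a run log
#' into \code{outdir}. Existing files are never clobbered: a numeric
#' suffix is appended instead.
#'
#' @param results a \code{starscale_results} object (possibly partial:
#'   NULL components are skipped and listed in the manifest).
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_report <- function(results, outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stopf("cannot create output directory %s", outdir)
  written <- character()
  put <- function(obj, name) {
    if (is.null(obj)) return()
    path <- versioned_path(file.path(outdir, paste0(name, ".tsv")))
    utils::write.table(as.data.frame(obj), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written[name] <<- path
  }
  if (!is.null(results$surfaces))
    put(do.call(rbind, lapply(results$surfaces, as.data.frame)),
        "surfaces")
  put(results$power_fits, "power_law_fits")
  put(results$star_fits, "star_fits")
  put(results$perm_tests, "permutation_tests")
  put(results$equivalence_ratios, "equivalence_ratios")
  put(results$window_family, "window_family")
  put(results$effects, "effect_sizes")
  put(results$heterogeneity, "heterogeneity")
  put(results$soil_effects, "soil_effect_sizes")
  put(results$rrn, "community_rrn")
  put(results$rrn_correlations, "rrn_correlations")
  put(results$ncm_fits, "ncm_fits")
  put(results$ncm_effects, "ncm_effect_sizes")
  put(results$stability, "temporal_stability")

  summary <- list(
    seed = results$config$seed,
    n_plots = nrow(results$plots),
    star = if (!is.null(results$star_fits))
      stats::aggregate(cbind(z, w, u, r_squared) ~ response,
                       data = results$star_fits, FUN = mean),
    equivalence_km2_per_yr = if (!is.null(results$equivalence_ratios))
      stats::aggregate(ratio_km2_per_yr ~ response,
                       data = results$equivalence_ratios, FUN = mean),
    files = as.list(written))
  jpath <- versioned_path(file.path(outdir, "summary.json"))
  jsonlite::write_json(summary, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  written["summary"] <- jpath

  lpath <- versioned_path(file.path(outdir, "run_log.txt"))
  cfg <- results$config
  cfg_echo <- utils::capture.output(utils::str(
    cfg[setdiff(names(cfg), "synthetic")], give.attr = FALSE))
  writeLines(c(results$log %||% character(), "", "config:", cfg_echo),
             lpath)
  written["log"] <- lpath
  invisible(written)
}
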