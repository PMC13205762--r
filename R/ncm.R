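# Sloan neutral community model: occurrence frequency vs mean abundance.

#' Fit the Sloan neutral community model at one time point
#'
#' For a set of local communities sampled at one time point, the neutral
#' model predicts each taxon's occurrence frequency from its mean
#' relative abundance \eqn{p} via the tail of a Beta distribution:
#' \deqn{\hat{f}(p) = 1 - B(d;\, N m p,\; N m (1 - p)),}
#' where \eqn{N} is the community (read) size, \eqn{m} the migration
#' rate, and \eqn{d} the detection limit. The migration rate is estimated
#' by bounded least squares of observed frequencies on predicted
#' frequencies across taxa; \eqn{R^2 = 1 - SSE/SST} (may be negative).
#' Higher \eqn{m} means weaker dispersal limitation.
#'
#' @param counts matrix of counts (samples x taxa) at one time point, or
#'   a \code{\link{community_matrix}}.
#' @param N community size; default: mean per-sample read depth.
#' @param detection_limit detection threshold \eqn{d}; default
#'   \eqn{1/N}.
#' @param min_samples,min_taxa minimum data requirements (defaults 5 and
#'   10).
#' @return object of class \code{"ncm_fit"}: list with \code{m},
#'   \code{Nm}, \code{r_squared}, \code{N}, \code{detection_limit},
#'   \code{n_taxa}, \code{n_samples}, \code{boundary} (TRUE when every
#'   taxon is ubiquitous, leaving the frequency spread degenerate).
#' @export
fit_ncm <- function(counts, N = NULL, detection_limit = NULL,
                    min_samples = 5L, min_taxa = 10L) {
  if (inherits(counts, "community_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < min_samples)
    stopf("need at least %d samples, got %d", min_samples, nrow(counts))
  if (ncol(counts) < min_taxa)
    stopf("need at least %d observed taxa, got %d", min_taxa,
          ncol(counts))
  depth <- rowSums(counts)
  if (any(depth == 0)) stopf("samples with zero reads present")
  N <- N %||% mean(depth)
  d <- detection_limit %||% (1 / N)
  rel <- sweep(counts, 1L, depth, "/")
  p <- colMeans(rel)
  f <- colMeans(counts > 0)
  boundary <- all(f == 1)

  sse <- function(m) {
    pred <- 1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
    sum((f - pred)^2)
  }
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-8)
  m_hat <- opt$minimum
  sst <- sum((f - mean(f))^2)
  r2 <- if (sst > 0) 1 - opt$objective / sst else NA_real_
  structure(list(m = m_hat, Nm = N * m_hat, r_squared = r2, N = N,
                 detection_limit = d, n_taxa = length(p),
                 n_samples = nrow(counts), boundary = boundary),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf(
    "Sloan NCM fit: m = %.4f (Nm = %.1f), R^2 = %.3f, %d taxa / %d samples%s\n",
    x$m, x$Nm, x$r_squared, x$n_taxa, x$n_samples,
    if (x$boundary) " [boundary: all taxa ubiquitous]" else ""))
  invisible(x)
}

#' Treatment effect on neutral-model migration rates
#'
#' Contrasts per-time-point migration rate estimates between two
#' treatments with a linear mixed model (random intercept per time
#' point). With a single shared time point a plain two-group comparison
#' is used, with a warning.
#'
#' @param fits data frame with columns \code{timepoint},
#'   \code{treatment}, \code{m} (e.g. assembled from \code{fit_ncm}
#'   results).
#' @param control reference treatment level; default first encountered.
#' @return an \code{"effect_size"} (\code{method = "lmm"}) for treated
#'   minus control migration rate.
#' @export
ncm_treatment_effect <- function(fits, control = NULL) {
  need <- c("timepoint", "treatment", "m")
  if (!all(need %in% names(fits)))
    stopf("fits needs columns: %s", paste(need, collapse = ", "))
  lv <- unique(fits$treatment)
  if (length(lv) != 2L) stopf("need exactly 2 treatments, got %d",
                              length(lv))
  control <- control %||% lv[1L]
  treat_lv <- setdiff(lv, control)
  dat <- data.frame(m = fits$m,
                    fx = factor(fits$treatment,
                                levels = c(control, treat_lv)),
                    tp = factor(fits$timepoint))
  contrast <- sprintf("%s vs %s (migration rate)", treat_lv, control)
  if (nlevels(dat$tp) < 2L) {
    warning("single time point: falling back to a two-group comparison",
            call. = FALSE)
    tt <- tryCatch(stats::t.test(m ~ fx, data = dat),
                   error = function(e) NULL)
    est <- mean(dat$m[dat$fx == treat_lv]) -
      mean(dat$m[dat$fx == control])
    return(new_effect_size("lmm", est,
                           p_value = if (is.null(tt)) NA_real_ else
                             tt$p.value,
                           contrast = contrast,
                           structure_used = "two-group fallback"))
  }
  fit <- tryCatch(
    nlme::lme(m ~ fx, random = ~1 | tp, data = dat, method = "REML",
              control = nlme::lmeControl(opt = "optim",
                                         returnObject = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sm <- summary(stats::lm(m ~ fx, data = dat))$coefficients
    return(new_effect_size("lmm", unname(sm[2L, 1L]), unname(sm[2L, 2L]),
                           unname(sm[2L, 4L]), contrast, "ols fallback"))
  }
  tt <- summary(fit)$tTable
  new_effect_size("lmm", unname(tt[2L, "Value"]),
                  unname(tt[2L, "Std.Error"]),
                  unname(tt[2L, "p-value"]), contrast,
                  "random intercept per timepoint")
}
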