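# Treatment and soil-texture effect sizes on moving-window exponents.

new_effect_size <- function(method, estimate, se = NA_real_,
                            p_value = NA_real_, contrast = NA_character_,
                            structure_used = NA_character_, extra = list()) {
  structure(c(list(method = method, estimate = estimate, se = se,
                   p_value = p_value, contrast = contrast,
                   structure_used = structure_used), extra),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Effect size (%s%s): %.4f", x$method,
              if (!is.na(x$structure_used))
                paste0(", ", x$structure_used) else "", x$estimate))
  if (!is.na(x$se)) cat(sprintf(" (se %.4f)", x$se))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$contrast)) cat(sprintf(" [%s]", x$contrast))
  cat("\n")
  invisible(x)
}

#' Linear mixed-model effect of a treatment on window-family exponents
#'
#' Estimates the fixed effect of a two-level contrast (e.g. bioenergy
#' cropping vs fallow, or clay loam vs sandy loam) on a moving-window
#' exponent family, with nested random intercepts over window size, site
#' and plot and -- where the data support it -- an AR(1) within-group
#' residual correlation indexed by the window start \code{ystart} to
#' absorb the temporal autocorrelation of overlapping windows. When the
#' AR(1) structure cannot be estimated (duplicated \code{ystart} within
#' the innermost grouping, or non-convergence) the model falls back to
#' nested random intercepts only, and as a last resort to ordinary least
#' squares; the structure actually used is recorded.
#'
#' @param family a \code{\link{fit_window_family}} result.
#' @param exponent which exponent to model: \code{"z"}, \code{"w"} or
#'   \code{"u"}.
#' @param response \code{"richness"} or \code{"pd"} rows of the family.
#' @param fixed name of the two-level grouping column (\code{"treatment"}
#'   or \code{"site"}).
#' @param control optional reference level of the contrast; default:
#'   first level encountered. The estimate is (other level) minus
#'   (control).
#' @param abs_value model the absolute exponent value (customary for the
#'   interaction term u, which is negative).
#' @param random_nesting character vector of grouping columns, outermost
#'   first; components with fewer than 2 levels in the data are dropped.
#' @param ar1 attempt the AR(1) residual correlation (default TRUE).
#' @return an \code{"effect_size"} with \code{method = "lmm"},
#'   the fixed-effect estimate, its standard error, p-value and the
#'   random/correlation structure actually fitted.
#' @export
lmm_effect_size <- function(family, exponent = c("w", "z", "u"),
                            response = c("richness", "pd"),
                            fixed = c("treatment", "site"),
                            control = NULL, abs_value = FALSE,
                            random_nesting = c("window_size", "site",
                                               "plot_id"),
                            ar1 = TRUE) {
  exponent <- match.arg(exponent); response <- match.arg(response)
  fixed <- match.arg(fixed)
  df <- as.data.frame(family)
  df <- df[df$response == response & df$ok, , drop = FALSE]
  if (nrow(df) == 0L) stopf("no usable fits in the window family")
  lv <- unique(df[[fixed]])
  if (length(lv) < 2L)
    stopf("fixed factor '%s' has a single level in the family", fixed)
  if (length(lv) > 2L)
    stopf("fixed factor '%s' must have exactly 2 levels", fixed)
  control <- control %||% lv[1L]
  if (!control %in% lv) stopf("control level '%s' not present", control)
  treat_lv <- setdiff(lv, control)

  y <- df[[exponent]]
  if (abs_value) y <- abs(y)
  dat <- data.frame(y = y,
                    fx = factor(df[[fixed]], levels = c(control, treat_lv)),
                    ystart = df$ystart)
  # drop nesting components without replication, keep hierarchy order
  random_nesting <- intersect(random_nesting,
                              names(df)[vapply(df, function(col)
                                length(unique(col)) >= 2L, TRUE)])
  random_nesting <- setdiff(random_nesting, fixed)
  for (g in random_nesting) dat[[g]] <- factor(df[[g]])

  contrast <- sprintf("%s vs %s (%s %s%s)", treat_lv, control, response,
                      exponent, if (abs_value) ", absolute" else "")

  extract_lme <- function(fit, label) {
    tt <- summary(fit)$tTable
    new_effect_size("lmm", unname(tt[2L, "Value"]),
                    unname(tt[2L, "Std.Error"]),
                    unname(tt[2L, "p-value"]), contrast, label)
  }

  if (length(random_nesting)) {
    rf <- stats::as.formula(paste0("~1|",
                                   paste(random_nesting, collapse = "/")))
    ctrl <- nlme::lmeControl(opt = "optim", maxIter = 200L,
                             msMaxIter = 200L, returnObject = TRUE)
    if (ar1) {
      cs <- nlme::corAR1(form = stats::as.formula(
        paste0("~ystart|", paste(random_nesting, collapse = "/"))))
      fit <- tryCatch(
        nlme::lme(y ~ fx, random = rf, correlation = cs, data = dat,
                  method = "REML", control = ctrl),
        error = function(e) NULL)
      if (!is.null(fit))
        return(extract_lme(fit, "random intercepts + AR(1)"))
    }
    fit <- tryCatch(
      nlme::lme(y ~ fx, random = rf, data = dat, method = "REML",
                control = nlme::lmeControl(opt = "optim",
                                           returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit))
      return(extract_lme(fit, "random intercepts"))
  }
  fit <- stats::lm(y ~ fx, data = dat)
  sm <- summary(fit)$coefficients
  new_effect_size("lmm", unname(sm[2L, 1L]), unname(sm[2L, 2L]),
                  unname(sm[2L, 4L]), contrast,
                  "ols fallback")
}

#' Log response ratio of a treatment
#'
#' \eqn{lnRR = \ln(\bar{x}_{treat} / \bar{x}_{control})} with the
#' standard delta-method variance
#' \eqn{s_t^2/(n_t \bar{x}_t^2) + s_c^2/(n_c \bar{x}_c^2)}. Both group
#' means must be positive.
#'
#' @param treat,control numeric vectors of group values.
#' @return an \code{"effect_size"} with \code{method = "lnRR"},
#'   estimate, standard error, normal-approximation p-value and
#'   \code{variance}.
#' @export
ln_response_ratio <- function(treat, control) {
  mt <- mean(treat); mc <- mean(control)
  if (mt <= 0 || mc <= 0) stopf("both group means must be positive")
  est <- log(mt / mc)
  v <- stats::var(treat) / (length(treat) * mt^2) +
    stats::var(control) / (length(control) * mc^2)
  if (is.na(v)) v <- NA_real_
  se <- sqrt(v)
  p <- if (!is.na(se) && se > 0) 2 * stats::pnorm(-abs(est) / se) else
    NA_real_
  new_effect_size("lnRR", est, se, p, "treat vs control",
                  extra = list(variance = v))
}

#' Cohen's d standardized mean difference
#'
#' \eqn{d = (\bar{x}_a - \bar{x}_b) / s_{pooled}} with the pooled sample
#' standard deviation. Each group needs at least two observations and
#' the pooled sd must be positive.
#'
#' @param group_a,group_b numeric vectors.
#' @return an \code{"effect_size"} with \code{method = "cohens_d"} and a
#'   Welch t-test p-value where computable.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stopf("each group needs at least 2 observations")
  sp <- sqrt(((na - 1) * stats::var(group_a) +
                (nb - 1) * stats::var(group_b)) / (na + nb - 2))
  if (sp == 0) stopf("zero pooled standard deviation")
  d <- (mean(group_a) - mean(group_b)) / sp
  p <- tryCatch(stats::t.test(group_a, group_b)$p.value,
                error = function(e) NA_real_)
  new_effect_size("cohens_d", d, p_value = p, contrast = "a vs b")
}

#' Spearman correlations with FDR adjustment
#'
#' Rank correlation between every column pair of a scaling-rate table and
#' a heterogeneity table (rows paired, e.g. by bacterial phylum), with
#' Benjamini-Hochberg adjustment across the whole family of tests.
#' Constant vectors yield a flagged record with undefined rho.
#'
#' @param rates data frame / matrix of scaling rates (one column per
#'   exponent).
#' @param heterogeneity data frame / matrix of heterogeneity measures
#'   (one column per property), same row order.
#' @return data frame with columns \code{rate}, \code{property},
#'   \code{n}, \code{rho}, \code{p_value}, \code{p_adjusted},
#'   \code{degenerate}.
#' @export
spearman_fdr <- function(rates, heterogeneity) {
  rates <- as.data.frame(rates)
  heterogeneity <- as.data.frame(heterogeneity)
  if (nrow(rates) != nrow(heterogeneity))
    stopf("tables must have the same number of rows")
  if (nrow(rates) < 4L) stopf("need at least 4 paired observations")
  grid <- expand.grid(rate = names(rates),
                      property = names(heterogeneity),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- rates[[grid$rate[i]]]; y <- heterogeneity[[grid$property[i]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(rate = grid$rate[i],
                        property = grid$property[i], n = length(x),
                        rho = NA_real_, p_value = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(rate = grid$rate[i], property = grid$property[i],
               n = length(x), rho = unname(ct$estimate),
               p_value = ct$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("rate", "property", "n", "rho", "p_value", "p_adjusted",
          "degenerate")]
}
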