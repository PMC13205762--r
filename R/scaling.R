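#' Fit a single-variable diversity power law (SAR / PAR / STR / PTR)
#'
#' Ordinary least squares of log diversity on log area or log time:
#' \eqn{\ln S = z \ln A + b} (species/phylogenetic-area relationship) or
#' \eqn{\ln S = w \ln T + b} (species/phylogenetic-time relationship).
#' The slope is the spatial or temporal scaling rate of richness or
#' Faith's PD. Natural logarithms throughout.
#'
#' @param surface an \code{accumulation_surface} (or data frame with
#'   \code{area_m2} / \code{time_months} and the response column).
#' @param predictor \code{"area"} or \code{"time"}.
#' @param response \code{"richness"} or \code{"pd"}.
#' @return an object of class \code{"power_law_fit"}: list with
#'   \code{model} (\code{"SAR"}, \code{"PAR"}, \code{"STR"} or
#'   \code{"PTR"}), \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n_points}, \code{degenerate} flag.
#' @export
fit_power_law <- function(surface, predictor = c("area", "time"),
                          response = c("richness", "pd")) {
  predictor <- match.arg(predictor); response <- match.arg(response)
  pcol <- if (predictor == "area") "area_m2" else "time_months"
  if (!response %in% names(surface))
    stopf("surface has no '%s' column", response)
  x <- surface[[pcol]]; y <- surface[[response]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stopf("need at least 2 rows with data")
  if (any(x <= 0) || any(y <= 0))
    stopf("power-law fitting needs strictly positive %s and %s",
          pcol, response)
  lx <- log(x); ly <- log(y)
  if (stats::var(lx) == 0)
    stopf("degenerate design: predictor '%s' has no variance", predictor)
  model <- if (predictor == "area") {
    if (response == "richness") "SAR" else "PAR"
  } else {
    if (response == "richness") "STR" else "PTR"
  }
  degenerate <- stats::var(ly) == 0
  if (degenerate) {
    fit <- list(slope = 0, intercept = mean(ly), r2 = 0)
  } else {
    lmfit <- stats::lm(ly ~ lx)
    fit <- list(slope = unname(stats::coef(lmfit)[2L]),
                intercept = unname(stats::coef(lmfit)[1L]),
                r2 = summary(lmfit)$r.squared)
  }
  structure(list(model = model, predictor = predictor,
                 response = response, slope = fit$slope,
                 intercept = fit$intercept, r_squared = fit$r2,
                 n_points = length(x), degenerate = degenerate),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("%s fit: slope = %.4f, intercept = %.4f, R^2 = %.3f (n = %d%s)\n",
              x$model, x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Fit the interaction species/phylogenetic-time-area model (STAR / PTAR)
#'
#' Ordinary least squares of the generalized power law
#' \deqn{\ln S = z \ln A + w \ln T + u \ln A \ln T + b,}
#' where \eqn{z} is the spatial scaling rate over one time unit, \eqn{w}
#' the temporal scaling rate at one area unit, and \eqn{u} the time-space
#' interaction (negative when scaling rates decay with the other
#' dimension). Fitting is done in the surface's native units (m\eqn{^2},
#' months); use \code{\link{rescale_units}} to report in other units.
#'
#' @inheritParams fit_power_law
#' @return an object of class \code{"star_fit"}: list with \code{response},
#'   \code{z}, \code{w}, \code{u}, \code{b}, \code{r_squared}, \code{n},
#'   \code{area_unit}, \code{time_unit}.
#' @export
fit_star <- function(surface, response = c("richness", "pd")) {
  response <- match.arg(response)
  if (!response %in% names(surface))
    stopf("surface has no '%s' column", response)
  ok <- stats::complete.cases(surface$area_m2, surface$time_months,
                              surface[[response]])
  A <- surface$area_m2[ok]; Tm <- surface$time_months[ok]
  y <- surface[[response]][ok]
  if (length(y) < 5L) stopf("need at least 5 rows to fit the model")
  if (any(A <= 0) || any(Tm <= 0) || any(y <= 0))
    stopf("model requires strictly positive area, time and %s", response)
  if (length(unique(A)) < 2L || length(unique(Tm)) < 2L)
    stopf("rank-deficient design: need >= 2 distinct areas and times")
  la <- log(A); lt <- log(Tm); ly <- log(y)
  X <- cbind(1, la, lt, la * lt)
  qx <- qr(X)
  if (qx$rank < 4L)
    stopf("rank-deficient design for the interaction model")
  beta <- qr.coef(qx, ly)
  res <- ly - X %*% beta
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  structure(list(response = response, z = unname(beta[2L]),
                 w = unname(beta[3L]), u = unname(beta[4L]),
                 b = unname(beta[1L]), r_squared = r2, n = length(y),
                 area_unit = "m2", time_unit = "month"),
            class = "star_fit")
}

#' @export
print.star_fit <- function(x, ...) {
  lab <- if (x$response == "richness") "STAR" else "PTAR"
  cat(sprintf(
    "%s fit (%s, %s): z = %.4f, w = %.4f, u = %.5f, b = %.4f, R^2 = %.4f (n = %d)\n",
    lab, x$area_unit, x$time_unit, x$z, x$w, x$u, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Time-space equivalence ratio
#'
#' The area at which the temporal scaling rate equals the spatial scaling
#' rate over one time unit: \eqn{A/T = \exp((z - w)/u)}, in the fit's
#' current units (e.g. m\eqn{^2} per month). A ratio of 4 m\eqn{^2}/month
#' means the diversity accumulated in one month matches that gained by
#' enlarging the sampled area to 4 m\eqn{^2}. Undefined at \eqn{u = 0}.
#'
#' @param fit a \code{star_fit}.
#' @param tol warn when \eqn{|u|} is below this tolerance (near-undefined
#'   ratio).
#' @return object of class \code{"equivalence_ratio"}: list with
#'   \code{value}, \code{basis} (\code{richness}/\code{pd}),
#'   \code{area_unit}, \code{time_unit}.
#' @export
equivalence_ratio <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "star_fit"))
  if (fit$u == 0)
    stopf("equivalence ratio undefined: interaction term u is 0")
  if (abs(fit$u) < tol)
    warning("interaction term |u| < tol; equivalence ratio is unstable",
            call. = FALSE)
  structure(list(value = exp((fit$z - fit$w) / fit$u),
                 basis = fit$response, area_unit = fit$area_unit,
                 time_unit = fit$time_unit),
            class = "equivalence_ratio")
}

#' @export
print.equivalence_ratio <- function(x, ...) {
  cat(sprintf("Time-space equivalence ratio (%s): %.4g %s/%s\n",
              x$basis, x$value, x$area_unit, x$time_unit))
  invisible(x)
}

#' Convert a fitted interaction model to new area/time units
#'
#' Because of the interaction term, exponents of the model are
#' scale-dependent, so changing units is not a matter of relabelling.
#' With \code{area_factor} \eqn{a} old area units per new unit (m\eqn{^2}
#' per km\eqn{^2} = 1e6) and \code{time_factor} \eqn{t} likewise
#' (months per year = 12), substituting
#' \eqn{\ln A_{old} = \ln a + \ln A_{new}} gives
#' \deqn{z' = z + u \ln t, \quad w' = w + u \ln a, \quad u' = u,}
#' \deqn{b' = b + z \ln a + w \ln t + u \ln a \ln t,}
#' and the equivalence ratio transforms exactly as
#' \eqn{ratio' = ratio \cdot t / a}.
#'
#' @param fit a \code{star_fit}.
#' @param area_factor,time_factor positive conversion factors (old units
#'   per new unit).
#' @param area_unit,time_unit labels for the new units.
#' @return a \code{star_fit} expressed in the new units.
#' @examples
#' # m^2/month fit reported in km^2/yr:
#' # rescale_units(fit, 1e6, 12, "km2", "yr")
#' @export
rescale_units <- function(fit, area_factor, time_factor,
                          area_unit = NULL, time_unit = NULL) {
  stopifnot(inherits(fit, "star_fit"))
  if (area_factor <= 0 || time_factor <= 0)
    stopf("conversion factors must be positive")
  la <- log(area_factor); lt <- log(time_factor)
  out <- fit
  out$z <- fit$z + fit$u * lt
  out$w <- fit$w + fit$u * la
  out$u <- fit$u
  out$b <- fit$b + fit$z * la + fit$w * lt + fit$u * la * lt
  out$area_unit <- area_unit %||%
    (if (area_factor == 1) fit$area_unit else
       sprintf("%s x %g", fit$area_unit, area_factor))
  out$time_unit <- time_unit %||%
    (if (time_factor == 1) fit$time_unit else
       sprintf("%s x %g", fit$time_unit, time_factor))
  out
}
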