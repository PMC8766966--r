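#' Assemble calibration points
#'
#' @param nominal nominal concentrations (ng/ml), all > 0.
#' @param response instrument responses (peak area or analyte/IS area ratio),
#'   all >= 0.
#' @param weight optional explicit weights; by default derived from the
#'   weighting scheme at fit time.
#' @return a tibble of class `calibration_points`.
#' @export
calibration_points <- function(nominal, response, weight = NULL) {
  if (length(nominal) != length(response))
    stop_tdm("tdm_invalid_points", "nominal and response must have equal length")
  if (any(!is.finite(nominal)) || any(nominal <= 0))
    stop_tdm("tdm_invalid_points", "nominal concentrations must be positive and finite")
  if (any(!is.finite(response)) || any(response < 0))
    stop_tdm("tdm_invalid_points", "responses must be non-negative and finite")
  if (!is.null(weight) && (length(weight) != length(nominal) || any(weight <= 0)))
    stop_tdm("tdm_invalid_points", "weights must be positive and match the points")
  out <- tibble::tibble(nominal = as.numeric(nominal),
                        response = as.numeric(response),
                        weight = if (is.null(weight)) NA_real_ else as.numeric(weight))
  class(out) <- c("calibration_points", class(out))
  out
}

calib_weights <- function(nominal, weighting) {
  switch(weighting,
         "1/x"  = 1 / nominal,
         "1/x2" = 1 / nominal^2,
         "none" = rep(1, length(nominal)),
         stop_tdm("tdm_invalid_design", sprintf("unknown weighting scheme '%s'", weighting)))
}

#' Fit a weighted quadratic calibration curve through the origin
#'
#' The instrument response is modelled as `y(c) = a*c + b*c^2` with zero
#' intercept, fitted by weighted least squares. The default weighting `1/x`
#' down-weights high standards so that relative accuracy is preserved at the
#' bottom of the dyadic range, where responses are several hundred-fold
#' smaller than at the top. The coefficients solve the 2x2 weighted normal
#' equations in closed form, so the fit is deterministic.
#'
#' An accepted curve must be monotone increasing over `[0, uloq]`
#' (`a + 2*b*uloq > 0`); mild negative curvature from detector saturation and
#' positive curvature from ionization enhancement are both admissible, but a
#' curve that turns over inside the calibration range is rejected because its
#' inverse would be ambiguous.
#'
#' @param points a [calibration_points()] tibble (or data frame with columns
#'   `nominal` and `response`).
#' @param weighting `"1/x"` (default), `"1/x2"` or `"none"`; ignored for
#'   points carrying explicit weights.
#' @param analyte optional analyte code stored on the curve.
#' @param lod optional empirical limit of detection (ng/ml), used by
#'   [inverse_predict()] to qualify sub-LLOQ results.
#' @param range optional `c(lloq, uloq)`; defaults to the span of the nominals.
#' @return an object of class `tdm_curve` with elements `a`, `b`, `r2`,
#'   `lloq`, `uloq`, `lod`, `weighting`, `points`.
#' @export
fit_calibration <- function(points, weighting = c("1/x", "1/x2", "none"),
                            analyte = NA_character_, lod = NA_real_,
                            range = NULL) {
  weighting <- match.arg(weighting)
  if (!all(c("nominal", "response") %in% names(points)))
    stop_tdm("tdm_invalid_points", "points must have columns 'nominal' and 'response'")
  c_ <- as.numeric(points$nominal)
  y <- as.numeric(points$response)
  if (length(unique(c_)) < 3L)
    stop_tdm("tdm_underdetermined",
             "at least 3 distinct nominal concentrations are required for a quadratic fit")
  w <- points$weight
  if (is.null(w) || all(is.na(w))) w <- calib_weights(c_, weighting)
  if (any(!is.finite(w)) || any(w <= 0))
    stop_tdm("tdm_invalid_points", "weights must be positive and finite")

  # Normal equations for y ~ a*c + b*c^2 under weights w:
  #   [ S(w c^2)  S(w c^3) ] [a]   [ S(w c y)   ]
  #   [ S(w c^3)  S(w c^4) ] [b] = [ S(w c^2 y) ]
  s22 <- sum(w * c_^2); s23 <- sum(w * c_^3); s24 <- sum(w * c_^4)
  t1 <- sum(w * c_ * y); t2 <- sum(w * c_^2 * y)
  coefs <- solve(matrix(c(s22, s23, s23, s24), 2L, 2L), c(t1, t2))
  a <- coefs[[1L]]; b <- coefs[[2L]]

  rng <- if (is.null(range)) c(min(c_), max(c_)) else as.numeric(range)
  uloq <- rng[[2L]]
  if (a + 2 * b * uloq <= 0 || a <= 0)
    stop_tdm("tdm_rejected_curve",
             sprintf("fitted curve is not monotone increasing on [0, %.4g] (a = %.4g, b = %.4g)",
                     uloq, a, b))

  fitted <- a * c_ + b * c_^2
  r2 <- weighted_r_squared(y, fitted, w)
  structure(
    list(analyte = analyte, a = a, b = b, r2 = r2,
         lloq = rng[[1L]], uloq = uloq, lod = lod,
         weighting = weighting,
         points = tibble::tibble(nominal = c_, response = y, weight = w,
                                 fitted = fitted)),
    class = "tdm_curve"
  )
}

# Weighted coefficient of determination about the weighted mean response.
# A negative value flags a pathological fit and is reported as-is.
weighted_r_squared <- function(y, fitted, w) {
  ybar <- sum(w * y) / sum(w)
  sstot <- sum(w * (y - ybar)^2)
  if (sstot <= 0)
    stop_tdm("tdm_undefined_r2", "zero weighted variance of responses; r2 is undefined")
  r2 <- 1 - sum(w * (y - fitted)^2) / sstot
  if (r2 < 0)
    warn_tdm("tdm_negative_r2", sprintf("negative weighted r2 (%.4g): pathological fit", r2))
  r2
}

#' Weighted r-squared of a fitted calibration curve
#'
#' Recomputes `1 - SSres_w / SStot_w` with the total sum of squares taken
#' about the weighted mean response (the standard weighted-least-squares
#' definition; the uncentered variant is not used because it inflates the
#' statistic for through-origin fits).
#'
#' @param curve a `tdm_curve`.
#' @param points optional points (defaults to the points the curve was fit on).
#' @return the weighted coefficient of determination; negative values are
#'   returned as-is with a warning.
#' @export
r_squared <- function(curve, points = NULL) {
  stopifnot(inherits(curve, "tdm_curve"))
  if (is.null(points)) points <- curve$points
  c_ <- points$nominal
  w <- points$weight
  if (is.null(w) || all(is.na(w))) w <- calib_weights(c_, curve$weighting)
  weighted_r_squared(points$response, curve$a * c_ + curve$b * c_^2, w)
}

#' @export
print.tdm_curve <- function(x, ...) {
  cat(sprintf("<tdm_curve> %s: y = %.6g*c %+.6g*c^2 (through origin, w = %s)\n",
              ifelse(is.na(x$analyte), "<unnamed>", x$analyte), x$a, x$b, x$weighting))
  cat(sprintf("  r2 = %.6f over [%.4g, %.4g] ng/ml (%d points)\n",
              x$r2, x$lloq, x$uloq, nrow(x$points)))
  invisible(x)
}

#' Plot a calibration curve with its points
#'
#' @param x a `tdm_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tdm_curve <- function(x, ...) {
  cc <- seq(0, x$uloq, length.out = 200)
  graphics::plot(x$points$nominal, x$points$response, log = "",
                 xlab = "nominal (ng/ml)", ylab = "response",
                 main = sprintf("%s calibration (r2 = %.4f)",
                                ifelse(is.na(x$analyte), "", x$analyte), x$r2), ...)
  graphics::lines(cc, x$a * cc + x$b * cc^2, col = "steelblue")
  invisible(x)
}

#' Invert a calibration curve
#'
#' Solves `b*c^2 + a*c - y = 0` for the concentration on the monotone branch,
#' using the numerically stable root `2*y / (a + sqrt(a^2 + 4*b*y))`, which
#' degrades gracefully to `y/a` as `b -> 0`. Each result carries a qualifier:
#' `below_lod`, `below_lloq` (detected but with quantification error risk
#' above 20%), `above_uloq`, or `quantified`.
#'
#' @param curve a `tdm_curve`.
#' @param response numeric vector of responses, all >= 0.
#' @param lod limit of detection used for qualification; defaults to the
#'   curve's stored LOD (results below the LLOQ are then `below_lloq` when no
#'   LOD is known).
#' @return a tibble with columns `response`, `conc`, `qualifier`.
#' @export
inverse_predict <- function(curve, response, lod = curve$lod) {
  stopifnot(inherits(curve, "tdm_curve"))
  y <- as.numeric(response)
  if (any(!is.finite(y)) || any(y < 0))
    stop_tdm("tdm_invalid_response", "responses must be non-negative and finite")
  a <- curve$a; b <- curve$b
  conc <- if (abs(b) < 1e-12 * abs(a)) {
    y / a
  } else {
    disc <- a^2 + 4 * b * y
    if (any(disc < 0))
      stop_tdm("tdm_out_of_model",
               "response exceeds the apex of the saturating calibration curve")
    2 * y / (a + sqrt(disc))
  }
  if (any(conc < 0 - 1e-12) || any(conc > 2 * curve$uloq))
    stop_tdm("tdm_out_of_model",
             sprintf("no admissible root in [0, %.4g] for some response", 2 * curve$uloq))
  qualifier <- rep("quantified", length(conc))
  qualifier[conc > curve$uloq] <- "above_uloq"
  qualifier[conc < curve$lloq] <- "below_lloq"
  if (!is.na(lod)) qualifier[conc < lod] <- "below_lod"
  tibble::tibble(response = y, conc = conc, qualifier = qualifier)
}

#' Back-calculate calibration points and their deviation from nominal
#'
#' Runs every point through [inverse_predict()] and reports the percent
#' deviation `100 * (back - nominal) / nominal`, the per-level accuracy
#' measure used to accept a calibration level (within 15%, or 20% at the
#' LLOQ).
#'
#' @param curve a `tdm_curve`.
#' @param points optional points (defaults to the fit points).
#' @return a tibble with columns `nominal`, `response`, `conc`, `qualifier`,
#'   `deviation_pct`.
#' @export
back_calculate <- function(curve, points = NULL) {
  stopifnot(inherits(curve, "tdm_curve"))
  if (is.null(points)) points <- curve$points
  inv <- inverse_predict(curve, points$response)
  tibble::tibble(nominal = points$nominal,
                 response = points$response,
                 conc = inv$conc,
                 qualifier = inv$qualifier,
                 deviation_pct = 100 * (inv$conc - points$nominal) / points$nominal)
}

#' Serialize a fitted curve to a JSON-ready record
#'
#' @param curve a `tdm_curve`.
#' @param response_mode `"is_ratio"` or `"area"`, recorded for provenance.
#' @return a named list with full-precision coefficients.
#' @export
curve_record <- function(curve, response_mode = "is_ratio") {
  stopifnot(inherits(curve, "tdm_curve"))
  list(analyte = curve$analyte, a = curve$a, b = curve$b, r2 = curve$r2,
       lloq = curve$lloq, uloq = curve$uloq,
       weighting = curve$weighting, response_mode = response_mode)
}
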