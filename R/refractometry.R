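#' Calibrate the linear refractive-index composition model
#'
#' For dilute aqueous polymer + salt solutions the refractive index is
#' linear in both mass fractions,
#' `n_D = n0 + a_p * w_p + a_s * w_s`,
#' with `n0` the refractive index of pure water (1.3325 at 298.15 K). The
#' two coefficients are calibrated from single-solute dilution series by
#' through-origin least squares of `(n_D - n0)` on `w`: the model fixes the
#' intercept at `n0`, which is measured separately, so it is not a free
#' parameter of the regression.
#'
#' Mass fractions here are on the fractional (0-1) scale: the calibration
#' range of a dilution series is a few percent at most, and the
#' coefficients are conventionally quoted per unit mass fraction.
#'
#' @param series_p Data frame (or list) with columns/elements `w` (polymer
#'   mass fraction, 0-1) and `n_d` (refractive index); at least 2 points.
#' @param series_s Same, for the salt dilution series.
#' @param n0 Refractive index of pure water; default 1.3325.
#' @return An object of class `"refracto_cal"`: list with coefficients
#'   `a_p`, `a_s`, `n0`, per-series `r_squared_p`, `r_squared_s`
#'   (through-origin coefficient of determination), and calibrated ranges
#'   `valid_range_p`, `valid_range_s` (the span of the calibration `w`).
#' @seealso [invert_to_polymer_fraction()], [predict.refracto_cal()]
#' @export
calibrate_refractometry <- function(series_p, series_s, n0 = 1.3325) {
  fit1 <- function(series, what) {
    w <- as.numeric(series$w); nd <- as.numeric(series$n_d)
    if (length(w) < 2L || length(w) != length(nd))
      stop("calibration series for ", what, " needs >= 2 (w, n_d) pairs")
    if (diff(range(w)) == 0)
      stop("degenerate ", what, " calibration series: all w equal")
    y <- nd - n0
    a <- sum(w * y) / sum(w * w)        # through-origin OLS
    ss_res <- sum((y - a * w)^2)
    ss_tot <- sum(y^2)                  # uncentered: intercept is fixed
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    list(a = a, r2 = max(0, min(1, r2)), range = range(w))
  }
  p <- fit1(series_p, "polymer"); s <- fit1(series_s, "salt")
  structure(list(n0 = n0, a_p = p$a, a_s = s$a,
                 r_squared_p = p$r2, r_squared_s = s$r2,
                 valid_range_p = p$range, valid_range_s = s$range),
            class = "refracto_cal")
}

#' @export
print.refracto_cal <- function(x, ...) {
  cat("Refractometric calibration: n_D = n0 + a_p*w_p + a_s*w_s\n")
  cat(sprintf("  n0  = %.4f\n", x$n0))
  cat(sprintf("  a_p = %.5g  (r^2 = %.4f, w in [%.4g, %.4g])\n",
              x$a_p, x$r_squared_p, x$valid_range_p[1], x$valid_range_p[2]))
  cat(sprintf("  a_s = %.5g  (r^2 = %.4f, w in [%.4g, %.4g])\n",
              x$a_s, x$r_squared_s, x$valid_range_s[1], x$valid_range_s[2]))
  invisible(x)
}

#' Forward refractive-index model
#'
#' @param object A `"refracto_cal"`.
#' @param w_p,w_s Mass fractions (0-1); vectorised.
#' @param ... Unused.
#' @return Predicted refractive index `n0 + a_p*w_p + a_s*w_s`.
#' @export
predict.refracto_cal <- function(object, w_p, w_s = 0, ...) {
  object$n0 + object$a_p * w_p + object$a_s * w_s
}

#' Invert a refractive-index reading to the polymer mass fraction
#'
#' Given a measured refractive index and the salt mass fraction from an
#' independent assay (e.g. flame photometry), solves the linear model for
#' the polymer content: `w_p = (n_d - n0 - a_s * w_s) / a_p`.
#'
#' Readings whose implied `w_p` (or supplied `w_s`) fall outside the
#' calibrated dilution range only warn, since equilibrium-phase samples are
#' routinely diluted before measurement; pass the applied `dilution_factor`
#' to have the returned value refer to the undiluted sample.
#'
#' @param n_d Measured refractive index (> 1); vectorised.
#' @param w_s_known Salt mass fraction (0-1) in the *measured* (diluted)
#'   sample.
#' @param cal A `"refracto_cal"` from [calibrate_refractometry()].
#' @param dilution_factor Mass dilution factor applied before measurement
#'   (>= 1); the returned `w_p` is multiplied by it. Default 1.
#' @param negative_tolerance Small negative `w_p` (>= -tolerance) is
#'   tolerated with a warning as measurement noise around zero; anything
#'   more negative is an error. Default 0.005 (0.5 wt%).
#' @return Polymer mass fraction (0-1 scale), rescaled by
#'   `dilution_factor`.
#' @examples
#' cal <- calibrate_refractometry(
#'   data.frame(w = c(0.01, 0.03, 0.05), n_d = 1.3325 + 0.14 * c(0.01, 0.03, 0.05)),
#'   data.frame(w = c(0.01, 0.03, 0.05), n_d = 1.3325 + 0.12 * c(0.01, 0.03, 0.05)))
#' invert_to_polymer_fraction(1.3325, 0, cal)   # pure water -> 0
#' @export
invert_to_polymer_fraction <- function(n_d, w_s_known, cal,
                                       dilution_factor = 1,
                                       negative_tolerance = 0.005) {
  stopifnot(inherits(cal, "refracto_cal"))
  if (!is.finite(cal$a_p) || cal$a_p == 0)
    stop("calibration has a_p = 0: refractive index carries no polymer signal")
  if (any(n_d <= 1))
    stop("refractive index must exceed 1")
  if (any(dilution_factor < 1))
    stop("dilution_factor must be >= 1")
  w_p <- (n_d - cal$n0 - cal$a_s * w_s_known) / cal$a_p
  if (any(w_p < -negative_tolerance))
    stop(sprintf("inverted polymer fraction %.4g is negative beyond tolerance %.3g",
                 min(w_p), negative_tolerance))
  if (any(w_p < 0))
    warning("small negative inverted polymer fraction (measurement noise around zero)")
  # exact zeros are exempt: the model has no free intercept, so it is
  # exact at w = 0 whatever the calibrated span
  out_p <- any(w_p != 0 & (w_p < cal$valid_range_p[1] - 1e-12 |
                             w_p > cal$valid_range_p[2] + 1e-12))
  out_s <- any(w_s_known != 0 & (w_s_known < cal$valid_range_s[1] - 1e-12 |
                                   w_s_known > cal$valid_range_s[2] + 1e-12))
  if (out_p || out_s)
    warning("reading outside the calibrated mass-fraction range; ",
            "extrapolating the linear model")
  w_p * dilution_factor
}

#' Read a calibration series CSV
#'
#' Expected columns: `component`, `w_mass_fraction`, `n_d`. Rows are split
#' by `component` into named series ready for
#' [calibrate_refractometry()].
#'
#' @param path CSV path.
#' @return Named list of data frames with columns `w`, `n_d`.
#' @export
read_calibration_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("component", "w_mass_fraction", "n_d")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$component),
         function(d) data.frame(w = d$w_mass_fraction, n_d = d$n_d))
}

#' Serialise a calibration to JSON
#'
#' @param cal A `"refracto_cal"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "refracto_cal"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
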