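#' Tie-line tables
#'
#' A tie-line records the overall mixture composition and the two
#' coexisting equilibrium phase compositions of an ATPS. The package
#' stores tie-lines as a data frame of class `"tielines"` with columns
#' `overall_ws`, `overall_wp`, `top_ws`, `top_wp`, `bot_ws`, `bot_wp`
#' (all wt%) plus the derived `tll` column. Water fractions are taken by
#' difference (`100 - w_p - w_s`), the convention of tie-line tables that
#' omit the water column.
#'
#' The phase-labelling convention is that the *top* phase is polymer-rich
#' (`top_wp > bot_wp`) and the *bottom* phase salt-rich
#' (`bot_ws > top_ws`). Rows violating it are swapped with a warning when
#' `fix_labels = TRUE`, so column-order mistakes in input files do not
#' silently corrupt the correlations.
#'
#' @param x Data frame with the six composition columns above (a `tll`
#'   column, if present, is recomputed).
#' @param tolerance Closure tolerance in wt% passed to the per-phase
#'   composition validation.
#' @param fix_labels Swap mislabelled phases (with a warning) instead of
#'   erroring.
#' @return A `"tielines"` data frame with a recomputed `tll` column.
#' @examples
#' as_tielines(data.frame(overall_ws = 17.58, overall_wp = 28.98,
#'                        top_ws = 9.44, top_wp = 61.42,
#'                        bot_ws = 22.43, bot_wp = 10.47))
#' @export
as_tielines <- function(x, tolerance = 0.5, fix_labels = TRUE) {
  df <- as.data.frame(x)
  need <- c("overall_ws", "overall_wp", "top_ws", "top_wp", "bot_ws", "bot_wp")
  if (!all(need %in% names(df)))
    stop("tie-line table needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("tie-line table is empty")
  df <- df[, need]
  if (anyNA(df)) stop("tie-line table contains missing values")
  for (ph in c("overall", "top", "bot")) {
    wp <- df[[paste0(ph, "_wp")]]; ws <- df[[paste0(ph, "_ws")]]
    for (i in seq_along(wp))
      validate_composition(c(wp[i], ws[i], 100 - wp[i] - ws[i]),
                           tolerance = tolerance)
  }
  bad <- df$top_wp <= df$bot_wp | df$bot_ws <= df$top_ws
  if (any(bad)) {
    if (!fix_labels)
      stop("phase-labelling convention violated (top must be polymer-rich) in row(s) ",
           paste(which(bad), collapse = ", "))
    warning("swapping mislabelled phases in row(s) ",
            paste(which(bad), collapse = ", "),
            ": top phase must be polymer-rich")
    tmp <- df[bad, c("top_ws", "top_wp")]
    df[bad, c("top_ws", "top_wp")] <- df[bad, c("bot_ws", "bot_wp")]
    df[bad, c("bot_ws", "bot_wp")] <- tmp
    still <- df$top_wp <= df$bot_wp | df$bot_ws <= df$top_ws
    if (any(still))
      stop("phase-labelling convention cannot be satisfied in row(s) ",
           paste(which(still), collapse = ", "))
  }
  df$tll <- tll(df)
  class(df) <- c("tielines", "data.frame")
  df
}

#' Construct a single tie-line
#'
#' @param overall,top,bottom Length-2 numeric vectors `(w_s, w_p)` in wt%,
#'   or [composition()] objects.
#' @param ... Passed to [as_tielines()].
#' @return A one-row `"tielines"` data frame.
#' @export
tieline <- function(overall, top, bottom, ...) {
  grab <- function(x) {
    if (inherits(x, "composition")) c(x[["w_s"]], x[["w_p"]])
    else c(x[[1]], x[[2]])
  }
  o <- grab(overall); t <- grab(top); b <- grab(bottom)
  as_tielines(data.frame(overall_ws = o[1], overall_wp = o[2],
                         top_ws = t[1], top_wp = t[2],
                         bot_ws = b[1], bot_wp = b[2]), ...)
}

#' Tie-line length
#'
#' The Euclidean distance between the two phase compositions in the
#' (salt, polymer) wt% plane:
#' `TLL = sqrt((w_p_top - w_p_bot)^2 + (w_s_top - w_s_bot)^2)`.
#' It has wt% units and measures how dissimilar the coexisting phases are;
#' it grows with overall composition depth into the two-phase region.
#'
#' @param x A `"tielines"` data frame (or any data frame with `top_ws`,
#'   `top_wp`, `bot_ws`, `bot_wp` columns).
#' @return Numeric vector of tie-line lengths in wt%.
#' @examples
#' tl <- tieline(c(17.58, 28.98), c(9.44, 61.42), c(22.43, 10.47))
#' tll(tl)  # 52.58
#' @export
tll <- function(x) {
  sqrt((x$top_wp - x$bot_wp)^2 + (x$top_ws - x$bot_ws)^2)
}

#' Lever-rule consistency of overall compositions
#'
#' Mass balance requires the overall mixture composition to lie on the
#' segment joining the two phase compositions, with the top-phase mass
#' fraction `phi` satisfying `overall = phi * top + (1 - phi) * bottom`
#' component-wise. This check computes `phi` independently from the salt
#' and the polymer coordinate, their spread, and the perpendicular
#' distance of the overall point from the tie-line segment; a tie-line
#' passes when that distance is within `tolerance`.
#'
#' @param x A `"tielines"` data frame.
#' @param tolerance Maximum allowed distance (wt%) of the overall point
#'   from the segment; default 0.5.
#' @return A data frame of class `"lever_rule_report"` with columns
#'   `phase_fraction_top` (salt/polymer average), `fraction_salt`,
#'   `fraction_polymer`, `fraction_spread`, `max_deviation` (wt%), and
#'   logical `pass`.
#' @export
lever_rule_check <- function(x, tolerance = 0.5) {
  if (any(tll(x) == 0))
    stop("degenerate tie-line (TLL = 0): lever rule undefined")
  fs <- (x$overall_ws - x$bot_ws) / (x$top_ws - x$bot_ws)
  fp <- (x$overall_wp - x$bot_wp) / (x$top_wp - x$bot_wp)
  # perpendicular distance of overall point from the segment [bottom, top]
  dxs <- x$top_ws - x$bot_ws; dxp <- x$top_wp - x$bot_wp
  len2 <- dxs^2 + dxp^2
  tproj <- ((x$overall_ws - x$bot_ws) * dxs +
              (x$overall_wp - x$bot_wp) * dxp) / len2
  tclamp <- pmin(pmax(tproj, 0), 1)
  dev <- sqrt((x$overall_ws - (x$bot_ws + tclamp * dxs))^2 +
                (x$overall_wp - (x$bot_wp + tclamp * dxp))^2)
  phi <- (fs + fp) / 2
  out <- data.frame(phase_fraction_top = phi, fraction_salt = fs,
                    fraction_polymer = fp, fraction_spread = abs(fs - fp),
                    max_deviation = dev,
                    pass = dev <= tolerance & phi >= 0 & phi <= 1)
  class(out) <- c("lever_rule_report", "data.frame")
  out
}

# shared linearised log-log regression for the two consistency plots
loglog_fit_ <- function(y_log, x_log, back, what) {
  if (length(x_log) < 2L) stop(what, " fit needs at least 2 tie-lines")
  if (diff(range(x_log)) == 0)
    stop(what, " fit: degenerate regressor (all tie-lines identical)")
  X <- cbind(1, x_log)
  cf <- as.numeric(qr.solve(X, y_log))
  pred_log <- drop(X %*% cf)
  ss_res <- sum((y_log - pred_log)^2)
  ss_tot <- sum((y_log - mean(y_log))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  gof <- compute_sd(back(y_log), back(pred_log))
  list(intercept = cf[1], slope = cf[2], r_squared = r2, gof = gof)
}

#' Othmer-Tobias tie-line consistency correlation
#'
#' Fits `(1 - w_p_top) / w_p_top = k * ((1 - w_s_bot) / w_s_bot)^n` on
#' fractional (0-1) compositions by ordinary least squares in base-10
#' log-log space (`k = 10^intercept`, `n = slope`), the standard
#' construction of the consistency plot: near-linearity of the plot
#' (high r-squared) indicates internally consistent tie-line data.
#' The reported `sd` is the RMS residual of the *back-transformed*
#' left-hand-side ratio.
#'
#' @param x A `"tielines"` data frame (>= 2 rows); all `top_wp` and
#'   `bot_ws` must be strictly inside (0, 100).
#' @param r2_threshold Consistency verdict gate on r-squared; default
#'   0.95.
#' @return An object of class `c("othmer_tobias_fit", "tieline_fit")`:
#'   coefficients `k`, `n`, plus `r_squared`, `consistent`, `gof`, `sd`.
#' @examples
#' fit_othmer_tobias(peg600_koh_tielines())
#' @export
fit_othmer_tobias <- function(x, r2_threshold = 0.95) {
  fpt <- wt_to_frac(x$top_wp); fsb <- wt_to_frac(x$bot_ws)
  if (any(fpt <= 0 | fpt >= 1) || any(fsb <= 0 | fsb >= 1))
    stop("Othmer-Tobias: phase compositions of 0 or 100 wt% give log singularities")
  f <- loglog_fit_(log10((1 - fpt) / fpt), log10((1 - fsb) / fsb),
                   back = function(l) 10^l, what = "Othmer-Tobias")
  structure(list(coefficients = c(k = 10^f$intercept, n = f$slope),
                 r_squared = f$r_squared,
                 consistent = f$r_squared >= r2_threshold,
                 r2_threshold = r2_threshold,
                 gof = f$gof, sd = f$gof$sd, data = x, call = sys.call()),
            class = c("othmer_tobias_fit", "tieline_fit"))
}

#' Bancroft tie-line consistency correlation
#'
#' Fits `(w_w_bot / w_s_bot) = k1 * (w_w_top / w_p_top)^r` by base-10
#' log-log least squares, with water fractions by difference from closure.
#' Interpretation and outputs mirror [fit_othmer_tobias()].
#'
#' @inheritParams fit_othmer_tobias
#' @return An object of class `c("bancroft_fit", "tieline_fit")` with
#'   coefficients `k1`, `r`.
#' @examples
#' fit_bancroft(peg600_koh_tielines())
#' @export
fit_bancroft <- function(x, r2_threshold = 0.95) {
  ww_top <- 100 - x$top_wp - x$top_ws
  ww_bot <- 100 - x$bot_wp - x$bot_ws
  if (any(ww_top <= 0 | ww_bot <= 0) || any(x$bot_ws <= 0 | x$top_wp <= 0))
    stop("Bancroft: non-positive composition gives log singularity")
  f <- loglog_fit_(log10(ww_bot / x$bot_ws), log10(ww_top / x$top_wp),
                   back = function(l) 10^l, what = "Bancroft")
  structure(list(coefficients = c(k1 = 10^f$intercept, r = f$slope),
                 r_squared = f$r_squared,
                 consistent = f$r_squared >= r2_threshold,
                 r2_threshold = r2_threshold,
                 gof = f$gof, sd = f$gof$sd, data = x, call = sys.call()),
            class = c("bancroft_fit", "tieline_fit"))
}

#' Setschenow salting-out correlation
#'
#' Fits `ln(C_p_top / C_p_bot) = k_p + k_s * (C_s_bot - C_s_top)`, where
#' `C_p`, `C_s` are phase molalities (mol per kg of water in that phase)
#' of polymer and salt. The slope `k_s` is the salting-out coefficient
#' (kg/mol): for a salting-out system it is expected positive, and the
#' function warns when the estimate is not. The fit is ordinary least
#' squares on the ln-ratio scale, where `sd` is also reported.
#'
#' Note the molality basis matters: in strongly asymmetric systems the
#' polymer-rich top phase can hold *more* salt per kg of its scarce water
#' than the bottom phase, making the regressor non-monotone; see the
#' package vignette.
#'
#' @param x A `"tielines"` data frame (>= 2 rows).
#' @param polymer,salt [species()] objects supplying molar masses;
#'   defaults [peg600()] and [koh()].
#' @return An object of class `c("setschenow_fit", "tieline_fit")` with
#'   coefficients `k_p` (dimensionless) and `k_s` (kg/mol), `gof`, `sd`,
#'   and the molality table in `molalities`.
#' @examples
#' suppressWarnings(fit_setschenow(peg600_koh_tielines()))
#' @export
fit_setschenow <- function(x, polymer = peg600(), salt = koh()) {
  if (nrow(x) < 2L) stop("Setschenow fit needs at least 2 tie-lines")
  ww_top <- 100 - x$top_wp - x$top_ws
  ww_bot <- 100 - x$bot_wp - x$bot_ws
  if (any(x$bot_wp <= 0))
    stop("Setschenow: zero polymer in bottom phase (ln-ratio singularity)")
  cp_top <- mass_fraction_to_molality(x$top_wp, ww_top, polymer)
  cp_bot <- mass_fraction_to_molality(x$bot_wp, ww_bot, polymer)
  cs_top <- mass_fraction_to_molality(x$top_ws, ww_top, salt)
  cs_bot <- mass_fraction_to_molality(x$bot_ws, ww_bot, salt)
  yy <- log(cp_top / cp_bot); xx <- cs_bot - cs_top
  if (diff(range(xx)) == 0)
    stop("Setschenow fit: degenerate regressor (equal salt molality differences)")
  X <- cbind(1, xx)
  cf <- as.numeric(qr.solve(X, yy))
  gof <- compute_sd(yy, drop(X %*% cf))
  if (cf[2] <= 0)
    warning(sprintf("estimated salting-out coefficient k_s = %.4g is not positive; ",
                    cf[2]),
            "unexpected for a salting-out system on this molality basis")
  structure(list(coefficients = c(k_p = cf[1], k_s = cf[2]),
                 gof = gof, sd = gof$sd,
                 molalities = data.frame(cp_top, cp_bot, cs_top, cs_bot),
                 data = x, call = sys.call()),
            class = c("setschenow_fit", "tieline_fit"))
}

#' @export
coef.tieline_fit <- function(object, ...) object$coefficients

#' @export
residuals.tieline_fit <- function(object, ...) object$gof$residuals

#' @export
print.tieline_fit <- function(x, digits = 6, ...) {
  lab <- switch(class(x)[1],
    othmer_tobias_fit = "Othmer-Tobias: (1-wp_top)/wp_top = k * ((1-ws_bot)/ws_bot)^n",
    bancroft_fit = "Bancroft: ww_bot/ws_bot = k1 * (ww_top/wp_top)^r",
    setschenow_fit = "Setschenow: ln(Cp_top/Cp_bot) = k_p + k_s * (Cs_bot - Cs_top)")
  cat(lab, "\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("sd = %.4g over %d tie-lines", x$sd, x$gof$n_points))
  if (!is.null(x$r_squared))
    cat(sprintf("; r^2 = %.4f (%s at gate %.2f)", x$r_squared,
                if (x$consistent) "consistent" else "NOT consistent",
                x$r2_threshold))
  cat("\n")
  invisible(x)
}

#' Predict from a tie-line consistency fit
#'
#' For an Othmer-Tobias fit, predicts the top-phase polymer content (wt%)
#' from bottom-phase salt content (wt%); for a Bancroft fit, the
#' bottom-phase water/salt ratio from the top-phase water/polymer ratio;
#' for a Setschenow fit, the ln molality ratio from the salt molality
#' difference (mol/kg).
#'
#' @param object A `"tieline_fit"`.
#' @param newdata Numeric vector on the scale described above.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.tieline_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  switch(class(object)[1],
    othmer_tobias_fit = {
      fsb <- wt_to_frac(newdata)
      ratio <- cf[["k"]] * ((1 - fsb) / fsb)^cf[["n"]]
      frac_to_wt(1 / (1 + ratio))
    },
    bancroft_fit = cf[["k1"]] * newdata^cf[["r"]],
    setschenow_fit = cf[["k_p"]] + cf[["k_s"]] * newdata)
}

#' Read a tie-line CSV
#'
#' Expected columns: `overall_ws`, `overall_wp`, `top_ws`, `top_wp`,
#' `bot_ws`, `bot_wp` in wt%.
#'
#' @param path CSV path.
#' @param ... Passed to [as_tielines()].
#' @return A `"tielines"` data frame.
#' @export
read_tielines <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("tie-line CSV is empty")
  as_tielines(df, ...)
}
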