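#' Evaluate the Merchuk binodal correlation
#'
#' The Merchuk three-parameter exponential form for a polymer-salt binodal:
#' `w_p = a * exp(b * w_s^0.5 - c * w_s^3)`, with both compositions in wt%.
#'
#' @param w_s Salt mass fraction, wt% (>= 0); vectorised.
#' @param a Amplitude, wt% (the curve's value at `w_s = 0`).
#' @param b Coefficient of `w_s^0.5`.
#' @param c Coefficient of `w_s^3`.
#' @return Polymer mass fraction, wt%.
#' @examples
#' merchuk_wp(17, a = 50, b = 0, c = 0)   # 50
#' merchuk_wp(4, a = 50, b = -0.3, c = 0) # 50 * exp(-0.6)
#' @export
merchuk_wp <- function(w_s, a, b, c) {
  if (any(w_s < 0)) stop("w_s must be non-negative (wt%)")
  a * exp(b * sqrt(w_s) - c * w_s^3)
}

#' Evaluate the Zafarani-Moattar binodal correlation
#'
#' The log-linear form `w_p = alpha + beta * ln(w_s) + gamma * w_s`,
#' compositions in wt%.
#'
#' @param w_s Salt mass fraction, wt% (> 0, the logarithm); vectorised.
#' @param alpha Intercept, wt%.
#' @param beta Coefficient of `ln(w_s)`, wt%.
#' @param gamma Linear slope.
#' @return Polymer mass fraction, wt%.
#' @examples
#' zm_wp(exp(1), alpha = 0, beta = 1, gamma = 0)  # 1
#' @export
zm_wp <- function(w_s, alpha, beta, gamma) {
  if (any(w_s <= 0)) stop("w_s must be positive (wt%): ln(w_s) is taken")
  alpha + beta * log(w_s) + gamma * w_s
}

#' Fit a binodal correlation to (salt, polymer) cloud points
#'
#' Fits either the Merchuk exponential form (nonlinear least squares) or
#' the Zafarani-Moattar log-linear form (exact linear least squares) to
#' binodal points, minimising `sum((w_p_obs - w_p_pred)^2)` on the wt%
#' scale. Fit quality is reported as the RMS residual via [compute_sd()].
#'
#' For the Merchuk fit the default start is `a0 = max(w_p)` (the binodal
#' intercept proxy), `b0 = -0.3`, `c0 = 1e-5`; on non-convergence up to
#' five jittered restarts are tried and the best converged solution kept.
#' The Levenberg-Marquardt tolerances are tight (1e-10 relative, 10000
#' evaluations) since the curve is smooth and cheap.
#'
#' @param points Data frame with columns `w_s` and `w_p` in wt% (a matrix
#'   or list with those elements also works).
#' @param model `"merchuk"` or `"zm"`.
#' @param start Optional named start values for the Merchuk fit
#'   (`a`, `b`, `c`).
#' @param lower,upper Optional parameter bounds for the Merchuk fit (e.g.
#'   `lower = c(a = 0, b = -Inf, c = -Inf)` to enforce a positive
#'   amplitude); unbounded by default.
#' @param control A [minpack.lm::nls.lm.control()] list for the Merchuk
#'   optimiser.
#' @return An object of class `c("<model>_fit", "binodal_fit")`: list with
#'   `coefficients`, `fitted.values`, `residuals`, `gof` (a `"gof"`),
#'   `sd`, `data`, `model`, `convergence` and `call`. Supports `coef()`,
#'   `predict()`, `residuals()`, `fitted()`, `print()`, `summary()`,
#'   `plot()` and `simulate()`.
#' @examples
#' ws <- seq(5, 40, by = 5)
#' pts <- data.frame(w_s = ws, w_p = merchuk_wp(ws, 60, -0.35, 5e-5))
#' fit <- fit_binodal(pts, "merchuk")
#' coef(fit)
#' @export
fit_binodal <- function(points, model = c("merchuk", "zm"), start = NULL,
                        lower = NULL, upper = NULL,
                        control = minpack.lm::nls.lm.control(
                          ftol = 1e-10, ptol = 1e-10, maxfev = 10000)) {
  model <- match.arg(model)
  pts <- as.data.frame(points)
  if (!all(c("w_s", "w_p") %in% names(pts)))
    stop("binodal points need columns w_s and w_p (wt%)")
  pts <- pts[, c("w_s", "w_p")]
  if (anyNA(pts)) stop("binodal points contain missing values")
  if (model == "merchuk") {
    fit_merchuk_(pts, start, lower, upper, control, sys.call())
  } else {
    fit_zm_(pts, sys.call())
  }
}

fit_merchuk_ <- function(pts, start, lower, upper, control, call) {
  if (nrow(pts) < 4L)
    stop("Merchuk fit needs at least 4 binodal points")
  if (any(pts$w_s < 0)) stop("w_s must be non-negative")
  if (length(unique(pts$w_s)) < 3L)
    stop("Merchuk fit needs w_s spread over at least 3 distinct values")
  resid_fn <- function(p) pts$w_p - merchuk_wp(pts$w_s, p[1], p[2], p[3])
  p0 <- if (is.null(start)) c(a = max(pts$w_p), b = -0.3, c = 1e-5)
        else c(a = start[["a"]], b = start[["b"]], c = start[["c"]])
  lo <- if (is.null(lower)) rep(-Inf, 3) else lower
  hi <- if (is.null(upper)) rep(Inf, 3) else upper
  # deterministic jitter for the multi-start fallback (no RNG side effects)
  starts <- c(list(p0), lapply(1:4, function(i)
    p0 * (1 + 0.3 * sin(seq(0.7, 2.1, length.out = 3) * i)) + c(0, -0.1, 1e-6) * i))
  best <- NULL
  for (s in starts) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lo, upper = hi, fn = resid_fn,
                         control = control),
      error = function(e) NULL)
    if (is.null(ans) || !(ans$info %in% 1:4)) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
    if (identical(s, starts[[1]])) break      # default start converged
  }
  if (is.null(best))
    stop("Merchuk fit did not converge from ", length(starts),
         " Levenberg-Marquardt starts; check the data spread")
  cf <- stats::setNames(as.numeric(best$par), c("a", "b", "c"))
  pred <- merchuk_wp(pts$w_s, cf["a"], cf["b"], cf["c"])
  gof <- compute_sd(pts$w_p, pred)
  structure(list(coefficients = cf, fitted.values = pred,
                 residuals = gof$residuals, gof = gof, sd = gof$sd,
                 data = pts, model = "merchuk",
                 convergence = list(info = best$info, message = best$message,
                                    deviance = best$deviance),
                 call = call),
            class = c("merchuk_fit", "binodal_fit"))
}

fit_zm_ <- function(pts, call) {
  if (nrow(pts) < 3L)
    stop("Zafarani-Moattar fit needs at least 3 binodal points")
  if (any(pts$w_s <= 0)) stop("w_s must be positive for the ln(w_s) regressor")
  X <- cbind(1, log(pts$w_s), pts$w_s)
  if (qr(X)$rank < 3L)
    stop("collinear regressors: need at least 3 distinct w_s values")
  cf <- stats::setNames(as.numeric(qr.solve(X, pts$w_p)),
                        c("alpha", "beta", "gamma"))
  pred <- drop(X %*% cf)
  gof <- compute_sd(pts$w_p, pred)
  structure(list(coefficients = cf, fitted.values = pred,
                 residuals = gof$residuals, gof = gof, sd = gof$sd,
                 data = pts, model = "zm",
                 convergence = list(info = 0L, message = "exact linear solve"),
                 call = call),
            class = c("zm_fit", "binodal_fit"))
}

#' @export
coef.binodal_fit <- function(object, ...) object$coefficients

#' @export
residuals.binodal_fit <- function(object, ...) object$residuals

#' @export
fitted.binodal_fit <- function(object, ...) object$fitted.values

#' Predict polymer content from a fitted binodal
#'
#' @param object A `"binodal_fit"`.
#' @param newdata Optional data frame with a `w_s` column, or a numeric
#'   vector of salt mass fractions (wt%); defaults to the fitted data.
#' @param ... Unused.
#' @return Predicted `w_p` in wt%.
#' @export
predict.binodal_fit <- function(object, newdata = NULL, ...) {
  ws <- if (is.null(newdata)) object$data$w_s
        else if (is.numeric(newdata)) newdata
        else as.data.frame(newdata)$w_s
  cf <- object$coefficients
  if (object$model == "merchuk") merchuk_wp(ws, cf["a"], cf["b"], cf["c"])
  else zm_wp(ws, cf["alpha"], cf["beta"], cf["gamma"])
}

#' @export
print.binodal_fit <- function(x, digits = 6, ...) {
  lab <- if (x$model == "merchuk")
    "Merchuk binodal: w_p = a*exp(b*w_s^0.5 - c*w_s^3)"
  else "Zafarani-Moattar binodal: w_p = alpha + beta*ln(w_s) + gamma*w_s"
  cat(lab, "\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("sd = %.4g wt%% over %d points\n", x$sd, x$gof$n_points))
  invisible(x)
}

#' @export
summary.binodal_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.binodal_fit")
}

#' @export
print.summary.binodal_fit <- function(x, ...) {
  print(x$fit)
  cat("residual range: [", signif(min(x$fit$residuals), 4), ", ",
      signif(max(x$fit$residuals), 4), "] wt%\n", sep = "")
  invisible(x)
}

#' Plot a fitted binodal with its data
#'
#' @param x A `"binodal_fit"`.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.binodal_fit <- function(x, n_grid = 200, ...) {
  graphics::plot(x$data$w_s, x$data$w_p, xlab = "salt (wt%)",
                 ylab = "polymer (wt%)", ...)
  lo <- max(min(x$data$w_s), if (x$model == "zm") 1e-6 else 0)
  ws <- seq(lo, max(x$data$w_s), length.out = n_grid)
  graphics::lines(ws, predict(x, ws))
  invisible(x)
}

#' Simulate binodal points from a fitted correlation
#'
#' Draws new points at the fitted `w_s` locations with Gaussian noise of
#' standard deviation equal to the fit's RMS residual.
#'
#' @param object A `"binodal_fit"`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `w_s`, `w_p`.
#' @export
simulate.binodal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  lapply(seq_len(nsim), function(i)
    data.frame(w_s = object$data$w_s,
               w_p = mu + stats::rnorm(length(mu), 0, object$sd)))
}

#' Read binodal points from CSV
#'
#' Expected columns: `w_s_wt_pct`, `w_p_wt_pct` (or plain `w_s`, `w_p`).
#'
#' @param path CSV path.
#' @return Data frame with columns `w_s`, `w_p` in wt%.
#' @export
read_binodal <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("w_s_wt_pct", "w_p_wt_pct") %in% names(df)))
    df <- data.frame(w_s = df$w_s_wt_pct, w_p = df$w_p_wt_pct)
  if (!all(c("w_s", "w_p") %in% names(df)))
    stop("binodal CSV needs columns (w_s_wt_pct, w_p_wt_pct) or (w_s, w_p)")
  if (nrow(df) == 0L) stop("binodal CSV is empty")
  df[, c("w_s", "w_p")]
}

#' Serialise a binodal fit to JSON
#'
#' @param fit A `"binodal_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binodal_json <- function(fit, path) {
  stopifnot(inherits(fit, "binodal_fit"))
  model_name <- if (fit$model == "merchuk") "merchuk" else "zafarani_moattar"
  jsonlite::write_json(
    list(model = model_name, params = as.list(fit$coefficients),
         sd = fit$sd, n_points = fit$gof$n_points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
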