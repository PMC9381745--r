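#' Configuration for the synthetic ATPS data generator
#'
#' Bundles the ground-truth parameters and noise levels from which
#' synthetic equilibrium datasets are drawn. Defaults emulate the scales
#' of the PEG600 + KOH + water system at 298.15 K: a binodal running from
#' about 75 wt% polymer at 8 wt% salt down to about 6 wt% at 30 wt% salt,
#' five tie-lines with TLL around 50-63 wt%, drug partition coefficients
#' around 7-14, and the stated measurement uncertainties (binodal scatter
#' 0.3 wt%; refractive index 0.0002; ln-K noise 0.015, which corresponds
#' to an absolute K uncertainty of about 0.15 at this system's typical
#' K of about 10).
#'
#' @param seed Integer seed. Each generator stage uses its own derived
#'   stream (`seed` plus a fixed per-stage offset), so stages are
#'   reproducible independently of each other.
#' @param binodal_truth Named vector `(a, b, c)` of Merchuk truth
#'   parameters (wt% scale).
#' @param n_binodal_points Number of binodal points (>= 1).
#' @param binodal_w_s_range Salt range (wt%) over which binodal points are
#'   gridded.
#' @param binodal_noise_sd Additive Gaussian noise on `w_p`, wt%.
#' @param n_tielines Number of tie-lines (>= 1).
#' @param tieline_mode How tie-lines are constructed: `"binodal"`
#'   (endpoints exactly on the truth binodal at the anchor salt
#'   fractions), `"othmer_tobias"` (top polymer content back-solved from
#'   the Othmer-Tobias truth, so that correlation holds exactly), or
#'   `"setschenow"` (top polymer content solved so the Setschenow relation
#'   holds exactly in molality space).
#' @param top_anchors,bottom_anchors Salt mass fractions (wt%) of the
#'   top / bottom phase endpoints; defaults run from 9.8 down to 8.8 and
#'   from 21 up to 29, mirroring how deeper overall compositions push the
#'   top phase to lower salt (higher polymer) and the bottom phase to
#'   higher salt, so tie-line length and the PEG composition difference
#'   both grow along the series.
#' @param tieline_noise_sd Optional Gaussian perturbation (wt%) of the
#'   endpoint compositions; default 0 (endpoints exactly on the binodal).
#' @param lever_range Range of the lever-rule fraction used to place the
#'   overall composition on the segment.
#' @param othmer_tobias_truth Named vector `(k, n)` for
#'   `tieline_mode = "othmer_tobias"`.
#' @param setschenow_truth Named vector `(k_p, k_s)` for
#'   `tieline_mode = "setschenow"`.
#' @param partition_truth Named list, one element per drug, each a named
#'   vector `(A, B)` (Diamond-Hsu) or `(A1, B1, C1)` (modified form) on
#'   the ln-K scale.
#' @param partition_noise_sd Gaussian noise on ln K (multiplicative,
#'   lognormal on K, so K stays positive).
#' @param total_drug_fraction Total drug mass fraction spiked into each
#'   mixture; default 0.002.
#' @param refractometry_truth List with `n0`, `a_p`, `a_s` (coefficients
#'   per unit mass fraction, 0-1 scale).
#' @param refractometry_noise_sd Gaussian noise on the refractive index;
#'   default 0.0002 (the typical stated measurement uncertainty).
#' @param polymer,salt [species()] objects (molar masses for the
#'   Setschenow construction).
#' @return A validated list of class `"sim_config"`.
#' @seealso [generate_binodal()], [generate_tielines()],
#'   [generate_partition()], [generate_refractometry()], [simulate_atps()]
#' @export
sim_config <- function(seed = 1,
                       binodal_truth = c(a = 1100, b = -0.95, c = 5e-6),
                       n_binodal_points = 20,
                       binodal_w_s_range = c(8, 32),
                       binodal_noise_sd = 0.3,
                       n_tielines = 5,
                       tieline_mode = c("binodal", "othmer_tobias", "setschenow"),
                       top_anchors = NULL,
                       bottom_anchors = NULL,
                       tieline_noise_sd = 0,
                       lever_range = c(0.3, 0.7),
                       othmer_tobias_truth = c(k = 0.15, n = 1.16),
                       setschenow_truth = c(k_p = 0.2, k_s = 1.1),
                       partition_truth = list(
                         ibuprofen = c(A = 0.044, B = -3e-5),
                         acetaminophen = c(A = 0.026, B = 2.2e-4)),
                       partition_noise_sd = 0.015,
                       total_drug_fraction = 0.002,
                       refractometry_truth = list(n0 = 1.3325, a_p = 0.14,
                                                  a_s = 0.12),
                       refractometry_noise_sd = 2e-4,
                       polymer = peg600(), salt = koh()) {
  tieline_mode <- match.arg(tieline_mode)
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_binodal_points < 1 || n_tielines < 1)
    stop("point counts must be >= 1")
  for (s in c(binodal_noise_sd, tieline_noise_sd, partition_noise_sd,
              refractometry_noise_sd))
    if (!is.finite(s) || s < 0) stop("noise standard deviations must be >= 0")
  if (is.null(top_anchors))
    top_anchors <- seq(9.8, 8.8, length.out = n_tielines)
  if (is.null(bottom_anchors))
    bottom_anchors <- seq(21, 29, length.out = n_tielines)
  if (length(top_anchors) != n_tielines || length(bottom_anchors) != n_tielines)
    stop("anchor vectors must have length n_tielines")
  if (any(top_anchors >= bottom_anchors))
    stop("top anchors must be below bottom anchors (top phase is low-salt)")
  structure(list(seed = as.integer(seed), binodal_truth = binodal_truth,
                 n_binodal_points = as.integer(n_binodal_points),
                 binodal_w_s_range = binodal_w_s_range,
                 binodal_noise_sd = binodal_noise_sd,
                 n_tielines = as.integer(n_tielines),
                 tieline_mode = tieline_mode,
                 top_anchors = top_anchors, bottom_anchors = bottom_anchors,
                 tieline_noise_sd = tieline_noise_sd,
                 lever_range = lever_range,
                 othmer_tobias_truth = othmer_tobias_truth,
                 setschenow_truth = setschenow_truth,
                 partition_truth = partition_truth,
                 partition_noise_sd = partition_noise_sd,
                 total_drug_fraction = total_drug_fraction,
                 refractometry_truth = refractometry_truth,
                 refractometry_noise_sd = refractometry_noise_sd,
                 polymer = polymer, salt = salt),
            class = "sim_config")
}

# Run expr under a derived, stage-local RNG stream; the caller's RNG state
# is untouched.
with_stream_ <- function(seed, offset, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed + offset)
  expr
}

#' Generate synthetic binodal points
#'
#' Salt fractions are gridded over the configured range and polymer
#' fractions drawn as the Merchuk truth curve plus additive Gaussian
#' noise. With zero noise every point satisfies the truth correlation
#' exactly.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `w_s`, `w_p` (wt%).
#' @export
generate_binodal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$binodal_truth
  ws <- seq(config$binodal_w_s_range[1], config$binodal_w_s_range[2],
            length.out = config$n_binodal_points)
  mu <- merchuk_wp(ws, tr[["a"]], tr[["b"]], tr[["c"]])
  if (any(mu < 0))
    stop("binodal truth produces negative noiseless w_p in the sampled range")
  wp <- with_stream_(config$seed, 101L,
                     mu + stats::rnorm(length(mu), 0, config$binodal_noise_sd))
  data.frame(w_s = ws, w_p = wp)
}

#' Generate synthetic tie-lines
#'
#' Endpoints are placed at the configured anchor salt fractions; the
#' polymer coordinates come from the truth binodal (`"binodal"` mode), or
#' are back-solved so that the Othmer-Tobias or Setschenow truth relation
#' holds exactly (`"othmer_tobias"` / `"setschenow"` modes, used for
#' parameter-recovery oracles). The overall composition is drawn on the
#' segment at a lever-rule fraction uniform in `lever_range`, so every
#' generated line passes [lever_rule_check()] by construction (up to
#' endpoint noise).
#'
#' @param config A [sim_config()].
#' @return A `"tielines"` data frame with `n_tielines` rows.
#' @export
generate_tielines <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$binodal_truth
  ws_top <- config$top_anchors; ws_bot <- config$bottom_anchors
  wp_bot <- merchuk_wp(ws_bot, tr[["a"]], tr[["b"]], tr[["c"]])
  wp_top <- switch(config$tieline_mode,
    binodal = merchuk_wp(ws_top, tr[["a"]], tr[["b"]], tr[["c"]]),
    othmer_tobias = {
      k <- config$othmer_tobias_truth[["k"]]
      n <- config$othmer_tobias_truth[["n"]]
      fsb <- wt_to_frac(ws_bot)
      ratio <- k * ((1 - fsb) / fsb)^n   # = (1 - fp_top) / fp_top
      frac_to_wt(1 / (1 + ratio))
    },
    setschenow = {
      kp <- config$setschenow_truth[["k_p"]]
      ks <- config$setschenow_truth[["k_s"]]
      ww_bot <- 100 - wp_bot - ws_bot
      cp_bot <- mass_fraction_to_molality(wp_bot, ww_bot, config$polymer)
      cs_bot <- mass_fraction_to_molality(ws_bot, ww_bot, config$salt)
      vapply(seq_along(ws_top), function(i) {
        g <- function(wp) {
          ww <- 100 - wp - ws_top[i]
          cp <- mass_fraction_to_molality(wp, ww, config$polymer)
          cs <- mass_fraction_to_molality(ws_top[i], ww, config$salt)
          log(cp / cp_bot[i]) - kp - ks * (cs_bot[i] - cs)
        }
        stats::uniroot(g, c(1e-6, 100 - ws_top[i] - 1e-6), tol = 1e-13)$root
      }, numeric(1))
    })
  with_stream_(config$seed, 202L, {
    if (config$tieline_noise_sd > 0) {
      n <- config$n_tielines
      ws_top <- ws_top + stats::rnorm(n, 0, config$tieline_noise_sd)
      wp_top <- wp_top + stats::rnorm(n, 0, config$tieline_noise_sd)
      ws_bot <- ws_bot + stats::rnorm(n, 0, config$tieline_noise_sd)
      wp_bot <- wp_bot + stats::rnorm(n, 0, config$tieline_noise_sd)
    }
    phi <- stats::runif(config$n_tielines, config$lever_range[1],
                        config$lever_range[2])
    as_tielines(data.frame(
      overall_ws = phi * ws_top + (1 - phi) * ws_bot,
      overall_wp = phi * wp_top + (1 - phi) * wp_bot,
      top_ws = ws_top, top_wp = wp_top,
      bot_ws = ws_bot, bot_wp = wp_bot))
  })
}

#' Generate synthetic drug-partitioning records
#'
#' For each drug and tie-line, ln K is drawn from the configured
#' Diamond-Hsu truth at the line's PEG composition difference plus
#' Gaussian ln-scale noise, and the phase drug mass fractions are
#' back-solved so that the total spiked drug mass fraction is exactly
#' `total_drug_fraction` under the lever-rule phase split:
#' `phi * w_top + (1 - phi) * w_bot = total` with `w_top = K * w_bot`.
#'
#' @param config A [sim_config()].
#' @param tielines A `"tielines"` data frame (e.g. from
#'   [generate_tielines()]).
#' @return A `"partition_records"` data frame with phase concentrations,
#'   `K`, `EE`, `delta_w_peg` and `tll`.
#' @export
generate_partition <- function(config, tielines) {
  stopifnot(inherits(config, "sim_config"))
  tl <- as_tielines(tielines)
  dw <- tl$top_wp - tl$bot_wp
  phi <- lever_rule_check(tl, tolerance = Inf)$phase_fraction_top
  if (any(phi <= 0 | phi >= 1))
    stop("unattainable mass balance: lever fraction outside (0, 1)")
  with_stream_(config$seed, 303L, {
    out <- lapply(names(config$partition_truth), function(drug) {
      p <- config$partition_truth[[drug]]
      lnk <- if (all(c("A1", "B1", "C1") %in% names(p)))
        p[["A1"]] + p[["B1"]] * dw + p[["C1"]] * dw^2
      else p[["A"]] * dw + p[["B"]] * dw^2
      lnk <- lnk + stats::rnorm(length(dw), 0, config$partition_noise_sd)
      K <- exp(lnk)
      w_bot <- config$total_drug_fraction / (phi * K + 1 - phi)
      data.frame(drug = drug,
                 overall_ws = tl$overall_ws, overall_wp = tl$overall_wp,
                 w_top_drug = K * w_bot, w_bot_drug = w_bot)
    })
    partition_records(do.call(rbind, out), tielines = tl)
  })
}

#' Generate synthetic refractometry data
#'
#' Produces single-solute calibration dilution series and, optionally,
#' readings for supplied phase compositions, all from the linear
#' refractive-index truth model plus Gaussian instrument noise.
#' Compositions are diluted by `dilution_factor` before "measurement", as
#' equilibrium phases are in practice far above the calibrated dilute
#' range.
#'
#' @param config A [sim_config()].
#' @param compositions Optional data frame with `w_p`, `w_s` columns in
#'   wt% (e.g. phase compositions) for which readings are generated.
#' @param n_calibration Points per calibration series; default 8 over
#'   mass fractions 0.004-0.075, a span wide enough to cover tenfold-
#'   diluted equilibrium phases while staying in the dilute linear
#'   regime.
#' @param dilution_factor Dilution applied to `compositions` before
#'   measurement; default 10.
#' @return List with `series_p`, `series_s` (columns `w`, `n_d`) and
#'   `readings` (columns `n_d`, `w_s_known`, `w_p_true`,
#'   `dilution_factor`; fractional 0-1 scale, diluted).
#' @export
generate_refractometry <- function(config, compositions = NULL,
                                   n_calibration = 8, dilution_factor = 10) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$refractometry_truth
  with_stream_(config$seed, 404L, {
    wcal <- seq(0.004, 0.075, length.out = n_calibration)
    noise <- function(n) stats::rnorm(n, 0, config$refractometry_noise_sd)
    series_p <- data.frame(w = wcal, n_d = tr$n0 + tr$a_p * wcal +
                             noise(n_calibration))
    series_s <- data.frame(w = wcal, n_d = tr$n0 + tr$a_s * wcal +
                             noise(n_calibration))
    readings <- NULL
    if (!is.null(compositions)) {
      wp <- wt_to_frac(compositions$w_p) / dilution_factor
      ws <- wt_to_frac(compositions$w_s) / dilution_factor
      readings <- data.frame(
        n_d = tr$n0 + tr$a_p * wp + tr$a_s * ws + noise(length(wp)),
        w_s_known = ws, w_p_true = wp, dilution_factor = dilution_factor)
    }
    list(series_p = series_p, series_s = series_s, readings = readings)
  })
}

#' Write a complete synthetic ATPS dataset to disk
#'
#' Generates binodal, tie-line, partition and refractometry data from one
#' configuration and writes them as CSVs plus a `truth.json` holding the
#' generating parameters, for parameter-recovery benchmarking. Output is
#' byte-identical for identical configurations (including the seed).
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_atps <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  binodal <- generate_binodal(config)
  tielines <- generate_tielines(config)
  partition <- generate_partition(config, tielines)
  phases <- data.frame(w_p = c(tielines$top_wp, tielines$bot_wp),
                       w_s = c(tielines$top_ws, tielines$bot_ws))
  refracto <- generate_refractometry(config, compositions = phases)
  paths <- file.path(outdir, c("binodal.csv", "tielines.csv",
                               "partition.csv", "refractometry.csv",
                               "truth.json"))
  utils::write.csv(data.frame(w_s_wt_pct = binodal$w_s,
                              w_p_wt_pct = binodal$w_p),
                   paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(tielines)[, c("overall_ws", "overall_wp",
                                               "top_ws", "top_wp",
                                               "bot_ws", "bot_wp")],
                   paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(partition)[, c("drug", "overall_ws",
                                                "overall_wp", "w_top_drug",
                                                "w_bot_drug")],
                   paths[3], row.names = FALSE)
  cal <- rbind(data.frame(component = "polymer", w_mass_fraction =
                            refracto$series_p$w, n_d = refracto$series_p$n_d),
               data.frame(component = "salt", w_mass_fraction =
                            refracto$series_s$w, n_d = refracto$series_s$n_d))
  utils::write.csv(cal, paths[4], row.names = FALSE)
  truth <- config[c("seed", "binodal_truth", "binodal_noise_sd",
                    "tieline_mode", "othmer_tobias_truth", "setschenow_truth",
                    "partition_truth", "partition_noise_sd",
                    "total_drug_fraction", "refractometry_truth",
                    "refractometry_noise_sd")]
  truth$binodal_truth <- as.list(truth$binodal_truth)
  truth$othmer_tobias_truth <- as.list(truth$othmer_tobias_truth)
  truth$setschenow_truth <- as.list(truth$setschenow_truth)
  truth$partition_truth <- lapply(truth$partition_truth, as.list)
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA)
  invisible(list(binodal = binodal, tielines = tielines,
                 partition = partition, refractometry = refracto,
                 paths = stats::setNames(as.list(paths),
                                         c("binodal", "tielines", "partition",
                                           "refractometry", "truth"))))
}
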