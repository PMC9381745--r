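#' Partition coefficient of a solute between ATPS phases
#'
#' `K = w_top_drug / w_bot_drug`, the ratio of the solute (drug) mass
#' fraction in the polymer-rich top phase to that in the salt-rich bottom
#' phase. `K > 1` means the solute favours the top phase.
#'
#' @param w_top_drug,w_bot_drug Drug mass fractions in top and bottom
#'   phase (same units); vectorised. `w_bot_drug` must be positive.
#' @return Dimensionless partition coefficient.
#' @examples
#' partition_coefficient(0.004, 0.002)  # 2
#' @export
partition_coefficient <- function(w_top_drug, w_bot_drug) {
  if (any(!is.finite(w_bot_drug)) || any(w_bot_drug <= 0))
    stop("bottom-phase drug concentration must be positive")
  w_top_drug / w_bot_drug
}

#' Extraction efficiency from a partition coefficient
#'
#' `EE% = 100 * K / (K + 1)`: the percentage of solute recovered in the
#' top phase for equal phase masses. A strictly increasing bijection from
#' K in (0, Inf) onto (0, 100).
#'
#' @param K Partition coefficient(s), > 0.
#' @return Extraction efficiency in percent.
#' @examples
#' extraction_efficiency(8.87)  # 89.87
#' extraction_efficiency(1)     # 50
#' @export
extraction_efficiency <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("partition coefficient must be positive")
  100 * K / (K + 1)
}

#' Inverse of [extraction_efficiency()]
#'
#' @param EE Extraction efficiency in percent, in (0, 100).
#' @return Partition coefficient `EE / (100 - EE)`.
#' @export
ee_to_k <- function(EE) {
  if (any(EE <= 0) || any(EE >= 100))
    stop("EE must lie strictly between 0 and 100 %")
  EE / (100 - EE)
}

#' Assemble partition records and match them to tie-lines
#'
#' Builds the per-measurement table used by the Diamond-Hsu correlations:
#' computes `K` from phase concentrations when not supplied, `EE` from
#' `K`, and, when a tie-line table is given, the matched PEG composition
#' difference `delta_w_peg = top_wp - bot_wp` (wt%). Matching is by
#' identical overall composition within `match_tolerance` (drug-spiked
#' mixtures are prepared at the same overall compositions as the
#' tie-lines).
#'
#' @param df Data frame with columns `drug`, `overall_ws`, `overall_wp`
#'   and either (`w_top_drug`, `w_bot_drug`) or `K`.
#' @param tielines Optional `"tielines"` data frame for `delta_w_peg`.
#' @param match_tolerance Maximum wt% difference in each overall
#'   coordinate for a tie-line match; default 0.01.
#' @return A data frame of class `"partition_records"` with columns
#'   `drug`, `overall_ws`, `overall_wp`, `K`, `EE` and (if matched)
#'   `delta_w_peg` and `tll`.
#' @examples
#' partition_records(peg600_koh_partition(), peg600_koh_tielines())
#' @export
partition_records <- function(df, tielines = NULL, match_tolerance = 0.01) {
  df <- as.data.frame(df)
  need <- c("drug", "overall_ws", "overall_wp")
  if (!all(need %in% names(df)))
    stop("partition table needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("partition table is empty")
  if (!"K" %in% names(df)) {
    if (!all(c("w_top_drug", "w_bot_drug") %in% names(df)))
      stop("partition table needs either a K column or w_top_drug + w_bot_drug")
    df$K <- partition_coefficient(df$w_top_drug, df$w_bot_drug)
  }
  if (any(df$K <= 0)) stop("partition coefficients must be positive")
  df$EE <- extraction_efficiency(df$K)
  if (!is.null(tielines)) {
    idx <- vapply(seq_len(nrow(df)), function(i) {
      hit <- which(abs(tielines$overall_ws - df$overall_ws[i]) <= match_tolerance &
                     abs(tielines$overall_wp - df$overall_wp[i]) <= match_tolerance)
      if (length(hit) == 0L)
        stop(sprintf("no tie-line matches overall composition (%.2f, %.2f) within %.2g wt%%",
                     df$overall_ws[i], df$overall_wp[i], match_tolerance))
      hit[1]
    }, integer(1))
    df$delta_w_peg <- tielines$top_wp[idx] - tielines$bot_wp[idx]
    df$tll <- tielines$tll[idx]
  }
  class(df) <- c("partition_records", "data.frame")
  df
}

#' Diamond-Hsu correlation of partition coefficients
#'
#' Correlates `ln K` with the PEG mass-fraction difference between the
#' phases, `dw = delta_w_peg` (wt%):
#'
#' * original form (no intercept): `ln K = A*dw + B*dw^2`;
#' * modified form: `ln K = A1 + B1*dw + C1*dw^2`.
#'
#' Both are linear in their coefficients and solved in closed form; the
#' modified form nests the original, so on identical records its RMS
#' residual (`sd`, reported on the ln K scale) can never exceed the
#' original's.
#'
#' @param records A `"partition_records"` data frame carrying `K` and
#'   `delta_w_peg` columns (see [partition_records()]), or a data frame
#'   with those columns. Fit one drug at a time.
#' @param modified Logical: fit the three-parameter modified form.
#' @return An object of class `c("diamond_hsu_fit", "atps_fit")` with
#'   `coefficients` (`A`, `B` or `A1`, `B1`, `C1`), `gof`, `sd` (ln K
#'   scale), `modified`, and the fitting data.
#' @examples
#' recs <- partition_records(peg600_koh_partition(), peg600_koh_tielines())
#' fit_diamond_hsu(recs[recs$drug == "ibuprofen", ])
#' fit_diamond_hsu(recs[recs$drug == "ibuprofen", ], modified = TRUE)
#' @export
fit_diamond_hsu <- function(records, modified = FALSE) {
  df <- as.data.frame(records)
  if (!all(c("K", "delta_w_peg") %in% names(df)))
    stop("records need K and delta_w_peg columns (match to tie-lines first)")
  if (any(df$K <= 0)) stop("partition coefficients must be positive")
  if ("drug" %in% names(df) && length(unique(df$drug)) > 1L)
    stop("fit one drug at a time; got: ",
         paste(unique(df$drug), collapse = ", "))
  dw <- df$delta_w_peg; y <- log(df$K)
  ndist <- length(unique(dw))
  if (!modified) {
    if (nrow(df) < 2L || ndist < 2L)
      stop("Diamond-Hsu fit needs >= 2 records with distinct delta_w_peg")
    X <- cbind(dw, dw^2); nm <- c("A", "B")
  } else {
    if (nrow(df) < 3L || ndist < 3L)
      stop("modified Diamond-Hsu fit needs >= 3 records with >= 3 distinct delta_w_peg")
    X <- cbind(1, dw, dw^2); nm <- c("A1", "B1", "C1")
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient regressors: delta_w_peg values too few or indistinct")
  cf <- stats::setNames(as.numeric(qr.solve(X, y)), nm)
  gof <- compute_sd(y, drop(X %*% cf))
  structure(list(coefficients = cf, gof = gof, sd = gof$sd,
                 modified = modified, data = df, call = sys.call()),
            class = c("diamond_hsu_fit", "atps_fit"))
}

#' @export
coef.diamond_hsu_fit <- function(object, ...) object$coefficients

#' @export
residuals.diamond_hsu_fit <- function(object, ...) object$gof$residuals

#' Predict partition coefficients from a Diamond-Hsu fit
#'
#' @param object A `"diamond_hsu_fit"`.
#' @param newdata Numeric vector of PEG composition differences
#'   `delta_w_peg` (wt%), or a data frame with that column; defaults to
#'   the fitted data.
#' @param type `"K"` (default) or `"lnK"`.
#' @param ... Unused.
#' @return Predicted K (or ln K).
#' @export
predict.diamond_hsu_fit <- function(object, newdata = NULL,
                                    type = c("K", "lnK"), ...) {
  type <- match.arg(type)
  dw <- if (is.null(newdata)) object$data$delta_w_peg
        else if (is.numeric(newdata)) newdata
        else as.data.frame(newdata)$delta_w_peg
  cf <- object$coefficients
  lnk <- if (object$modified) cf[["A1"]] + cf[["B1"]] * dw + cf[["C1"]] * dw^2
         else cf[["A"]] * dw + cf[["B"]] * dw^2
  if (type == "K") exp(lnk) else lnk
}

#' @export
print.diamond_hsu_fit <- function(x, digits = 6, ...) {
  cat(if (x$modified) "modified Diamond-Hsu: ln K = A1 + B1*dw + C1*dw^2\n"
      else "Diamond-Hsu: ln K = A*dw + B*dw^2\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("sd(ln K) = %.4g over %d records\n", x$sd, x$gof$n_points))
  invisible(x)
}

#' Rank drugs by extraction efficiency and check the hydrophobicity order
#'
#' Solute partitioning into the polymer-rich phase tracks hydrophobicity:
#' drugs with higher octanol-water log K_ow should show higher K and EE
#' at every overall composition. This report computes per-drug mean K and
#' EE, orders drugs by mean EE, and checks that ordering against the
#' supplied log K_ow values, both on the means and composition-wise.
#'
#' @param records A `"partition_records"` data frame with >= 1 drug.
#' @param log_kow Named numeric vector of octanol-water log K_ow per drug,
#'   e.g. `c(ibuprofen = 3.97, acetaminophen = 2.34)`.
#' @return A list of class `"hydrophobicity_report"`: `summary` (per-drug
#'   mean K/EE and log K_ow, ordered by EE), `consistent_means`,
#'   `consistent_pointwise` (every pairwise comparison at matched overall
#'   compositions agrees), and `verdict` (`"consistent"` /
#'   `"inconsistent"`).
#' @examples
#' recs <- partition_records(peg600_koh_partition())
#' rank_drugs_by_hydrophobicity(recs, c(ibuprofen = 3.97, acetaminophen = 2.34))
#' @export
rank_drugs_by_hydrophobicity <- function(records, log_kow) {
  df <- as.data.frame(records)
  drugs <- unique(df$drug)
  missing_kow <- setdiff(drugs, names(log_kow))
  if (length(missing_kow))
    stop("log_kow missing for: ", paste(missing_kow, collapse = ", "))
  summ <- do.call(rbind, lapply(drugs, function(d) {
    sub <- df[df$drug == d, ]
    data.frame(drug = d, n = nrow(sub), mean_K = mean(sub$K),
               mean_EE = mean(sub$EE), log_kow = log_kow[[d]])
  }))
  summ <- summ[order(-summ$mean_EE), ]
  consistent_means <- !is.unsorted(-summ$log_kow)
  # composition-wise comparison over all drug pairs at matched overalls
  consistent_pointwise <- TRUE
  if (length(drugs) > 1L) {
    key <- function(d) paste(round(d$overall_ws, 2), round(d$overall_wp, 2))
    for (i in seq_len(length(drugs) - 1L)) for (j in (i + 1L):length(drugs)) {
      a <- df[df$drug == drugs[i], ]; b <- df[df$drug == drugs[j], ]
      common <- intersect(key(a), key(b))
      if (!length(common)) next
      ee_a <- a$EE[match(common, key(a))]; ee_b <- b$EE[match(common, key(b))]
      want <- sign(log_kow[[drugs[i]]] - log_kow[[drugs[j]]])
      if (want != 0 && any(sign(ee_a - ee_b) != want))
        consistent_pointwise <- FALSE
    }
  }
  structure(list(summary = summ, consistent_means = consistent_means,
                 consistent_pointwise = consistent_pointwise,
                 verdict = if (consistent_means && consistent_pointwise)
                   "consistent" else "inconsistent"),
            class = "hydrophobicity_report")
}

#' @export
print.hydrophobicity_report <- function(x, ...) {
  cat("Drug partitioning vs hydrophobicity (ordered by mean EE%):\n")
  print(x$summary, row.names = FALSE)
  cat("EE ordering matches log K_ow ordering:", x$verdict, "\n")
  invisible(x)
}

#' Read a partition CSV
#'
#' Expected columns: `drug`, `overall_ws`, `overall_wp`, and either
#' (`w_top_drug`, `w_bot_drug`) or `K`.
#'
#' @param path CSV path.
#' @return Data frame (validate with [partition_records()]).
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("partition CSV is empty")
  df
}
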