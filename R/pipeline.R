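#' Run the full ATPS liquid-liquid equilibrium analysis
#'
#' End-to-end pipeline from tabular inputs to a report: binodal fits (both
#' Merchuk and Zafarani-Moattar, when binodal points are supplied),
#' tie-line characterisation (TLL, lever-rule mass balance) and the three
#' consistency correlations (Othmer-Tobias, Bancroft, Setschenow), and —
#' when partitioning data are supplied — partition coefficients,
#' extraction efficiencies, both Diamond-Hsu correlations per drug, and
#' the hydrophobicity-ordering verdict.
#'
#' @param tielines Tie-line data: a `"tielines"` data frame, a plain data
#'   frame, or a CSV path (see [read_tielines()]). Required.
#' @param binodal Optional binodal points (data frame with `w_s`, `w_p`,
#'   or CSV path).
#' @param partition Optional partition data (data frame or CSV path; see
#'   [read_partition()]).
#' @param polymer,salt [species()] for the Setschenow molality conversion.
#' @param log_kow Named log K_ow vector for the hydrophobicity ordering;
#'   drugs missing from it are skipped in the ranking.
#' @param closure_tolerance,lever_tolerance Tolerances in wt% for
#'   composition closure and the lever-rule deviation; defaults 0.5 and
#'   0.8 (the component measurement uncertainty).
#' @param r2_threshold Consistency gate on the linearised r-squared;
#'   default 0.95.
#' @param match_tolerance Overall-composition matching tolerance (wt%)
#'   between partition records and tie-lines.
#' @param outdir Optional output directory: writes `report.json` and
#'   `report.md`.
#' @return An object of class `"atps_report"`: nested list with elements
#'   `tielines`, `lever_rule`, `consistency` (the three fits), `binodal`
#'   (two fits, if data given), `partitioning` (records, per-drug fits,
#'   ranking, if data given), `warnings` (collected numerical warnings)
#'   and `pass` (logical: every validation and consistency gate passed).
#' @examples
#' rep <- run_full_analysis(tielines = peg600_koh_tielines(),
#'                          partition = peg600_koh_partition())
#' rep$pass
#' @export
run_full_analysis <- function(tielines, binodal = NULL, partition = NULL,
                              polymer = peg600(), salt = koh(),
                              log_kow = peg600_koh_log_kow(),
                              closure_tolerance = 0.5, lever_tolerance = 0.8,
                              r2_threshold = 0.95, match_tolerance = 0.01,
                              outdir = NULL) {
  warnings_log <- character()
  catching <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  tl <- if (is.character(tielines))
    catching(read_tielines(tielines, tolerance = closure_tolerance))
  else catching(as_tielines(tielines, tolerance = closure_tolerance))

  lever <- lever_rule_check(tl, tolerance = lever_tolerance)
  ot <- catching(fit_othmer_tobias(tl, r2_threshold = r2_threshold))
  ba <- catching(fit_bancroft(tl, r2_threshold = r2_threshold))
  se <- catching(fit_setschenow(tl, polymer = polymer, salt = salt))

  report <- list(
    tielines = as.data.frame(tl),
    lever_rule = as.data.frame(lever),
    consistency = list(othmer_tobias = ot, bancroft = ba, setschenow = se))

  if (!is.null(binodal)) {
    pts <- if (is.character(binodal)) read_binodal(binodal)
           else as.data.frame(binodal)
    report$binodal <- list(merchuk = fit_binodal(pts, "merchuk"),
                           zm = fit_binodal(pts, "zm"))
  }

  if (!is.null(partition)) {
    pdf <- if (is.character(partition)) read_partition(partition)
           else as.data.frame(partition)
    recs <- partition_records(pdf, tielines = tl,
                              match_tolerance = match_tolerance)
    drugs <- unique(recs$drug)
    fits <- lapply(drugs, function(d) {
      sub <- recs[recs$drug == d, ]
      list(diamond_hsu = fit_diamond_hsu(sub),
           modified = fit_diamond_hsu(sub, modified = TRUE))
    })
    names(fits) <- drugs
    ranked <- if (all(drugs %in% names(log_kow)))
      rank_drugs_by_hydrophobicity(recs, log_kow) else NULL
    report$partitioning <- list(records = as.data.frame(recs), fits = fits,
                                ranking = ranked)
  }

  report$warnings <- warnings_log
  report$pass <- all(lever$pass) && ot$consistent && ba$consistent &&
    (is.null(report$partitioning$ranking) ||
       report$partitioning$ranking$verdict == "consistent")
  class(report) <- "atps_report"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(outdir, "report.json"))
    write_report_md(report, file.path(outdir, "report.md"))
  }
  report
}

#' @export
print.atps_report <- function(x, ...) {
  cat("ATPS liquid-liquid equilibrium report\n")
  cat(sprintf("  tie-lines: %d, TLL %.2f - %.2f wt%%\n", nrow(x$tielines),
              min(x$tielines$tll), max(x$tielines$tll)))
  cat(sprintf("  lever rule: %d/%d pass (max deviation %.3f wt%%)\n",
              sum(x$lever_rule$pass), nrow(x$lever_rule),
              max(x$lever_rule$max_deviation)))
  for (nm in names(x$consistency)) {
    f <- x$consistency[[nm]]
    cat(sprintf("  %s: %s, sd = %.4g%s\n", nm,
                paste(names(f$coefficients), "=",
                      signif(f$coefficients, 4), collapse = ", "),
                f$sd,
                if (!is.null(f$r_squared))
                  sprintf(", r^2 = %.4f", f$r_squared) else ""))
  }
  if (!is.null(x$binodal))
    for (nm in names(x$binodal))
      cat(sprintf("  binodal %s: sd = %.4g wt%%\n", nm, x$binodal[[nm]]$sd))
  if (!is.null(x$partitioning)) {
    for (d in names(x$partitioning$fits)) {
      f <- x$partitioning$fits[[d]]
      cat(sprintf("  %s: sd(ln K) = %.4g (Diamond-Hsu) / %.4g (modified)\n",
                  d, f$diamond_hsu$sd, f$modified$sd))
    }
    if (!is.null(x$partitioning$ranking))
      cat("  hydrophobicity ordering:", x$partitioning$ranking$verdict, "\n")
  }
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see $warnings)\n")
  cat("  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

fit_to_list_ <- function(f) {
  out <- list(params = as.list(f$coefficients), sd = f$sd,
              n_points = f$gof$n_points)
  if (!is.null(f$r_squared)) {
    out$r_squared <- f$r_squared
    out$verdict <- if (f$consistent) "consistent" else "inconsistent"
  }
  out
}

#' Serialise an analysis report to JSON
#'
#' @param report An `"atps_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "atps_report"))
  out <- list(
    tielines = report$tielines,
    lever_rule = report$lever_rule,
    consistency = lapply(report$consistency, fit_to_list_),
    warnings = report$warnings,
    pass = report$pass)
  if (!is.null(report$binodal))
    out$binodal <- lapply(report$binodal, fit_to_list_)
  if (!is.null(report$partitioning)) {
    out$partitioning <- list(
      records = report$partitioning$records,
      fits = lapply(report$partitioning$fits,
                    function(f) lapply(f, fit_to_list_)))
    if (!is.null(report$partitioning$ranking))
      out$partitioning$ranking <- list(
        summary = report$partitioning$ranking$summary,
        verdict = report$partitioning$ranking$verdict)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a human-readable markdown summary of a report
#'
#' @param report An `"atps_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_md <- function(report, path) {
  stopifnot(inherits(report, "atps_report"))
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# ATPS liquid-liquid equilibrium report")
  w("")
  w("## Tie-lines (wt%%)")
  utils::write.table(format(report$tielines, digits = 5), con, sep = " | ",
                     row.names = FALSE, quote = FALSE)
  w("")
  w("Lever rule: %d/%d pass, max deviation %.3f wt%%.",
    sum(report$lever_rule$pass), nrow(report$lever_rule),
    max(report$lever_rule$max_deviation))
  w("")
  w("## Consistency correlations")
  for (nm in names(report$consistency)) {
    f <- report$consistency[[nm]]
    w("- %s: %s; sd = %.4g%s", nm,
      paste(names(f$coefficients), "=", signif(f$coefficients, 5),
            collapse = ", "),
      f$sd,
      if (!is.null(f$r_squared)) sprintf("; r^2 = %.4f (%s)", f$r_squared,
        if (f$consistent) "consistent" else "inconsistent") else "")
  }
  if (!is.null(report$binodal)) {
    w(""); w("## Binodal fits")
    for (nm in names(report$binodal)) {
      f <- report$binodal[[nm]]
      w("- %s: %s; sd = %.4g wt%%", nm,
        paste(names(f$coefficients), "=", signif(f$coefficients, 5),
              collapse = ", "), f$sd)
    }
  }
  if (!is.null(report$partitioning)) {
    w(""); w("## Drug partitioning")
    for (d in names(report$partitioning$fits)) {
      f <- report$partitioning$fits[[d]]
      w("- %s: Diamond-Hsu sd(ln K) = %.4g; modified sd(ln K) = %.4g",
        d, f$diamond_hsu$sd, f$modified$sd)
    }
    if (!is.null(report$partitioning$ranking))
      w("- hydrophobicity ordering: %s", report$partitioning$ranking$verdict)
  }
  if (length(report$warnings)) {
    w(""); w("## Warnings")
    for (msg in report$warnings) w("- %s", msg)
  }
  w(""); w("Overall: %s", if (report$pass) "PASS" else "FAIL")
  invisible(path)
}
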