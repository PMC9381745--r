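#' Experimental tie-line data for the PEG600 + KOH + water system
#'
#' Five measured tie-lines of the aqueous two-phase system formed by
#' poly(ethylene glycol) of nominal molar mass 600 g/mol and potassium
#' hydroxide at 298.15 K and ambient pressure (~85 kPa), shipped as a
#' plain-text CSV under `extdata`. Columns are overall / PEG-rich (top) /
#' salt-rich (bottom) phase compositions in wt% (water by difference) plus
#' the reported tie-line length. The reported standard uncertainty of each
#' component's weight percent is 0.8.
#'
#' @param reported_tll Keep the reported `tll` column (`tll_reported`)
#'   alongside the recomputed one; default TRUE.
#' @return A `"tielines"` data frame with 5 rows (see [as_tielines()]).
#' @examples
#' peg600_koh_tielines()
#' @export
peg600_koh_tielines <- function(reported_tll = TRUE) {
  path <- system.file("extdata", "peg600_koh_tielines.csv", package = "atps",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- as_tielines(df[, setdiff(names(df), "tll")])
  if (reported_tll) out$tll_reported <- df$tll
  out
}

#' Experimental drug-partitioning data for the PEG600 + KOH ATPS
#'
#' Measured partition coefficients `K` and reported extraction
#' efficiencies of ibuprofen and acetaminophen in the PEG600 + KOH + water
#' ATPS at 298.15 K, at the same five overall compositions as
#' [peg600_koh_tielines()]. The reported standard uncertainty of K is
#' 0.15. Octanol-water log K_ow values for these drugs are 3.97
#' (ibuprofen) and 2.34 (acetaminophen).
#'
#' @return A data frame with columns `drug`, `overall_ws`, `overall_wp`,
#'   `K`, `EE_reported`; pass through [partition_records()] to derive
#'   `EE` and match tie-lines.
#' @examples
#' head(peg600_koh_partition())
#' @export
peg600_koh_partition <- function() {
  path <- system.file("extdata", "peg600_koh_partition.csv", package = "atps",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference log K_ow values for the packaged drugs
#'
#' @return Named numeric vector of octanol-water log K_ow.
#' @export
peg600_koh_log_kow <- function() c(ibuprofen = 3.97, acetaminophen = 2.34)
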