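#' Ternary composition in mass percent
#'
#' A `composition` is a (polymer, salt, water) mass-fraction triple in wt%
#' (0-100), the unit of all equilibrium data in the package. When `w_w` is
#' omitted it is computed by difference, the usual convention for tie-line
#' tables that omit the water column.
#'
#' @param w_p Polymer mass fraction, wt% (0-100).
#' @param w_s Salt mass fraction, wt% (0-100).
#' @param w_w Water mass fraction, wt%; default `100 - w_p - w_s`.
#' @param tolerance Closure tolerance in wt%: the triple must sum to 100
#'   within `2 * tolerance` (hard error), and a closure residual larger
#'   than `tolerance` raises a warning. The default 0.5 wt% reflects the
#'   typical reported component uncertainty (~0.8 wt%) of gravimetric /
#'   photometric phase analysis.
#' @return An object of class `"composition"`: a named numeric vector with
#'   elements `w_p`, `w_s`, `w_w` and attribute `closure` (the signed
#'   closure residual `w_p + w_s + w_w - 100`).
#' @examples
#' composition(w_p = 28.98, w_s = 17.58)        # water by difference
#' composition(0, 0, 100)                        # pure water
#' @seealso [validate_composition()], [mass_fraction_to_molality()]
#' @export
composition <- function(w_p, w_s, w_w = 100 - w_p - w_s, tolerance = 0.5) {
  c0 <- structure(c(w_p = as.numeric(w_p), w_s = as.numeric(w_s),
                    w_w = as.numeric(w_w)),
                  class = "composition")
  validate_composition(c0, tolerance = tolerance)
}

#' Validate a ternary composition
#'
#' Checks the range invariant (each component in \[0, 100\]) and the closure
#' invariant (components sum to 100 wt%). Closure residuals up to
#' `tolerance` pass silently, residuals in `(tolerance, 2 * tolerance]`
#' warn, and anything larger is an error.
#'
#' @param x A `"composition"` or a numeric vector of length 3
#'   `(w_p, w_s, w_w)` in wt%.
#' @param tolerance Closure tolerance, wt%.
#' @return `x` as a validated `"composition"`, with the signed closure
#'   residual stored in attribute `closure`.
#' @export
validate_composition <- function(x, tolerance = 0.5) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x))
    stop("composition must be 3 finite numeric values (w_p, w_s, w_w)")
  names(x) <- c("w_p", "w_s", "w_w")
  if (any(x < 0) || any(x > 100))
    stop("composition components must lie in [0, 100] wt%; got (",
         paste(signif(x, 6), collapse = ", "), ")")
  closure <- sum(x) - 100
  if (abs(closure) > 2 * tolerance)
    stop(sprintf("composition closure violation: components sum to %.4f wt%% (tolerance %.2f)",
                 sum(x), tolerance))
  if (abs(closure) > tolerance)
    warning(sprintf("composition closure residual %.4f wt%% exceeds tolerance %.2f",
                    closure, tolerance))
  structure(x, class = "composition", closure = closure)
}

#' @export
print.composition <- function(x, digits = 4, ...) {
  cat(sprintf("composition (wt%%): polymer %.*g, salt %.*g, water %.*g\n",
              digits, x[["w_p"]], digits, x[["w_s"]], digits, x[["w_w"]]))
  invisible(x)
}

#' Chemical species metadata
#'
#' @param name Species identifier.
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @return An object of class `"species"`.
#' @examples
#' species("PEG600", 600)
#' species("KOH", 56.11)
#' @export
species <- function(name, molar_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L ||
      !is.finite(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be a single positive number (g/mol)")
  structure(list(name = name, molar_mass = as.numeric(molar_mass)),
            class = "species")
}

# Package-default species for the PEG600 + KOH system.
#' Default species: PEG with nominal molar mass 600 g/mol
#' @return A `"species"` object.
#' @export
peg600 <- function() species("PEG600", 600)

#' Default species: potassium hydroxide, 56.11 g/mol
#' @return A `"species"` object.
#' @export
koh <- function() species("KOH", 56.11)

#' Convert a mass fraction to molality
#'
#' Molality is taken as moles of solute per kilogram of *water* in the same
#' phase (not per kg of solution), the usual basis of Setschenow-type
#' salting-out correlations. Per 100 g of solution, `w_solute` grams of
#' solute dissolve in `w_water` grams of water, so
#' `m = (w_solute / M) / (w_water / 1000)` mol/kg.
#'
#' @param w_solute Solute mass fraction, wt%.
#' @param w_water Water mass fraction, wt%; must be positive.
#' @param species A [species()] carrying the solute molar mass.
#' @return Molality in mol/kg water. Vectorised over `w_solute`/`w_water`.
#' @examples
#' mass_fraction_to_molality(5.61, 94.39, species("KOH", 56.1))  # 1.0594
#' mass_fraction_to_molality(60, 40, peg600())                   # 2.5
#' @export
mass_fraction_to_molality <- function(w_solute, w_water, species) {
  stopifnot(inherits(species, "species"))
  if (any(!is.finite(w_water)) || any(w_water <= 0))
    stop("w_water must be positive (wt%)")
  1000 * w_solute / (species$molar_mass * w_water)
}

#' Inverse of [mass_fraction_to_molality()]
#'
#' @param molality Molality, mol/kg water.
#' @param w_water Water mass fraction, wt%.
#' @param species A [species()].
#' @return Solute mass fraction in wt%.
#' @export
molality_to_mass_fraction <- function(molality, w_water, species) {
  stopifnot(inherits(species, "species"))
  if (any(!is.finite(w_water)) || any(w_water <= 0))
    stop("w_water must be positive (wt%)")
  molality * species$molar_mass * w_water / 1000
}

#' Scale helpers between wt% (0-100) and mass fraction (0-1)
#'
#' Compositions are stored and fitted in wt%; a few correlations
#' (Othmer-Tobias, Bancroft, refractometry) are defined on the fractional
#' scale, where terms like `1 - w` are meaningful.
#'
#' @param w Numeric vector.
#' @return The rescaled vector.
#' @export
wt_to_frac <- function(w) w / 100

#' @rdname wt_to_frac
#' @export
frac_to_wt <- function(w) w * 100

#' Root-mean-square goodness of fit
#'
#' The standard deviation reported with every correlation in the package:
#' `sd = sqrt(sum((obs - pred)^2) / n)`, i.e. the RMS residual with divisor
#' `n` (the convention of the ATPS correlation literature), in the units of
#' the fitted variable.
#'
#' @param observed,predicted Equal-length numeric vectors, `n >= 1`.
#' @return An object of class `"gof"`: list with `sd`, `n_points` and the
#'   signed `residuals` (observed - predicted).
#' @examples
#' compute_sd(c(1, 2), c(0, 2))  # sd = sqrt(0.5)
#' @export
compute_sd <- function(observed, predicted) {
  if (length(observed) == 0L)
    stop("compute_sd: empty input")
  if (length(observed) != length(predicted))
    stop("compute_sd: observed and predicted lengths differ (",
         length(observed), " vs ", length(predicted), ")")
  if (anyNA(observed) || anyNA(predicted))
    stop("compute_sd: missing values in input")
  res <- observed - predicted
  structure(list(sd = sqrt(mean(res^2)), n_points = length(res),
                 residuals = res),
            class = "gof")
}

#' @export
print.gof <- function(x, ...) {
  cat(sprintf("goodness of fit: sd = %.6g over %d points\n", x$sd, x$n_points))
  invisible(x)
}
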