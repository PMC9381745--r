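---
title: "Models and methods for polymer-salt ATPS equilibrium analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for polymer-salt ATPS equilibrium analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atps)
```

## The system and the data

An aqueous two-phase system (ATPS) forms when a hydrophilic polymer and a
kosmotropic salt are dissolved together in water above a critical
composition: the mixture demixes into a polymer-rich *top* phase and a
salt-rich *bottom* phase, both still mostly water. The package analyses
isothermal equilibrium measurements of such systems — the packaged example
is PEG of nominal molar mass 600 g/mol with KOH at 298.15 K — through four
connected stages:

1. **Binodal curve**: the boundary between the one-phase and two-phase
   regions in the (salt, polymer) composition plane, measured as cloud
   points and summarised by empirical correlations.
2. **Tie-lines**: the compositions of coexisting phases for mixtures
   inside the two-phase region, characterised by their length and tested
   for internal consistency.
3. **Refractometry**: conversion of refractive-index readings into
   polymer content, given an independently assayed salt content.
4. **Drug partitioning**: partition coefficients and extraction
   efficiencies of solutes spiked into the mixtures, correlated against
   the phase-composition difference.

All compositions are mass fractions in wt% (0-100). The two consistency
correlations that involve `1 - w` terms, and the refractometric
calibration, work internally on the fractional (0-1) scale, where those
expressions are meaningful; conversion happens at the interface.

## Binodal correlations

Two standard empirical forms are fitted to binodal points
$(w_s, w_p)$:

* the Merchuk exponential form
  $w_p = a\,\exp(b\,w_s^{0.5} - c\,w_s^3)$, fitted by
  Levenberg-Marquardt nonlinear least squares; and
* the Zafarani-Moattar log-linear form
  $w_p = \alpha + \beta \ln w_s + \gamma w_s$, which is linear in its
  coefficients and solved exactly by least squares.

Both are fitted on the wt% scale, minimising
$\sum (w_{p,\mathrm{obs}} - w_{p,\mathrm{pred}})^2$. The Merchuk start
is $a_0 = \max w_p$ (the amplitude is the curve extrapolated to zero
salt), $b_0 = -0.3$, $c_0 = 10^{-5}$; if the default start fails, up to
four deterministically jittered restarts are tried and the best
converged solution kept. Tolerances are tight (relative 1e-10, 10 000
evaluations) because the curve is smooth and each evaluation is cheap.
No parameter bounds are imposed by default — the sign pattern of a
fitted binodal is a diagnostic, not a constraint — but bounds (e.g.
$a > 0$) can be passed through `fit_binodal()`.

Every fit reports `sd`, the root-mean-square residual with divisor $n$
(not $n - 1$), in the units of the fitted variable. This is the
goodness-of-fit convention of the ATPS correlation literature; the
choice of divisor is stated here because conventions differ across
fields.

## Tie-line characterisation

The tie-line length
$TLL = \sqrt{(w_p^{top} - w_p^{bot})^2 + (w_s^{top} - w_s^{bot})^2}$
measures phase dissimilarity in wt%. The lever rule requires the
overall composition to lie on the segment joining the phases; the check
computes the top-phase mass fraction $\phi$ from each component
separately (`overall = phi*top + (1-phi)*bottom`) and the perpendicular
distance of the overall point from the segment, passing when that
distance is within tolerance. The default tolerance, 0.8 wt%, is the
component measurement uncertainty of the packaged dataset. Note that
$\phi$ is the *top*-phase fraction: an overall point lying closer to
the bottom-phase composition has $\phi < 0.5$.

Three consistency correlations are fitted:

* **Othmer-Tobias**:
  $(1 - w_p^{top})/w_p^{top} = k\,[(1 - w_s^{bot})/w_s^{bot}]^n$,
* **Bancroft**:
  $w_w^{bot}/w_s^{bot} = k_1\,(w_w^{top}/w_p^{top})^r$,
* **Setschenow**:
  $\ln(C_p^{top}/C_p^{bot}) = k_p + k_s\,(C_s^{bot} - C_s^{top})$.

The first two are fitted by ordinary least squares in base-10 log-log
space, exactly as the consistency plot is constructed; near-linearity
of that plot (high $r^2$) is the classical evidence that a tie-line set
is internally consistent. Because "acceptable linearity" is qualitative,
the package applies a configurable numeric gate, $r^2 \ge 0.95$ by
default, to produce a reproducible verdict. The reported `sd` for these
two fits is computed on the back-transformed left-hand-side ratio, so
it is comparable across datasets regardless of the logarithm base used
in fitting. Water fractions are taken by difference
($w_w = 100 - w_p - w_s$), since tie-line tables conventionally omit
the water column. Natural log is used for Setschenow, base-10 for the
other two, following the standard notation of each correlation.

### The Setschenow molality basis

Molality here is moles of solute per kilogram of *water in that phase*,
the standard salting-out basis. This choice has a real consequence: in
strongly asymmetric systems the polymer-rich top phase can be so
water-poor that its salt molality per kg water *exceeds* the bottom
phase's even though its salt mass fraction is far lower. On the
packaged measurements the regressor $C_s^{bot} - C_s^{top}$ is then
non-monotone across the series and the fitted slope $k_s$ comes out
negative — the opposite sign from what a salting-out description
expects. The fitter therefore warns whenever $k_s \le 0$ rather than
failing: the fit is still a valid least-squares summary, but the
warning flags that the correlation is not behaving as a salting-out
law on this basis. (On a per-kg-solution basis the same data give a
positive slope with high $r^2$; the package keeps the per-kg-water
convention and surfaces the anomaly instead of silently switching
bases.)

## Refractometry

For dilute polymer + salt solutions the refractive index is linear in
both mass fractions, $n_D = n_0 + a_p w_p + a_s w_s$, with $n_0$ the
measured refractive index of pure water (default 1.3325 at 298.15 K).
Calibration regresses $(n_D - n_0)$ on $w$ through the origin — the
intercept is fixed by the model, not estimated — one dilution series
per solute. Inversion solves the same equation for $w_p$ given a
reading and the independently assayed salt content. Readings outside
the calibrated span produce warnings, not errors, because equilibrium
phases are always diluted before measurement; the applied dilution
factor rescales the result. Exact zeros are exempt from the range
check, since a through-origin model is exact at zero by construction.

## Drug partitioning

The partition coefficient is $K = w^{top}_{drug} / w^{bot}_{drug}$ and
the extraction efficiency $EE\% = 100\,K/(K+1)$, a strictly monotone
bijection from $(0, \infty)$ onto $(0, 100)$. Partition records are
matched to tie-lines by identical overall composition (tolerance
0.01 wt%), which supplies each record's
$\Delta w(\mathrm{PEG}) = w_p^{top} - w_p^{bot} > 0$.

Two correlations of $\ln K$ against $\Delta w$ are provided, fitted per
drug by closed-form least squares:

* Diamond-Hsu: $\ln K = A\,\Delta w + B\,\Delta w^2$ (no intercept, so
  $\Delta w = 0$ forces $K = 1$: identical phases cannot discriminate a
  solute);
* the modified three-parameter form:
  $\ln K = A_1 + B_1\,\Delta w + C_1\,\Delta w^2$.

The modified form nests the original, so on identical records its RMS
residual can never exceed the original's — a structural property the
test suite asserts on both measured and synthetic data.

Partitioning into the polymer-rich phase tracks solute hydrophobicity.
`rank_drugs_by_hydrophobicity()` orders drugs by mean EE and checks the
ordering against supplied octanol-water log $K_{ow}$ values, both on
means and composition-wise.

## The synthetic-data generator

`sim_config()` fixes a ground truth and noise model from which all
stages can be generated:

* **Binodal**: a Merchuk truth ($a = 1100$, $b = -0.95$,
  $c = 5\times10^{-6}$) sampled on a grid of 20 points over
  $w_s \in [8, 32]$ wt% with additive Gaussian noise of sd 0.3 wt%.
  These values were chosen to reproduce the packaged system's scales —
  roughly 75 wt% polymer at 8 wt% salt falling to ~6 wt% at 30 wt% —
  and the composition uncertainty of the measurements; the noise is
  treated as absolute, not relative.
* **Tie-lines**: five lines whose endpoints sit exactly on the truth
  binodal at anchor salt fractions (top 9.8 down to 8.8 wt%, bottom 21
  up to 29 wt%), with the overall composition placed on the segment at
  a lever fraction uniform in [0.3, 0.7]. Anchors move in opposite
  directions so that TLL and $\Delta w$ both grow along the series, as
  they do in real tie-line tables. Two exact modes ("othmer_tobias",
  "setschenow") instead back-solve the top-phase polymer content so the
  respective correlation holds exactly — binodal-constrained tie-lines
  need not satisfy either correlation exactly, so these modes exist for
  recovery oracles. The Setschenow construction solves a
  one-dimensional root problem per line; the objective is monotone in
  $w_p^{top}$, so the root is unique.
* **Partitioning**: $\ln K$ drawn from a per-drug Diamond-Hsu truth
  plus Gaussian ln-scale noise (sd 0.015, corresponding to an absolute
  K uncertainty of about 0.15 at this system's typical $K \approx 10$;
  ln-scale noise keeps K positive). Phase concentrations are
  back-solved so the total spiked drug mass fraction is exactly 0.002
  under the lever-rule phase split.
* **Refractometry**: the linear model with $a_p = 0.14$, $a_s = 0.12$
  per unit mass fraction — typical magnitudes for polymer and
  inorganic-salt refractive-index increments — and instrument noise
  0.0002, the stated precision class of bench refractometers.

One integer seed drives a separate derived stream per stage, so each
stage is reproducible independently; generators restore the caller's
RNG state. What the generator does *not* emulate: titration kinetics,
instrument drift, correlated composition errors between phases, or
closure violations — real data can fail validation in ways synthetic
data never will, so passing recovery tests demonstrates estimator
correctness, not robustness to every laboratory pathology.

## Recovery benchmarking

`recovery_benchmark()` measures estimator calibration: 200 Monte-Carlo
replicates per model, each fitted and wrapped in a studentized
residual-bootstrap (bootstrap-t) 95% interval, recording how often the
interval covers the generating truth. Numerical choices that matter:

* residuals are rescaled by $\sqrt{n/(n-p)}$ before resampling (raw
  least-squares residuals underestimate the error variance);
* each resampled estimate is studentized by its own standard error —
  from $(X'X)^{-1}$ for the linear fits, from the numerical Jacobian
  for the Merchuk fit — making the interval second-order accurate,
  which matters at the small $n$ of equilibrium series;
* the Merchuk amplitude $a$ is handled on the log scale (delta-method
  standard error), since it is a positive scale parameter extrapolated
  well outside the sampled salt range and its sampling distribution is
  right-skewed;
* 499 bootstrap resamples per replicate keep the $t$-quantile noise
  small relative to the interval width.

Problem sizes used by the packaged benchmark runs: 20 binodal points
for the Merchuk and Zafarani-Moattar benchmarks and 10 tie-lines for
the Diamond-Hsu benchmark. Ten was chosen over the five lines typical
of a single measured series because two-parameter interval calibration
degrades noticeably below ~10 observations; the benchmark measures
estimator calibration at a design where calibration is attainable,
while the generator's default of five tie-lines remains the emulated
study condition.

## Degenerate inputs and tie-breaks

* Compositions must sum to 100 wt% within twice the closure tolerance
  (default 0.5 wt%, reflecting ~0.8 wt% component uncertainty); the
  band between one and two tolerances warns.
* Tie-line tables with mislabelled phases (top not polymer-rich) are
  swapped with a warning rather than rejected — column-order mistakes
  are the common failure mode of hand-assembled CSVs.
* Consistency fits refuse compositions of exactly 0 or 100 wt% (log
  singularities) and all-identical tie-lines (degenerate regressor).
* The Merchuk fit refuses fewer than 4 points or fewer than 3 distinct
  salt values; constant data converge to $a = \bar w_p$, $b = c = 0$.
* `compute_sd` of a perfect fit is exactly 0; empty or mismatched
  vectors are errors, never silently recycled.

## Limitations

The package is deliberately empirical: no activity-coefficient or
Gibbs-energy model (NRTL, UNIQUAC), no temperature dependence, no
prediction of tie-lines from the binodal alone, and no structure-based
prediction of partition coefficients. The correlations summarise and
consistency-check measured equilibria; they do not extrapolate beyond
the measured composition range, and the Setschenow discussion above
shows why a correlation's parameters should be read together with the
convention they were fitted under.
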