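## uptake: Beer-Lambert solution-depletion quantification, loading <->
## concentration conversions, equilibration detection, and standard BET /
## Dubinin-Radushkevich isotherm linearizations.

#' Formula unit of the desolvated host framework
#'
#' Element counts per formula unit of the bio-MOF host:
#' Zn1.5 O0.25 (adeninate C5H4N5) (half TBAPy(4-) C44H22O8), optionally
#' including the charge-balancing half dimethylammonium cation (C2H8N) —
#' the composition used for elemental analysis.
#'
#' @param cation include the half charge-balancing cation (default TRUE).
#' @return named numeric vector, element -> count per formula unit.
#' @examples
#' sum(sion19FormulaUnit() * atomicWeight(names(sion19FormulaUnit())))
#' @export
sion19FormulaUnit <- function(cation = TRUE) {
  f <- c(Zn = 1.5, O = 0.25 + 8 / 2, C = 5 + 44 / 2, H = 4 + 22 / 2, N = 5)
  if (cation) f <- f + c(Zn = 0, O = 0, C = 0.5 * 2, H = 0.5 * 8, N = 0.5)
  f
}

#' Beer-Lambert absorbance to molar concentration
#'
#' \eqn{c = A / (\epsilon \ell)}. The default molar absorption coefficient
#' is that of thymine in EtOH:MeCN at 263 nm.
#'
#' @param A absorbance (dimensionless, >= 0).
#' @param epsilon molar absorption coefficient, 1/(cm M) (default 8217).
#' @param pathLength optical path length, cm (default 1).
#' @return concentration in mol/L.
#' @examples
#' absorbanceToConcentration(0.8217)  # 1e-4 M
#' @export
absorbanceToConcentration <- function(A, epsilon = 8217, pathLength = 1) {
  stopifnot(epsilon > 0, pathLength > 0)
  if (any(A < 0)) stop("absorbance must be non-negative")
  A / (epsilon * pathLength)
}

#' Inverse Beer-Lambert: concentration to absorbance
#' @param conc concentration in mol/L.
#' @inheritParams absorbanceToConcentration
#' @return absorbance.
#' @export
concentrationToAbsorbance <- function(conc, epsilon = 8217, pathLength = 1) {
  stopifnot(epsilon > 0, pathLength > 0)
  conc * epsilon * pathLength
}

#' Loading percentage to solution concentration
#'
#' Linear map: `loading/100 * cAt100`, the concentration that fills the
#' host to the given fraction of its theoretical capacity.
#'
#' @param loadingPercent loading in (0, 100].
#' @param cAt100 concentration corresponding to 100% loading, mol/L
#'   (default 2.80e-4).
#' @return concentration in mol/L.
#' @examples
#' loadingToConcentration(20)  # 0.56e-4
#' @export
loadingToConcentration <- function(loadingPercent, cAt100 = 2.80e-4) {
  stopifnot(all(loadingPercent > 0), all(loadingPercent <= 100), cAt100 > 0)
  loadingPercent / 100 * cAt100
}

#' Solution-depletion uptake in guest molecules per formula unit
#'
#' Guest moles removed from solution, `(c0 - cFinal) * volume`, divided by
#' the moles of host formula units, `mass / fuMolarMass`. The final
#' concentration comes from the supernatant absorbance via Beer-Lambert.
#' Negative depletion (final above initial) is flagged with a warning, not
#' clipped.
#'
#' @param initialConcentration c0, mol/L.
#' @param finalAbsorbance supernatant absorbance after equilibration.
#' @param solutionVolume L.
#' @param sorbentMass g (> 0).
#' @param fuMolarMass molar mass of one formula unit, g/mol; default the
#'   desolvated host including the charge-balancing cation
#'   ([sion19FormulaUnit()]).
#' @param epsilon,pathLength Beer-Lambert parameters.
#' @return molecules of guest per formula unit.
#' @export
depletionToMoleculesPerFU <- function(initialConcentration, finalAbsorbance,
                                      solutionVolume, sorbentMass,
                                      fuMolarMass = NULL,
                                      epsilon = 8217, pathLength = 1) {
  stopifnot(initialConcentration > 0, solutionVolume > 0)
  if (sorbentMass <= 0) stop("sorbent mass must be positive")
  if (is.null(fuMolarMass)) {
    f <- sion19FormulaUnit()
    fuMolarMass <- sum(f * atomicWeight(names(f)))
  }
  cFinal <- absorbanceToConcentration(finalAbsorbance, epsilon, pathLength)
  if (cFinal > initialConcentration)
    warning("final concentration exceeds initial (negative depletion)")
  (initialConcentration - cFinal) * solutionVolume /
    (sorbentMass / fuMolarMass)
}

#' Time to reach sorption equilibrium from an absorbance series
#'
#' Returns the first time point after which every subsequent relative
#' absorbance change stays below the tolerance; `NA` ("not reached") when
#' no such point exists.
#'
#' @param time numeric vector of times (hours), strictly increasing,
#'   length >= 3.
#' @param absorbance matching absorbance readings.
#' @param tolerance maximum relative step-to-step change at equilibrium
#'   (default 0.01, i.e. 1%).
#' @return equilibration time in the units of `time`, or `NA_real_`.
#' @export
equilibrationTime <- function(time, absorbance, tolerance = 0.01) {
  stopifnot(length(time) == length(absorbance), length(time) >= 3)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  rel <- abs(diff(absorbance)) / pmax(abs(absorbance[-length(absorbance)]),
                                      .Machine$double.eps)
  ## rel[i] is the change entering point i+1; find first i with all later
  ## changes quiet
  quiet <- rev(cumprod(rev(rel < tolerance))) > 0
  if (!any(quiet)) return(NA_real_)
  time[which(quiet)[1]]
}

.to_mmol <- function(q, unit) switch(unit,
  "mmol/g" = q,
  "cm3STP/g" = q / 22.414,
  stop("unknown quantity unit: ", unit))

#' BET surface area from an adsorption isotherm
#'
#' Standard BET linearization: a least-squares line through
#' \eqn{x/(n(1-x))} versus \eqn{x = p/p_0} over the fit range gives the
#' monolayer capacity \eqn{n_m = 1/(slope+intercept)} and the BET constant
#' \eqn{C = slope/intercept + 1}; the area follows from the adsorbate
#' cross-section.
#'
#' @param relativePressure p/p0 values in (0, 1).
#' @param quantityAdsorbed adsorbed amounts, matching length.
#' @param fitRange p/p0 interval used for the fit (default c(0.05, 0.30)).
#' @param crossSection adsorbate cross-sectional area, A^2 (N2 default 16.2).
#' @param quantityUnit "mmol/g" or "cm3STP/g".
#' @return list: `surfaceArea` (m^2/g), `monolayerCapacity` (mmol/g), `C`,
#'   `r2`, `valid` (FALSE when C <= 0, flagging an invalid fit).
#' @export
betSurfaceArea <- function(relativePressure, quantityAdsorbed,
                           fitRange = c(0.05, 0.30), crossSection = 16.2,
                           quantityUnit = c("mmol/g", "cm3STP/g")) {
  quantityUnit <- match.arg(quantityUnit)
  stopifnot(length(relativePressure) == length(quantityAdsorbed))
  n <- .to_mmol(quantityAdsorbed, quantityUnit)
  keep <- relativePressure >= fitRange[1] & relativePressure <= fitRange[2] &
    n > 0
  if (sum(keep) < 3) stop("fewer than 3 isotherm points in the fit range")
  x <- relativePressure[keep]
  y <- x / (n[keep] * (1 - x))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
  nm <- 1 / (slope + icpt)
  C <- slope / icpt + 1
  area <- nm * 1e-3 * .N_AVOGADRO * crossSection * 1e-20
  list(surfaceArea = area, monolayerCapacity = nm, C = C,
       r2 = suppressWarnings(summary(fit)$r.squared),
       valid = is.finite(C) && C > 0)
}

#' Dubinin-Radushkevich micropore volume from an adsorption isotherm
#'
#' Standard D-R linearization: a least-squares line through
#' \eqn{\log_{10} n} versus \eqn{\log_{10}^2(p_0/p)} over the fit range;
#' the intercept gives the limiting micropore uptake, converted to liquid
#' volume with the adsorbate molar volume.
#'
#' @inheritParams betSurfaceArea
#' @param fitRange p/p0 interval (default c(1e-5, 0.1), the low-pressure
#'   micropore-filling regime).
#' @param molarVolume liquid molar volume of the adsorbate, cm^3/mol
#'   (N2 default 34.67).
#' @return list: `poreVolume` (cm^3/g), `limitingUptake` (mmol/g), `slope`,
#'   `r2`.
#' @export
drPoreVolume <- function(relativePressure, quantityAdsorbed,
                         fitRange = c(1e-5, 0.1), molarVolume = 34.67,
                         quantityUnit = c("mmol/g", "cm3STP/g")) {
  quantityUnit <- match.arg(quantityUnit)
  stopifnot(length(relativePressure) == length(quantityAdsorbed))
  n <- .to_mmol(quantityAdsorbed, quantityUnit)
  keep <- relativePressure >= fitRange[1] & relativePressure <= fitRange[2] &
    n > 0 & relativePressure < 1
  if (sum(keep) < 3) stop("fewer than 3 isotherm points in the fit range")
  x <- log10(1 / relativePressure[keep])^2
  y <- log10(n[keep])
  fit <- stats::lm(y ~ x)
  n0 <- 10^unname(stats::coef(fit)[1])
  list(poreVolume = n0 * 1e-3 * molarVolume,
       limitingUptake = n0, slope = unname(stats::coef(fit)[2]),
       r2 = suppressWarnings(summary(fit)$r.squared))
}

#' Forward-generate a synthetic adsorption isotherm
#'
#' Langmuir/BET-form or D-R-form isotherms with known parameters, for
#' validating the fitting routines (experimental raw isotherms are not
#' reproduced here).
#'
#' @param relativePressure p/p0 grid.
#' @param model "langmuir", "bet" or "dr".
#' @param nm monolayer (or limiting) capacity, mmol/g.
#' @param C Langmuir/BET constant.
#' @param D D-R slope magnitude (log10 units).
#' @return numeric vector of adsorbed quantities, mmol/g.
#' @export
syntheticIsotherm <- function(relativePressure,
                              model = c("langmuir", "bet", "dr"),
                              nm = 5, C = 100, D = 0.05) {
  model <- match.arg(model)
  x <- relativePressure
  switch(model,
         langmuir = nm * C * x / (1 + C * x),
         bet = nm * C * x / ((1 - x) * (1 + (C - 1) * x)),
         dr = 10^(log10(nm) - D * log10(1 / x)^2))
}
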