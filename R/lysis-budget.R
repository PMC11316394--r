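#' Bacterial growth yield per lysed algal cell
#'
#' From a lysate growth experiment: `(CFU in lysate - baseline CFU) /
#' lysed algal density`. When replicate vectors are supplied the
#' replicate spread is propagated to a standard deviation of the yield; a
#' one-significant-figure headline value is reported alongside full
#' precision, mirroring the "roughly" usage such estimates warrant.
#'
#' @param cfuInLysate final bacterial density grown in the lysate, CFU/ml
#'   (scalar or replicate vector).
#' @param cfuBaseline matched no-carbon baseline, CFU/ml (default 0; the
#'   un-subtracted convention).
#' @param lysedAlgalDensity density of algal cells lysed to produce the
#'   lysate, cells/ml.
#' @return list: `yield` (CFU per lysed cell), `sd` (replicate-propagated,
#'   NA for scalar input), `headline` (1 significant figure), and the
#'   per-replicate yields.
#' @examples
#' yieldPerLysedCell(1.7e8, 0, 1.6e6)$yield     # 106.25
#' yieldPerLysedCell(1.7e8, 0, 1.6e6)$headline  # 100
#' @export
yieldPerLysedCell <- function(cfuInLysate, cfuBaseline = 0,
                              lysedAlgalDensity) {
  if (any(lysedAlgalDensity <= 0)) stop("lysed algal density must be > 0")
  if (any(cfuBaseline < 0)) stop("baseline CFU must be >= 0")
  if (any(cfuInLysate < cfuBaseline))
    stop("baseline exceeds final CFU: nothing grew")
  perRep <- (cfuInLysate - cfuBaseline) / lysedAlgalDensity
  y <- mean(perRep)
  list(yield = y,
       sd = if (length(perRep) > 1L) stats::sd(perRep) else NA_real_,
       headline = signif(y, 1),
       replicate_yields = perRep)
}

#' Lysed-cell density required to explain bacterial proliferation
#'
#' `observed proliferation / yield per lysed cell`: how many algal cells
#' per ml must have lysed to supply the observed increase in viable
#' bacteria.
#'
#' @param observedProliferation increase in bacterial density, CFU/ml.
#' @param yield CFU supported per lysed algal cell (> 0).
#' @return required lysed algal density, cells/ml.
#' @examples
#' requiredLysedDensity(1.1e7, 100)  # 1.1e5
#' @export
requiredLysedDensity <- function(observedProliferation, yield) {
  if (any(yield <= 0)) stop("yield must be > 0")
  if (any(observedProliferation < 0)) stop("proliferation must be >= 0")
  observedProliferation / yield
}

#' Required lysis as a percentage of the algal population
#'
#' @param requiredLysedDensity lysed cells/ml needed
#'   ([requiredLysedDensity()]).
#' @param algalDensity algal population density, cells/ml (> 0).
#' @return percent of the algal population.
#' @examples
#' requiredLysisFraction(1.1e5, 6.1e6)  # ~1.8
#' @export
requiredLysisFraction <- function(requiredLysedDensity, algalDensity) {
  if (any(algalDensity <= 0)) stop("algal density must be > 0")
  if (any(requiredLysedDensity < 0)) stop("required density must be >= 0")
  100 * requiredLysedDensity / algalDensity
}

#' Assemble a lysis budget
#'
#' Composes the necromass carrying-capacity model: yield per lysed cell
#' (with replicate uncertainty), observed coculture proliferation,
#' required lysed-cell density and population fraction, and first-order
#' (delta-method) propagation of the yield uncertainty onto the required
#' fraction.
#'
#' @param cfuInLysate,cfuBaseline,lysedAlgalDensity see
#'   [yieldPerLysedCell()].
#' @param observedProliferation coculture bacterial increase, CFU/ml
#'   (scalar or per-replicate; max CFU minus inoculum, averaged).
#' @param algalDensity coculture algal density, cells/ml.
#' @return list of all intermediates: `yield`, `yield_sd`,
#'   `yield_headline`, `observed_proliferation`, `required_lysed_density`,
#'   `required_fraction_pct`, `required_fraction_sd_pct`, plus the
#'   baseline-subtracted and unsubtracted yields.
#' @export
lysisBudget <- function(cfuInLysate, cfuBaseline = 0, lysedAlgalDensity,
                        observedProliferation, algalDensity) {
  y0 <- yieldPerLysedCell(cfuInLysate, 0, lysedAlgalDensity)
  yb <- yieldPerLysedCell(cfuInLysate, cfuBaseline, lysedAlgalDensity)
  prolif <- mean(observedProliferation)
  req <- requiredLysedDensity(prolif, yb$headline)
  frac <- requiredLysisFraction(req, algalDensity)
  # delta method on frac = 100 * prolif / (yield * algal): relative sds add
  relY <- if (is.na(yb$sd)) 0 else yb$sd / yb$yield
  relP <- if (length(observedProliferation) > 1L)
    stats::sd(observedProliferation) / sqrt(length(observedProliferation)) /
      prolif else 0
  fracSd <- frac * sqrt(relY^2 + relP^2)
  list(yield = yb$yield, yield_sd = yb$sd, yield_headline = yb$headline,
       yield_unsubtracted = y0$yield,
       observed_proliferation = prolif,
       required_lysed_density = req,
       algal_density = algalDensity,
       required_fraction_pct = frac,
       required_fraction_sd_pct = fracSd)
}

#' Judge a lysis budget against the measured lysis range
#'
#' Consistent when the required lysis fraction falls inside the measured
#' cytotoxicity range expanded by the propagated yield uncertainty;
#' otherwise `insufficient_lysis` (more lysis would be needed than
#' measured) or `excess_lysis` (measured lysis over-explains the observed
#' proliferation). Margins to the nearest bound are reported.
#'
#' @param budget list from [lysisBudget()].
#' @param measuredLysisRangePct length-2 numeric, percent (e.g.
#'   `c(1, 3)`).
#' @return list: `verdict` (`"consistent"`, `"insufficient_lysis"`,
#'   `"excess_lysis"`), `margin_pct` (distance to the violated bound, 0
#'   when consistent), `required_fraction_pct`, `expanded_range_pct`.
#' @examples
#' b <- lysisBudget(1.7e8, 0, 1.6e6, 1.1e7, 6.1e6)
#' lysisConsistency(b, c(1, 3))$verdict  # "consistent"
#' @export
lysisConsistency <- function(budget, measuredLysisRangePct) {
  stopifnot(length(measuredLysisRangePct) == 2L,
            diff(measuredLysisRangePct) >= 0)
  sdp <- if (is.na(budget$required_fraction_sd_pct)) 0 else
    budget$required_fraction_sd_pct
  lo <- measuredLysisRangePct[1] - sdp
  hi <- measuredLysisRangePct[2] + sdp
  f <- budget$required_fraction_pct
  if (f > hi)
    list(verdict = "insufficient_lysis", margin_pct = f - hi,
         required_fraction_pct = f, expanded_range_pct = c(lo, hi))
  else if (f < lo)
    list(verdict = "excess_lysis", margin_pct = lo - f,
         required_fraction_pct = f, expanded_range_pct = c(lo, hi))
  else
    list(verdict = "consistent", margin_pct = 0,
         required_fraction_pct = f, expanded_range_pct = c(lo, hi))
}
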