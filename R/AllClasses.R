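#' @import methods
NULL

# Canonical ion species handled by the quantification core. 32S- is carried
# along for cell identification but takes no part in the isotope math.
.ION_SPECIES <- c("C2", "C13C", "CN", "C15N", "S")

#' CocultureScenario: configuration of a simulated phototroph-heterotroph run
#'
#' Describes one coculture experiment for the synthetic-data generator:
#' light regime, duration, algal growth parameters, carbon-release terms
#' (exudation and lysis), bacterial yields, the stable-isotope label
#' schedule, and the random seed. The packaged defaults (see
#' [defaultScenario()]) emulate an air-bubbled minimal-medium coculture of a
#' green alga with a B12-producing rhizobium: 50% of medium ammonium
#' supplied as 15N (99 atom%), 13CO2 bubbling starting 13 h
#' post-inoculation, an algal plateau near 4e6 cells/ml, and roughly
#' three-fold more bacterial growth under continuous than diurnal light.
#'
#' @slot lightRegime `"continuous"` or `"diurnal_12_12"` (12 h light / 12 h
#'   dark, inoculation at dawn).
#' @slot durationH total simulated time, hours.
#' @slot algalN0,algalK inoculum density and carrying capacity, cells/ml.
#' @slot algalDoublingH exponential-phase doubling time under continuous
#'   light, hours. Under `diurnal_12_12` the population instead divides
#'   synchronously once per dark phase.
#' @slot bacterialN0 bacterial inoculum, CFU/ml.
#' @slot exudationRate dissolved organic carbon released by live algal
#'   cells, ug NPOC per 1e6 cells per hour of light.
#' @slot lysisFractionPerDay fraction of the algal population lysing per
#'   day.
#' @slot bacterialYieldPerLysedCell viable bacterial cells supported by the
#'   necromass of one lysed algal cell, CFU.
#' @slot bacterialYieldPerUgNPOC viable bacterial cells supported per ug of
#'   exuded NPOC, CFU.
#' @slot bacterialGrowthRate intrinsic bacterial CFU growth rate, 1/h.
#' @slot biomassYieldFactor new bacterial biomass synthesized per unit of
#'   CFU carrying capacity consumed, in inoculum-cell biomass equivalents
#'   per CFU. Values well below 1 produce the starvation mismatch between
#'   division and biomass synthesis (reductive division).
#' @slot reductiveDivisionMax maximum extra doublings the population can
#'   perform without commensurate biomass gain (bounds how small mean cell
#'   size can get).
#' @slot labelStartH hour at which 13CO2 delivery begins (default 13).
#' @slot f15NSubstrate 15N atom fraction of the medium ammonium pool.
#' @slot f13CSourceMax 13C atom fraction of newly fixed algal carbon once
#'   the gas label is flowing.
#' @slot b12OnsetH hour after which bacterial B12 accumulates in medium.
#' @slot cellLengthMaxUm,cellLengthMinUm bacterial pole-to-pole length of
#'   carbon-replete cells and the floor reached under starvation, um.
#' @slot seed integer random seed; all generator randomness derives from it.
#' @export
setClass("CocultureScenario",
  representation(
    lightRegime = "character",
    durationH = "numeric",
    algalN0 = "numeric",
    algalK = "numeric",
    algalDoublingH = "numeric",
    bacterialN0 = "numeric",
    exudationRate = "numeric",
    lysisFractionPerDay = "numeric",
    bacterialYieldPerLysedCell = "numeric",
    bacterialYieldPerUgNPOC = "numeric",
    bacterialGrowthRate = "numeric",
    biomassYieldFactor = "numeric",
    reductiveDivisionMax = "numeric",
    labelStartH = "numeric",
    f15NSubstrate = "numeric",
    f13CSourceMax = "numeric",
    b12OnsetH = "numeric",
    cellLengthMaxUm = "numeric",
    cellLengthMinUm = "numeric",
    seed = "integer"
  )
)

setValidity("CocultureScenario", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!object@lightRegime %in% c("continuous", "diurnal_12_12"))
    msg <- c(msg, "lightRegime must be 'continuous' or 'diurnal_12_12'")
  for (s in c("durationH", "algalN0", "algalK", "algalDoublingH",
              "bacterialN0", "exudationRate", "lysisFractionPerDay",
              "bacterialYieldPerLysedCell", "bacterialYieldPerUgNPOC",
              "bacterialGrowthRate", "biomassYieldFactor",
              "reductiveDivisionMax", "labelStartH", "f15NSubstrate",
              "f13CSourceMax", "b12OnsetH", "cellLengthMaxUm",
              "cellLengthMinUm")) {
    v <- slot(object, s)
    if (!num1(v)) msg <- c(msg, sprintf("%s must be a single finite number", s))
    else if (v < 0) msg <- c(msg, sprintf("%s must be >= 0", s))
  }
  if (num1(object@lysisFractionPerDay) && object@lysisFractionPerDay > 1)
    msg <- c(msg, "lysisFractionPerDay must be in [0, 1]")
  for (s in c("f15NSubstrate", "f13CSourceMax")) {
    v <- slot(object, s)
    if (num1(v) && v > 1) msg <- c(msg, sprintf("%s is an atom fraction in [0, 1]", s))
  }
  if (num1(object@durationH) && num1(object@labelStartH) &&
      object@durationH <= object@labelStartH)
    msg <- c(msg, "durationH must exceed labelStartH")
  if (num1(object@cellLengthMaxUm) && num1(object@cellLengthMinUm) &&
      object@cellLengthMinUm > object@cellLengthMaxUm)
    msg <- c(msg, "cellLengthMinUm must not exceed cellLengthMaxUm")
  if (length(msg)) msg else TRUE
})

#' IonImageStack: co-registered secondary ion count images
#'
#' Holds one integer count raster per collected secondary ion species
#' (12C2-, 12C13C-, 12C14N-, 12C15N-, 32S-) for a single analysis field,
#' together with the pixel size and acquisition metadata. All channels share
#' one geometry; counts are non-negative integers.
#'
#' @slot channels named list of integer matrices, names among
#'   `c("C2", "C13C", "CN", "C15N", "S")` (`C2` = 12C2-, `C13C` = 12C13C-,
#'   `CN` = 12C14N-, `C15N` = 12C15N-, `S` = 32S-).
#' @slot pixelSizeUm pixel edge length, um.
#' @slot fieldId,cultureId character identifiers.
#' @slot timepointH acquisition timepoint, hours post-inoculation.
#' @export
setClass("IonImageStack",
  representation(
    channels = "list",
    pixelSizeUm = "numeric",
    fieldId = "character",
    cultureId = "character",
    timepointH = "numeric"
  )
)

setValidity("IonImageStack", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) == 0L || is.null(names(ch)) || any(names(ch) == ""))
    return("channels must be a non-empty named list of count matrices")
  bad <- setdiff(names(ch), .ION_SPECIES)
  if (length(bad))
    msg <- c(msg, paste0("unknown ion channel(s): ", paste(bad, collapse = ", ")))
  dims <- lapply(ch, dim)
  if (any(vapply(dims, is.null, logical(1))))
    msg <- c(msg, "all channels must be matrices")
  else if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    msg <- c(msg, "all channels must share the same dimensions")
  for (nm in names(ch)) {
    x <- ch[[nm]]
    if (is.matrix(x) && (any(x < 0) || any(x != round(x))))
      msg <- c(msg, sprintf("channel %s must contain non-negative integer counts", nm))
  }
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ROISet: labeled cell regions with partner annotations
#'
#' A label mask aligned to an [IonImageStack-class] plus a per-label
#' annotation table. Label 0 is background; every annotated label must be
#' present in the mask.
#'
#' @slot mask integer matrix of cell labels (0 = background).
#' @slot annotations data.frame with columns `label`, `cell_id`, `partner`
#'   (`"alga"` or `"bacterium"`), `culture`, `replicate`, `timepoint_h`.
#' @export
setClass("ROISet",
  representation(mask = "matrix", annotations = "data.frame")
)

setValidity("ROISet", function(object) {
  msg <- character()
  m <- object@mask
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "mask must contain non-negative integer labels")
  ann <- object@annotations
  need <- c("label", "cell_id", "partner", "culture", "replicate", "timepoint_h")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    msg <- c(msg, paste0("annotations missing column(s): ", paste(miss, collapse = ", ")))
  else {
    if (any(ann$label <= 0))
      msg <- c(msg, "annotation labels must be positive integers")
    if (anyDuplicated(ann$label))
      msg <- c(msg, "annotation labels must be unique")
    absent <- setdiff(ann$label, unique(as.vector(m)))
    if (length(absent))
      msg <- c(msg, paste0("annotated label(s) absent from mask: ",
                           paste(absent, collapse = ", ")))
    if (!all(ann$partner %in% c("alga", "bacterium")))
      msg <- c(msg, "partner must be 'alga' or 'bacterium'")
  }
  if (length(msg)) msg else TRUE
})

#' IsotopeStandards: natural-abundance ratios and label composition
#'
#' Bundles the instrument standard ratios used to anchor enrichment to
#' natural abundance, together with the label purity and substrate mixing
#' fraction that define the nitrogen source composition.
#'
#' @slot RstdC natural-abundance 12C13C-/12C2- ion ratio (default 0.02247).
#' @slot RstdN natural-abundance 12C15N-/12C14N- ion ratio (default 0.00367).
#' @slot label15NPurity atom fraction 15N of the labeled ammonium (0.99).
#' @slot substrateMixingFraction fraction of medium ammonium supplied as the
#'   labeled salt (0.5).
#' @slot carbonConvention `"dimer"` (random-pairing C2 model, p = R/(2+R))
#'   or `"simple"` (p = R/(1+R)) for the carbon ratio-to-atom-fraction map.
#' @export
setClass("IsotopeStandards",
  representation(
    RstdC = "numeric",
    RstdN = "numeric",
    label15NPurity = "numeric",
    substrateMixingFraction = "numeric",
    carbonConvention = "character"
  )
)

setValidity("IsotopeStandards", function(object) {
  msg <- character()
  if (object@RstdC <= 0 || object@RstdN <= 0)
    msg <- c(msg, "standard ratios must be positive")
  for (s in c("label15NPurity", "substrateMixingFraction")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", s))
  }
  if (!object@carbonConvention %in% c("dimer", "simple"))
    msg <- c(msg, "carbonConvention must be 'dimer' or 'simple'")
  if (length(msg)) msg else TRUE
})

#' GrowthSeries: timestamped density observations
#'
#' Wraps a long-format table of culture density observations with unit
#' checking: one row per (time, condition, replicate, partner), density in
#' CFU/ml (bacteria) or cells/ml (algae).
#'
#' @slot data data.frame with columns `time_h`, `condition`, `replicate`,
#'   `partner`, `density`, `unit`.
#' @export
setClass("GrowthSeries", representation(data = "data.frame"))

setValidity("GrowthSeries", function(object) {
  msg <- character()
  d <- object@data
  need <- c("time_h", "condition", "replicate", "partner", "density", "unit")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (any(!is.finite(d$density)) || any(d$density < 0))
    msg <- c(msg, "densities must be finite and >= 0")
  if (!all(d$unit %in% c("CFU/ml", "cells/ml")))
    msg <- c(msg, "unit must be 'CFU/ml' or 'cells/ml'")
  srt <- tapply(d$time_h, interaction(d$condition, d$replicate, d$partner, drop = TRUE),
                function(t) all(diff(t) >= 0))
  if (length(srt) && !all(unlist(srt)))
    msg <- c(msg, "times must be non-decreasing within each replicate series")
  if (length(msg)) msg else TRUE
})

#' StandardCurve: fitted monotone bioassay calibration
#'
#' Monotone map from differential growth (delta OD600) to vitamin B12
#' concentration, fitted on standards. Quantification outside the
#' calibrated range is censored, never extrapolated silently.
#'
#' @slot model `"logistic4"` (4-parameter logistic in log10 concentration)
#'   or `"linear_interp"` (monotone piecewise-linear fallback).
#' @slot coef named numeric coefficients (logistic4: `bottom`, `top`,
#'   `log10ec50`, `slope`).
#' @slot calibration data.frame of `nominal_ng_per_l`, `delta_od`,
#'   `fitted_delta_od`.
#' @slot validRange concentration range covered by the standards, ng/l.
#' @slot responseRange delta-OD range attainable within validRange.
#' @slot diagnostics list of fit diagnostics (residual sd, convergence).
#' @export
setClass("StandardCurve",
  representation(
    model = "character",
    coef = "numeric",
    calibration = "data.frame",
    validRange = "numeric",
    responseRange = "numeric",
    diagnostics = "list"
  )
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (!object@model %in% c("logistic4", "linear_interp"))
    msg <- c(msg, "model must be 'logistic4' or 'linear_interp'")
  if (length(object@validRange) != 2L || diff(object@validRange) <= 0)
    msg <- c(msg, "validRange must be an increasing length-2 numeric")
  if (length(msg)) msg else TRUE
})
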