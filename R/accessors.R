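#' Construct an IonImageStack
#'
#' @param channels named list of non-negative integer count matrices; names
#'   among `"C2"`, `"C13C"`, `"CN"`, `"C15N"`, `"S"`.
#' @param pixelSizeUm pixel edge length in um (default 0.1).
#' @param fieldId,cultureId identifiers recorded in outputs.
#' @param timepointH acquisition time, hours post-inoculation.
#' @return An [IonImageStack-class] object.
#' @examples
#' ch <- list(C2 = matrix(5L, 4, 4), C13C = matrix(0L, 4, 4))
#' IonImageStack(ch, pixelSizeUm = 0.1)
#' @export
IonImageStack <- function(channels, pixelSizeUm = 0.1, fieldId = "field1",
                          cultureId = "culture1", timepointH = NA_real_) {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("IonImageStack", channels = channels, pixelSizeUm = pixelSizeUm,
      fieldId = fieldId, cultureId = cultureId, timepointH = timepointH)
}

#' Construct an ROISet
#'
#' @param mask integer label matrix aligned to the image stack (0 =
#'   background).
#' @param annotations data.frame with columns `label`, `cell_id`,
#'   `partner`, `culture`, `replicate`, `timepoint_h`.
#' @return An [ROISet-class] object.
#' @export
ROISet <- function(mask, annotations) {
  storage.mode(mask) <- "integer"
  annotations$label <- as.integer(annotations$label)
  new("ROISet", mask = mask, annotations = annotations)
}

#' Isotope standards and label composition
#'
#' Defaults are the natural-abundance instrument standard ratios 0.02247
#' (12C13C-/12C2-) and 0.00367 (12C15N-/12C14N-), 99 atom% 15N label
#' purity, and a 50% labeled-ammonium substrate mixing fraction.
#'
#' @param RstdC,RstdN natural-abundance standard ion ratios.
#' @param label15NPurity atom fraction 15N of the labeled ammonium salt.
#' @param substrateMixingFraction fraction of medium ammonium replaced by
#'   the labeled salt.
#' @param carbonConvention `"dimer"` (default) or `"simple"`; see
#'   [ratioToAtomFraction()].
#' @return An [IsotopeStandards-class] object.
#' @examples
#' std <- IsotopeStandards()
#' naturalAbundance(std, "C_dimer")
#' @export
IsotopeStandards <- function(RstdC = 0.02247, RstdN = 0.00367,
                             label15NPurity = 0.99,
                             substrateMixingFraction = 0.5,
                             carbonConvention = c("dimer", "simple")) {
  new("IsotopeStandards", RstdC = RstdC, RstdN = RstdN,
      label15NPurity = label15NPurity,
      substrateMixingFraction = substrateMixingFraction,
      carbonConvention = match.arg(carbonConvention))
}

#' Construct a GrowthSeries
#'
#' @param data data.frame with columns `time_h`, `condition`, `replicate`,
#'   `partner`, `density`, `unit` (`"CFU/ml"` or `"cells/ml"`).
#' @return A [GrowthSeries-class] object.
#' @export
GrowthSeries <- function(data) new("GrowthSeries", data = data)

#' @rdname channelNames
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Accessors for ion image stacks
#'
#' `channelNames()` lists the ion species present; `ionCounts()` extracts
#' one channel's count matrix; `pixelSize()` returns the pixel edge length
#' in um.
#'
#' @param x an [IonImageStack-class].
#' @param channel channel name, e.g. `"C2"`.
#' @name channelNames
#' @export
setMethod("channelNames", "IonImageStack", function(x) names(x@channels))

#' @rdname channelNames
#' @export
setGeneric("ionCounts", function(x, channel) standardGeneric("ionCounts"))

#' @rdname channelNames
#' @export
setMethod("ionCounts", "IonImageStack", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("no such channel: ", channel)
  x@channels[[channel]]
})

#' @rdname channelNames
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname channelNames
#' @export
setMethod("pixelSize", "IonImageStack", function(x) x@pixelSizeUm)

#' @rdname roiMask
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' Accessors for ROI sets
#'
#' `roiMask()` returns the integer label mask; `roiAnnotations()` the
#' per-label annotation table.
#'
#' @param x an [ROISet-class].
#' @name roiMask
#' @export
setMethod("roiMask", "ROISet", function(x) x@mask)

#' @rdname roiMask
#' @export
setGeneric("roiAnnotations", function(x) standardGeneric("roiAnnotations"))

#' @rdname roiMask
#' @export
setMethod("roiAnnotations", "ROISet", function(x) x@annotations)

#' @rdname growthData
#' @export
setGeneric("growthData", function(x) standardGeneric("growthData"))

#' Extract the observation table from a GrowthSeries
#'
#' @param x a [GrowthSeries-class].
#' @return data.frame of observations.
#' @name growthData
#' @export
setMethod("growthData", "GrowthSeries", function(x) x@data)

#' Natural-abundance atom fraction implied by a standards object
#'
#' Converts the configured standard ion ratio to an atom fraction with the
#' configured convention, so that the enrichment of the standard itself is
#' exactly zero.
#'
#' @param standards an [IsotopeStandards-class].
#' @param species `"C_dimer"` or `"N_cyanide"`.
#' @return natural-abundance heavy-isotope atom fraction.
#' @export
naturalAbundance <- function(standards, species = c("C_dimer", "N_cyanide")) {
  species <- match.arg(species)
  if (species == "C_dimer")
    ratioToAtomFraction(standards@RstdC, "C_dimer",
                        convention = standards@carbonConvention)
  else
    ratioToAtomFraction(standards@RstdN, "N_cyanide")
}

#' 15N atom fraction of the medium ammonium pool
#'
#' Computed from label purity and the fraction of ammonium supplied as the
#' labeled salt: `mix * purity + (1 - mix) * natural`. With the default 99
#' atom% label and 50% mixing this is 0.4968.
#'
#' @param standards an [IsotopeStandards-class].
#' @return atom fraction 15N of the nitrogen source substrate.
#' @export
substrate15NFraction <- function(standards) {
  nat <- naturalAbundance(standards, "N_cyanide")
  standards@substrateMixingFraction * standards@label15NPurity +
    (1 - standards@substrateMixingFraction) * nat
}

setMethod("show", "CocultureScenario", function(object) {
  cat("CocultureScenario:", object@lightRegime, "light,",
      object@durationH, "h\n")
  cat("  alga:  N0", format(object@algalN0, scientific = TRUE), "-> K",
      format(object@algalK, scientific = TRUE), "cells/ml\n")
  cat("  bact:  N0", format(object@bacterialN0, scientific = TRUE),
      "CFU/ml; yield", object@bacterialYieldPerLysedCell, "CFU/lysed cell\n")
  cat("  label: 13CO2 from", object@labelStartH, "h; 15N substrate",
      signif(object@f15NSubstrate, 4), "\n")
  cat("  lysis:", 100 * object@lysisFractionPerDay, "%/day; exudation",
      object@exudationRate, "ug NPOC/1e6 cells/h (light); seed",
      object@seed, "\n")
})

setMethod("show", "IonImageStack", function(object) {
  d <- dim(object@channels[[1]])
  cat("IonImageStack", object@fieldId, ":", d[1], "x", d[2], "px,",
      object@pixelSizeUm, "um/px\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  tot <- vapply(object@channels, sum, numeric(1))
  cat("  total counts:", paste(sprintf("%s=%g", names(tot), tot),
                               collapse = ", "), "\n")
})

setMethod("show", "ROISet", function(object) {
  ann <- object@annotations
  cat("ROISet:", nrow(ann), "annotated ROI(s) in a",
      nrow(object@mask), "x", ncol(object@mask), "mask\n")
  if (nrow(ann))
    print(table(ann$partner))
})

setMethod("show", "GrowthSeries", function(object) {
  d <- object@data
  cat("GrowthSeries:", nrow(d), "observations,",
      length(unique(d$condition)), "condition(s),",
      "t =", min(d$time_h), "-", max(d$time_h), "h\n")
})

setMethod("show", "StandardCurve", function(object) {
  cat("StandardCurve (", object@model, "): valid range [",
      format(object@validRange[1]), ",", format(object@validRange[2]),
      "] ng/l,", nrow(object@calibration), "standards\n")
})
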