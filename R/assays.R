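#' Differential indicator growth for the B12 bioassay
#'
#' `delta OD = OD(dmetE) - OD(dmetE dmetH)`: subtracting the control
#' strain's B12-independent growth isolates the cobalamin response.
#' Negative differences are biologically impossible signal, so they are
#' floored at 0 and flagged.
#'
#' @param odDmetE,odControl OD600 vectors for the responsive and control
#'   strains (paired, same length).
#' @return data.frame with `delta_od` and logical `floored`.
#' @examples
#' b12DeltaGrowth(0.50, 0.10)$delta_od  # 0.40
#' @export
b12DeltaGrowth <- function(odDmetE, odControl) {
  if (length(odDmetE) != length(odControl))
    stop("odDmetE and odControl must be paired (equal length)")
  if (any(!is.finite(odDmetE)) || any(!is.finite(odControl)))
    stop("missing OD in a strain pair")
  d <- odDmetE - odControl
  data.frame(delta_od = pmax(d, 0), floored = d < 0)
}

#' Fit a monotone B12 standard curve
#'
#' Fits delta OD versus log10(concentration) for the calibration
#' standards. With six or more distinct standards a 4-parameter logistic
#' is fitted (Levenberg-Marquardt); with fewer, a monotone
#' piecewise-linear interpolant is used. A fit whose response is not
#' strictly increasing over the standards' range (beyond noise) is
#' refused with a diagnostic rather than returned.
#'
#' @param standards data.frame with columns `nominal_ng_per_l` (> 0) and
#'   `delta_od`; replicate wells are averaged per nominal level.
#' @return a [StandardCurve-class].
#' @export
fitStandardCurve <- function(standards) {
  stopifnot(all(c("nominal_ng_per_l", "delta_od") %in% names(standards)))
  if (any(standards$nominal_ng_per_l <= 0))
    stop("standard concentrations must be positive")
  agg <- stats::aggregate(delta_od ~ nominal_ng_per_l, standards, mean)
  agg <- agg[order(agg$nominal_ng_per_l), ]
  if (nrow(agg) < 4L)
    stop("need >= 4 distinct standard concentrations")
  if (log10(max(agg$nominal_ng_per_l) / min(agg$nominal_ng_per_l)) < 2)
    stop("standards must span at least two orders of magnitude")
  # non-monotone beyond noise tolerance -> refuse
  resSd0 <- stats::sd(standards$delta_od -
                        agg$delta_od[match(standards$nominal_ng_per_l,
                                           agg$nominal_ng_per_l)])
  tol <- max(2 * resSd0, 1e-6, na.rm = TRUE)
  drops <- diff(agg$delta_od)
  if (any(drops < -tol))
    stop("standards are not monotone beyond noise tolerance (drop of ",
         signif(min(drops), 3), " delta OD); check the plate")
  lx <- log10(agg$nominal_ng_per_l)
  if (nrow(agg) >= 6L) {
    y <- agg$delta_od
    residFn <- function(par)
      .logistic4(lx, par[1], par[2], par[3], par[4]) - y
    fit <- try(minpack.lm::nls.lm(
      par = c(bottom = 0, top = max(y) * 1.05,
              log10ec50 = stats::median(lx), slope = 1),
      fn = residFn,
      lower = c(bottom = 0, top = 1e-6, log10ec50 = min(lx) - 2,
                slope = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$info %in% 1:4) {
      cf <- fit$par
      fitted <- .logistic4(lx, cf["bottom"], cf["top"], cf["log10ec50"],
                           cf["slope"])
      return(new("StandardCurve", model = "logistic4", coef = cf,
                 calibration = data.frame(nominal_ng_per_l = agg$nominal_ng_per_l,
                                          delta_od = agg$delta_od,
                                          fitted_delta_od = fitted),
                 validRange = range(agg$nominal_ng_per_l),
                 responseRange = range(fitted),
                 diagnostics = list(residual_sd = stats::sd(agg$delta_od - fitted),
                                    converged = TRUE)))
    }
    # fall through to the interpolant if the nonlinear fit fails
  }
  mono <- cummax(agg$delta_od)  # enforce (weak) monotonicity within tolerance
  new("StandardCurve", model = "linear_interp", coef = numeric(0),
      calibration = data.frame(nominal_ng_per_l = agg$nominal_ng_per_l,
                               delta_od = agg$delta_od,
                               fitted_delta_od = mono),
      validRange = range(agg$nominal_ng_per_l),
      responseRange = range(mono),
      diagnostics = list(residual_sd = stats::sd(agg$delta_od - mono),
                         converged = TRUE))
}

#' Quantify B12 concentrations from delta-OD readings
#'
#' Inverts the fitted standard curve. Readings below the response of the
#' lowest standard (the limit of detection) are censored as
#' `below_detection`; readings above the highest standard's response as
#' `above_range`. Censored rows carry the censoring bound, never an
#' extrapolated concentration.
#'
#' @param curve a [StandardCurve-class] from [fitStandardCurve()].
#' @param deltaOd numeric vector of delta-OD readings.
#' @return data.frame: `delta_od`, `b12_ng_per_l` (NA when censored),
#'   `censored` (`"none"`, `"below_detection"`, `"above_range"`), `bound`.
#' @export
quantifyB12 <- function(curve, deltaOd) {
  stopifnot(is(curve, "StandardCurve"))
  lo <- curve@responseRange[1]; hi <- curve@responseRange[2]
  invert <- function(y) {
    if (curve@model == "logistic4") {
      cf <- curve@coef
      # y = bottom + (top-bottom)/(1 + 10^(slope*(ec50 - x)))
      frac <- (cf[["top"]] - cf[["bottom"]]) / (y - cf[["bottom"]]) - 1
      10^(cf[["log10ec50"]] - log10(frac) / cf[["slope"]])
    } else {
      cal <- curve@calibration
      stats::approx(cal$fitted_delta_od, cal$nominal_ng_per_l, xout = y,
                    ties = "ordered")$y
    }
  }
  out <- data.frame(delta_od = deltaOd,
                    b12_ng_per_l = rep(NA_real_, length(deltaOd)),
                    censored = rep("none", length(deltaOd)),
                    bound = rep(NA_real_, length(deltaOd)))
  below <- deltaOd <= lo
  above <- deltaOd > hi
  ok <- !below & !above
  if (any(ok)) out$b12_ng_per_l[ok] <- vapply(deltaOd[ok], invert, numeric(1))
  out$censored[below] <- "below_detection"
  out$bound[below] <- curve@validRange[1]
  out$censored[above] <- "above_range"
  out$bound[above] <- curve@validRange[2]
  out
}

#' Quantify a whole bioassay plate
#'
#' Convenience wrapper: computes per-sample mean delta growth
#' ([b12DeltaGrowth()] on replicate-averaged ODs), fits the curve on the
#' plate's standards, and quantifies the samples.
#'
#' @param plate data.frame of wells as produced by
#'   [simulateBioassayPlate()] (columns `sample_id`, `strain`, `od600`,
#'   `is_standard`, `nominal_b12_ng_per_l`).
#' @return list with `curve` ([StandardCurve-class]) and `samples`
#'   (quantification table with one row per non-standard sample).
#' @export
quantifyBioassayPlate <- function(plate) {
  need <- c("sample_id", "strain", "od600", "is_standard",
            "nominal_b12_ng_per_l")
  stopifnot(all(need %in% names(plate)))
  info <- unique(plate[c("sample_id", "is_standard", "nominal_b12_ng_per_l")])
  meanOd <- function(id, strain)
    mean(plate$od600[plate$sample_id == id & plate$strain == strain])
  info$od_dmetE <- vapply(info$sample_id, meanOd, numeric(1), strain = "dmetE")
  info$od_control <- vapply(info$sample_id, meanOd, numeric(1),
                            strain = "dmetE_dmetH")
  if (any(!is.finite(info$od_dmetE)) || any(!is.finite(info$od_control)))
    stop("every sample must be measured with both strains")
  dg <- b12DeltaGrowth(info$od_dmetE, info$od_control)
  info$delta_od <- dg$delta_od
  info$floored <- dg$floored
  stds <- info[info$is_standard, ]
  curve <- fitStandardCurve(data.frame(nominal_ng_per_l = stds$nominal_b12_ng_per_l,
                                       delta_od = stds$delta_od))
  smp <- info[!info$is_standard, ]
  q <- quantifyB12(curve, smp$delta_od)
  q$sample_id <- smp$sample_id
  q$floored <- smp$floored
  list(curve = curve, samples = q[c("sample_id", "delta_od", "b12_ng_per_l",
                                    "censored", "bound", "floored")])
}

#' Cytotoxicity (compromised-membrane) percentage
#'
#' `100 * (sample - blank) / (killed - blank)`: fluorescence of the
#' membrane-impermeable DNA dye relative to a fully killed control, after
#' medium-blank subtraction. Values above 100% are flagged, not clipped.
#'
#' @param sample,blank,killed fluorescence readings (arbitrary units);
#'   `killed` must exceed `blank`.
#' @return data.frame with `percent_compromised` and `over_range` flag.
#' @examples
#' cytotoxicityPercent(150, 100, 600)$percent_compromised  # 10
#' @export
cytotoxicityPercent <- function(sample, blank, killed) {
  if (any(killed <= blank))
    stop("killed control must exceed the medium blank")
  pct <- 100 * (sample - blank) / (killed - blank)
  data.frame(percent_compromised = pct, over_range = pct > 100)
}

#' Correct an NPOC reading for sample dilution
#'
#' Spent media are diluted before acid sparging; the reported
#' concentration is measured value times the dilution factor.
#'
#' @param measuredMgPerL measured NPOC, mg/l (equivalently ug/ml).
#' @param dilutionFactor dilution factor >= 1 (2 for a 2-fold dilution).
#' @return corrected NPOC on the original-sample scale.
#' @examples
#' npocDilutionCorrect(7.5, 2)  # 15
#' @export
npocDilutionCorrect <- function(measuredMgPerL, dilutionFactor) {
  if (any(dilutionFactor < 1)) stop("dilutionFactor must be >= 1")
  if (any(measuredMgPerL < 0)) stop("measured NPOC must be >= 0")
  measuredMgPerL * dilutionFactor
}
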