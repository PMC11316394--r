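# 4-parameter logistic response in log10 concentration; the standard
# sigmoidal form for microbiological growth-response bioassays.
.logistic4 <- function(log10conc, bottom, top, log10ec50, slope) {
  bottom + (top - bottom) / (1 + 10^(slope * (log10ec50 - log10conc)))
}

#' Simulate a vitamin B12 bioassay plate
#'
#' Generates OD600 readings for the two indicator strains: the B12- or
#' methionine-responsive `dmetE` strain follows a saturating 4-parameter
#' logistic response to B12 concentration, while the `dmetE_dmetH` control
#' strain (lacking both methionine synthase isoforms) grows only its basal
#' background regardless of B12. Standards and samples are measured with
#' both strains, with replicated Gaussian noise.
#'
#' @param trueB12NgPerL numeric vector of sample B12 concentrations, ng/l.
#' @param standardsNgPerL standard concentrations (default
#'   `c(1, 10, 50, 100, 500, 1000)`).
#' @param curveParams list: `bottom`, `top`, `log10ec50`, `slope` of the
#'   delta-OD response, and `controlOd` (basal OD of either strain).
#' @param noiseSd OD600 measurement noise standard deviation.
#' @param nReplicates replicate wells per sample/strain.
#' @param seed integer seed.
#' @return data.frame of wells: `sample_id`, `strain`, `replicate`,
#'   `od600`, `is_standard`, `nominal_b12_ng_per_l` (NA for samples).
#' @examples
#' plate <- simulateBioassayPlate(c(0, 50), seed = 1)
#' head(plate)
#' @export
simulateBioassayPlate <- function(trueB12NgPerL,
                                  standardsNgPerL = c(1, 10, 50, 100, 500, 1000),
                                  curveParams = list(bottom = 0, top = 0.6,
                                                     log10ec50 = 1.7,
                                                     slope = 1,
                                                     controlOd = 0.05),
                                  noiseSd = 0.01, nReplicates = 3L,
                                  seed = 1L) {
  if (any(trueB12NgPerL < 0) || any(standardsNgPerL <= 0))
    stop("concentrations must be >= 0 (standards strictly positive)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  resp <- function(conc) {
    out <- numeric(length(conc))
    pos <- conc > 0
    out[pos] <- .logistic4(log10(conc[pos]), curveParams$bottom,
                           curveParams$top, curveParams$log10ec50,
                           curveParams$slope)
    # zero concentration sits at the curve bottom
    out[!pos] <- curveParams$bottom
    out
  }
  .withSeed(seed, {
    mk <- function(ids, conc, isStd) {
      do.call(rbind, lapply(seq_along(ids), function(i) {
        do.call(rbind, lapply(c("dmetE", "dmetE_dmetH"), function(strain) {
          mu <- curveParams$controlOd +
            if (strain == "dmetE") resp(conc[i]) else 0
          data.frame(sample_id = ids[i], strain = strain,
                     replicate = seq_len(nReplicates),
                     od600 = pmax(0, stats::rnorm(nReplicates, mu, noiseSd)),
                     is_standard = isStd,
                     nominal_b12_ng_per_l = if (isStd) conc[i] else NA_real_)
        }))
      }))
    }
    rbind(
      mk(sprintf("std_%g", standardsNgPerL), standardsNgPerL, TRUE),
      mk(sprintf("sample_%02d", seq_along(trueB12NgPerL)), trueB12NgPerL,
         FALSE)
    )
  })
}
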