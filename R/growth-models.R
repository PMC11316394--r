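#' Population doublings between two densities
#'
#' `d = log2(Nt / N0)`. Negative values (decline) are allowed and flagged
#' via the `"declined"` attribute.
#'
#' @param N0,Nt initial and final densities (same unit), > 0.
#' @return doublings (unitless); attribute `"declined"` marks d < 0.
#' @examples
#' doublings(1e6, 8e6)  # 3
#' @export
doublings <- function(N0, Nt) {
  if (any(N0 <= 0) || any(Nt <= 0)) stop("densities must be positive")
  d <- log2(Nt / N0)
  attr(d, "declined") <- d < 0
  d
}

#' Expected net biomass synthesis after balanced doublings
#'
#' If every doubling in viable counts were matched by a doubling in
#' biomass, the pre-existing biomass would be diluted to `2^(-d)` of the
#' total after `d` doublings, so the expected newly synthesized fraction
#' is `1 - 2^(-d)`. Five balanced doublings give 0.97; eight or more give
#' at least 0.99. Comparing this expectation with measured net
#' assimilation exposes division without commensurate biomass synthesis.
#'
#' @param d doublings (>= 0), from [doublings()]; non-integer values are
#'   used as-is (CFU fold-changes are not rounded).
#' @return expected newly synthesized biomass fraction in [0, 1).
#' @examples
#' expectedXnet(5)  # 0.96875
#' @export
expectedXnet <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("d must be finite and >= 0")
  1 - 2^(-d)
}

#' Compare measured net assimilation with the balanced-growth expectation
#'
#' For each matched timepoint, computes doublings since inoculation, the
#' expected net-assimilation fraction under balanced growth
#' ([expectedXnet()]), the gap to the measured value, and a
#' reductive-division flag: raised when the measured value falls below
#' `flagRatio` times the expectation while the culture has kept dividing
#' since the previous timepoint.
#'
#' @param series a [GrowthSeries-class] (or its data.frame) holding the
#'   bacterial counts of one condition; replicate densities are averaged
#'   per timepoint.
#' @param measuredXnet data.frame with columns `timepoint_h` and `xnet`
#'   (measured net assimilation, e.g. median per-cell `N_net`).
#' @param flagRatio flagging threshold on measured/expected (default 0.5).
#' @param N0 inoculation density override; default is the first
#'   observation of each replicate.
#' @return data.frame per timepoint: `timepoint_h`, `d`, `expected_xnet`,
#'   `measured_xnet`, `gap`, `reductive_division_flag`.
#' @export
assessSynthesis <- function(series, measuredXnet, flagRatio = 0.5,
                            N0 = NULL) {
  d <- if (is(series, "GrowthSeries")) growthData(series) else series
  stopifnot(all(c("time_h", "replicate", "density") %in% names(d)))
  stopifnot(all(c("timepoint_h", "xnet") %in% names(measuredXnet)))
  if (is.null(N0)) {
    firsts <- vapply(split(d, d$replicate), function(g)
      g$density[which.min(g$time_h)], numeric(1))
    N0 <- mean(firsts)
  }
  dens <- stats::aggregate(density ~ time_h, d, mean)
  tp <- sort(unique(measuredXnet$timepoint_h))
  miss <- setdiff(tp, dens$time_h)
  if (length(miss))
    stop("no growth observation at measured timepoint(s): ",
         paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(tp, function(t1) {
    Nt <- dens$density[dens$time_h == t1]
    dd <- as.numeric(doublings(N0, Nt))
    meas <- mean(measuredXnet$xnet[measuredXnet$timepoint_h == t1])
    exp_ <- expectedXnet(max(dd, 0))
    data.frame(timepoint_h = t1, d = dd, expected_xnet = exp_,
               measured_xnet = meas, gap = exp_ - meas)
  }))
  dPrev <- c(0, out$d[-nrow(out)])
  out$reductive_division_flag <- out$measured_xnet < flagRatio * out$expected_xnet &
    out$d > dPrev
  out
}

#' Cell length summary and percent reduction
#'
#' `lengthStats()` returns mean, sd and n of pole-to-pole cell lengths;
#' `percentReduction()` the relative length decrease
#' `100 * (l_ref - l_t) / l_ref`.
#'
#' @param lengthsUm positive pole-to-pole lengths, um.
#' @return `lengthStats()`: list with `mean`, `sd`, `n`.
#' @examples
#' percentReduction(2.3, 1.45)  # ~36.96
#' @export
lengthStats <- function(lengthsUm) {
  if (length(lengthsUm) < 1L) stop("empty cell length sample")
  if (any(lengthsUm <= 0)) stop("lengths must be positive")
  list(mean = mean(lengthsUm),
       sd = if (length(lengthsUm) > 1L) stats::sd(lengthsUm) else 0,
       n = length(lengthsUm))
}

#' @rdname lengthStats
#' @param lRef,lT reference and later mean lengths, um.
#' @return `percentReduction()`: percent reduction relative to `lRef`.
#' @export
percentReduction <- function(lRef, lT) {
  if (any(lRef <= 0) || any(lT <= 0)) stop("lengths must be positive")
  100 * (lRef - lT) / lRef
}

#' Fold ratio of maximum densities between two growth series
#'
#' Computes, per series, the maximum of the replicate-mean density over
#' time, and returns their ratio a / b. Per-replicate maxima are also
#' returned for uncertainty checks.
#'
#' @param seriesA,seriesB [GrowthSeries-class] objects (or data.frames)
#'   with a single partner/condition each, same unit.
#' @return list: `fold` (ratio of maxima of replicate means),
#'   `max_a`, `max_b`, `replicate_max_a`, `replicate_max_b`.
#' @export
maxDensityFold <- function(seriesA, seriesB) {
  getd <- function(s) if (is(s, "GrowthSeries")) growthData(s) else s
  a <- getd(seriesA); b <- getd(seriesB)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty growth series")
  if (!identical(unique(a$unit), unique(b$unit)))
    stop("unit mismatch between series: ", unique(a$unit)[1], " vs ",
         unique(b$unit)[1])
  maxOfMeans <- function(d) {
    m <- stats::aggregate(density ~ time_h, d, mean)
    max(m$density)
  }
  repMax <- function(d) vapply(split(d, d$replicate),
                               function(g) max(g$density), numeric(1))
  list(fold = maxOfMeans(a) / maxOfMeans(b),
       max_a = maxOfMeans(a), max_b = maxOfMeans(b),
       replicate_max_a = repMax(a), replicate_max_b = repMax(b))
}

#' Two-tailed Student's t-test with the conventions used here
#'
#' Classical Student's t: pooled-variance two-sample for unpaired data,
#' difference-based for paired data (Welch's unequal-variance variant
#' available via `welch = TRUE`). Degenerate zero-variance comparisons
#' with identical means return t = 0, p = 1 (with a message) instead of
#' erroring.
#'
#' @param x,y numeric samples (n >= 2 each; paired requires equal n).
#' @param paired logical.
#' @param welch use Welch's correction instead of pooled variance.
#' @param alpha significance level for the convenience flag.
#' @return list: `statistic`, `df`, `p_value`, `significant` (p < alpha),
#'   `method`.
#' @examples
#' tTestTwoTailed(c(1, 2, 3), c(4, 5, 6))$p_value
#' @export
tTestTwoTailed <- function(x, y, paired = FALSE, welch = FALSE,
                           alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (paired && length(x) != length(y)) stop("paired test requires equal n")
  degenerate <- if (paired) stats::var(x - y) == 0 else
    (stats::var(x) == 0 && stats::var(y) == 0)
  if (degenerate) {
    if (paired && all(x == y) || (!paired && mean(x) == mean(y))) {
      message("zero variance with identical means: returning t = 0, p = 1")
      return(list(statistic = 0, df = NA_real_, p_value = 1,
                  significant = FALSE, method = "degenerate"))
    }
    stop("zero variance with differing means: t statistic undefined")
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = !welch,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       method = tt$method)
}
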