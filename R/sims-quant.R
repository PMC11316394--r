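#' Convert a measured ion count ratio to a heavy-isotope atom fraction
#'
#' For the carbon dimer species (12C13C-/12C2-) the default `"dimer"`
#' convention assumes random pairing of carbon atoms into dimer ions, so
#' that the observed ratio is `R = 2p(1-p)/(1-p)^2 = 2p/(1-p)` and
#' `p = R/(2 + R)`. This maps the instrument standard ratio 0.02247 to
#' p = 0.01111, the natural 13C abundance. The `"simple"` convention
#' `p = R/(1 + R)` is available for comparison with analyses that treat the
#' dimer ratio like a monatomic one. For the cyanide pair
#' (12C15N-/12C14N-) the heavy and light ions each carry one nitrogen atom
#' and `p = R/(1 + R)` always.
#'
#' @param R non-negative ion count ratio (heavy/light); vectorized.
#' @param species `"C_dimer"` or `"N_cyanide"`.
#' @param convention carbon convention, `"dimer"` (default) or `"simple"`;
#'   ignored for nitrogen.
#' @return heavy-isotope atom fraction(s) in [0, 1).
#' @seealso [atomFractionToRatio()] for the exact inverse.
#' @examples
#' ratioToAtomFraction(0.02247, "C_dimer")   # 0.011110 (natural 13C)
#' ratioToAtomFraction(0.00367, "N_cyanide") # 0.003657 (natural 15N)
#' @export
ratioToAtomFraction <- function(R, species = c("C_dimer", "N_cyanide"),
                                convention = c("dimer", "simple")) {
  species <- match.arg(species)
  convention <- match.arg(convention)
  if (any(!is.finite(R)) || any(R < 0))
    stop("ion count ratios must be finite and >= 0")
  if (species == "C_dimer" && convention == "dimer") R / (2 + R)
  else R / (1 + R)
}

#' Convert a heavy-isotope atom fraction back to an ion count ratio
#'
#' Exact inverse of [ratioToAtomFraction()] under the same convention.
#'
#' @inheritParams ratioToAtomFraction
#' @param p atom fraction(s) in [0, 1).
#' @return ion count ratio(s).
#' @export
atomFractionToRatio <- function(p, species = c("C_dimer", "N_cyanide"),
                                convention = c("dimer", "simple")) {
  species <- match.arg(species)
  convention <- match.arg(convention)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("atom fractions must be in [0, 1)")
  if (species == "C_dimer" && convention == "dimer") 2 * p / (1 - p)
  else p / (1 - p)
}

#' Atom percent enrichment
#'
#' `APE = 100 * (F_cell - F_natural)`: the excess heavy-isotope atom
#' percentage of a cell over the natural-abundance baseline. A cell at
#' natural abundance has APE exactly 0; unlabeled material can be slightly
#' negative by measurement noise, bounded below by `-100 * F_natural`.
#'
#' @param Fcell measured heavy-isotope atom fraction(s), in [0, 1].
#' @param Fnatural natural-abundance atom fraction, in [0, 1].
#' @return atom percent enrichment (percentage points).
#' @examples
#' apEnrichment(0.0611, 0.0111)  # 5.0
#' @export
apEnrichment <- function(Fcell, Fnatural) {
  if (any(!is.finite(Fcell)) || any(Fcell < 0) || any(Fcell > 1))
    stop("Fcell must be atom fraction(s) in [0, 1]")
  if (length(Fnatural) != 1L || !is.finite(Fnatural) || Fnatural < 0 || Fnatural > 1)
    stop("Fnatural must be a single atom fraction in [0, 1]")
  100 * (Fcell - Fnatural)
}

#' Net assimilation: fraction of newly synthesized biomass
#'
#' `X_net = (F_cell - F_unlabeled) / (F_substrate - F_unlabeled)` is the
#' fraction of a cell's biomass newly synthesized from the labeled source
#' substrate. For 15N the substrate composition is the known medium
#' ammonium 15N fraction; for 13C the convention is the experiment-mean
#' algal biomass composition (see [sourceCarbonFraction()]). Values outside
#' [0, 1] are retained and flagged via the `"outOfRange"` attribute, never
#' clipped: they are diagnostic of a mis-specified source composition.
#'
#' @param Fcell measured atom fraction(s) of the cell.
#' @param Funlabeled natural-abundance (unlabeled biomass) atom fraction.
#' @param Fsubstrate atom fraction of the labeled source substrate; must
#'   differ from `Funlabeled`.
#' @return numeric vector of net assimilation fractions with logical
#'   attribute `"outOfRange"` marking values outside [0, 1].
#' @examples
#' xNet(0.25, 0.003657, 0.4968)  # ~0.4996
#' @export
xNet <- function(Fcell, Funlabeled, Fsubstrate) {
  for (v in list(Fcell, Funlabeled, Fsubstrate))
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("all atom fractions must be finite and in [0, 1]")
  if (any(Fsubstrate == Funlabeled))
    stop("degenerate denominator: Fsubstrate must differ from Funlabeled")
  x <- (Fcell - Funlabeled) / (Fsubstrate - Funlabeled)
  attr(x, "outOfRange") <- x < 0 | x > 1
  x
}

#' Sum ion counts over annotated cell regions
#'
#' For every annotated ROI, sums each channel's counts over the ROI's
#' pixels. ROIs smaller than `minPixels` are excluded from the result and
#' reported in the `"excluded"` attribute (with their sizes), never
#' silently dropped.
#'
#' @param stack an [IonImageStack-class].
#' @param rois an [ROISet-class] whose mask matches the stack geometry.
#' @param minPixels minimum ROI area in pixels (default 5).
#' @return data.frame with one row per retained ROI: annotation columns,
#'   `n_pixels`, and one `counts_<channel>` column per channel. Attribute
#'   `"excluded"`: data.frame of excluded ROIs.
#' @export
summarizeRois <- function(stack, rois, minPixels = 5L) {
  mask <- roiMask(rois)
  ann <- roiAnnotations(rois)
  d <- dim(ionCounts(stack, channelNames(stack)[1]))
  if (!identical(dim(mask), d))
    stop(sprintf("mask shape (%d x %d) does not match image shape (%d x %d)",
                 nrow(mask), ncol(mask), d[1], d[2]))
  if (nrow(ann) == 0L) {
    warning("empty ROI annotation table: returning empty summary")
    out <- ann
    out$n_pixels <- integer(0)
    attr(out, "excluded") <- ann
    return(out)
  }
  labs <- ann$label
  # tabulate() indexes by positive label; mask label 0 (background) ignored
  npix <- tabulate(mask, nbins = max(labs))[labs]
  sums <- lapply(channelNames(stack), function(chn) {
    ch <- ionCounts(stack, chn)
    s <- vapply(split(as.numeric(ch), factor(mask, levels = labs)),
                sum, numeric(1))
    unname(s)
  })
  names(sums) <- paste0("counts_", channelNames(stack))
  out <- cbind(ann, n_pixels = npix, as.data.frame(sums))
  keep <- out$n_pixels >= minPixels
  excluded <- out[!keep, , drop = FALSE]
  if (nrow(excluded))
    message(nrow(excluded), " ROI(s) below minPixels = ", minPixels,
            " excluded: label(s) ", paste(excluded$label, collapse = ", "))
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Estimate the carbon source composition from algal cells
#'
#' The 13C composition of the carbon actually available to bacteria cannot
#' be mass-balanced when the gas label is delivered in an open system, so
#' the source substrate is approximated by the arithmetic mean 13C atom
#' fraction of all algal cells measured in the experiment, across
#' timepoints.
#'
#' @param records data.frame of per-cell records with columns `partner`
#'   and `F13C`.
#' @return list with `F_substrate_C` (mean algal F13C), `n_algal_cells`,
#'   and `sd`.
#' @export
sourceCarbonFraction <- function(records) {
  alg <- records[records$partner == "alga" & is.finite(records$F13C), , drop = FALSE]
  if (nrow(alg) == 0L)
    stop("no algal records with valid F13C: cannot estimate carbon source composition")
  list(F_substrate_C = mean(alg$F13C), n_algal_cells = nrow(alg),
       sd = stats::sd(alg$F13C))
}

#' Quantify per-cell isotope enrichment for a whole experiment
#'
#' Composes the quantification chain over one or more analysis fields:
#' per-ROI channel sums, ion ratios, atom fractions, APE, and net
#' assimilation. Carbon net assimilation (`C_net`) is computed against the
#' experiment-mean algal 13C composition ([sourceCarbonFraction()]);
#' nitrogen net assimilation (`N_net`) against the known medium ammonium
#' composition ([substrate15NFraction()]).
#'
#' @param fields list of `list(stack = , rois = )` pairs, one per analysis
#'   field of the experiment.
#' @param standards an [IsotopeStandards-class].
#' @param minPixels minimum ROI size forwarded to [summarizeRois()].
#' @return list with elements
#'   * `cells`: data.frame, one row per retained cell (counts, `R_C`,
#'     `R_N`, `F13C`, `F15N`, `APE_C`, `APE_N`, `C_net`, `N_net`,
#'     out-of-range flags);
#'   * `source`: the [sourceCarbonFraction()] estimate plus
#'     `F_substrate_N` and the natural-abundance baselines;
#'   * `summary`: per (partner, culture, timepoint_h) medians of `C_net`
#'     and `N_net` and means of APE, with cell counts — medians because
#'     single-cell net-assimilation distributions are skewed;
#'   * `pooled`: the same summaries pooled across cultures.
#' @export
quantifyExperiment <- function(fields, standards = IsotopeStandards(),
                               minPixels = 5L) {
  stopifnot(length(fields) >= 1L)
  per <- lapply(fields, function(f) {
    s <- summarizeRois(f$stack, f$rois, minPixels = minPixels)
    if (nrow(s)) {
      s$field_id <- f$stack@fieldId
      if (is.na(s$timepoint_h[1]) && !is.na(f$stack@timepointH))
        s$timepoint_h <- f$stack@timepointH
    }
    s
  })
  cells <- do.call(rbind, per)
  if (is.null(cells) || nrow(cells) == 0L)
    stop("no ROIs retained in any field")
  needed <- c("counts_C2", "counts_C13C", "counts_CN", "counts_C15N")
  miss <- setdiff(needed, names(cells))
  if (length(miss))
    stop("missing channel sum(s) required for isotope math: ",
         paste(miss, collapse = ", "))
  zeroC <- cells$counts_C2 == 0
  if (any(zeroC))
    warning("cell(s) with zero 12C2 counts get NA carbon quantities: cell_id ",
            paste(cells$cell_id[zeroC], collapse = ", "))
  cells$R_C <- ifelse(zeroC, NA_real_, cells$counts_C13C / cells$counts_C2)
  zeroN <- cells$counts_CN == 0
  cells$R_N <- ifelse(zeroN, NA_real_, cells$counts_C15N / cells$counts_CN)
  conv <- standards@carbonConvention
  cells$F13C <- ifelse(is.na(cells$R_C), NA_real_,
                       ratioToAtomFraction(ifelse(is.na(cells$R_C), 0, cells$R_C),
                                           "C_dimer", convention = conv))
  cells$F15N <- ifelse(is.na(cells$R_N), NA_real_,
                       ratioToAtomFraction(ifelse(is.na(cells$R_N), 0, cells$R_N),
                                           "N_cyanide"))
  natC <- naturalAbundance(standards, "C_dimer")
  natN <- naturalAbundance(standards, "N_cyanide")
  cells$APE_C <- 100 * (cells$F13C - natC)
  cells$APE_N <- 100 * (cells$F15N - natN)
  hasAlga <- any(cells$partner == "alga" & is.finite(cells$F13C))
  src <- if (hasAlga) sourceCarbonFraction(cells) else {
    warning("no algal cells in the experiment: carbon source composition ",
            "unknown, C_net left NA")
    list(F_substrate_C = NA_real_, n_algal_cells = 0L, sd = NA_real_)
  }
  src$F_substrate_N <- substrate15NFraction(standards)
  src$F_unlabeled_C <- natC
  src$F_unlabeled_N <- natN
  ok <- is.finite(cells$F13C) & hasAlga
  cn <- rep(NA_real_, nrow(cells)); oorC <- rep(NA, nrow(cells))
  if (any(ok)) {
    x <- xNet(cells$F13C[ok], natC, src$F_substrate_C)
    cn[ok] <- as.numeric(x); oorC[ok] <- attr(x, "outOfRange")
  }
  cells$C_net <- cn; cells$C_net_out_of_range <- oorC
  okN <- is.finite(cells$F15N)
  nn <- rep(NA_real_, nrow(cells)); oorN <- rep(NA, nrow(cells))
  xn <- xNet(cells$F15N[okN], natN, src$F_substrate_N)
  nn[okN] <- as.numeric(xn); oorN[okN] <- attr(xn, "outOfRange")
  cells$N_net <- nn; cells$N_net_out_of_range <- oorN
  rownames(cells) <- NULL

  summarize <- function(df, by) {
    sp <- split(df, df[by], drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g) {
      cbind(g[1, by, drop = FALSE],
            data.frame(n_cells = nrow(g),
                       median_C_net = stats::median(g$C_net, na.rm = TRUE),
                       median_N_net = stats::median(g$N_net, na.rm = TRUE),
                       mean_APE_C = mean(g$APE_C, na.rm = TRUE),
                       mean_APE_N = mean(g$APE_N, na.rm = TRUE)))
    }))
    rownames(out) <- NULL
    out
  }
  summary <- summarize(cells, c("partner", "culture", "timepoint_h"))
  pooled <- summarize(cells, c("partner", "timepoint_h"))
  list(cells = cells, source = src, summary = summary, pooled = pooled)
}
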