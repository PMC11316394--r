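# Shared fixture builders; everything is generated in code at test time.

# A small truth table of mixed cells for rendering tests.
mixedTruth <- function(nAlga = 2, nBact = 4, p13Alga = 0.25, p13Bact = 0.05,
                       p15Alga = 0.3, p15Bact = 0.02, timepoint = 48) {
  n <- nAlga + nBact
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    partner = rep(c("alga", "bacterium"), c(nAlga, nBact)),
    true_p13C = rep(c(p13Alga, p13Bact), c(nAlga, nBact)),
    true_p15N = rep(c(p15Alga, p15Bact), c(nAlga, nBact)),
    true_length_um = rep(c(6.5, 1.6), c(nAlga, nBact)),
    culture = "test_rep1", replicate = 1L, timepoint_h = timepoint
  )
}

# Brute-force per-pixel accumulation oracle for ROI sums: a plain double
# loop over every pixel, independent of the vectorized implementation.
bruteForceRoiSums <- function(stack, rois) {
  mask <- roiMask(rois)
  ann <- roiAnnotations(rois)
  out <- lapply(channelNames(stack), function(chn) {
    ch <- ionCounts(stack, chn)
    sums <- stats::setNames(numeric(nrow(ann)), ann$label)
    for (i in seq_len(nrow(mask)))
      for (j in seq_len(ncol(mask))) {
        lab <- mask[i, j]
        if (lab > 0 && as.character(lab) %in% names(sums))
          sums[as.character(lab)] <- sums[as.character(lab)] + ch[i, j]
      }
    sums
  })
  names(out) <- channelNames(stack)
  out
}

# Textbook pooled-variance two-sample t statistic and p value.
textbookT <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    t <- mean(d) / (sd(d) / sqrt(length(d)))
    df <- length(d) - 1
  } else {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}
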