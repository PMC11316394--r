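test_that("standard ratios map to natural atom fractions under each convention", {
  # dimer model at the carbon standard recovers natural 13C abundance
  expect_equal(ratioToAtomFraction(0.02247, "C_dimer"), 0.011110,
               tolerance = 1e-4)
  expect_equal(ratioToAtomFraction(0.00367, "N_cyanide"), 0.003657,
               tolerance = 2e-4)
  expect_identical(ratioToAtomFraction(0, "C_dimer"), 0)
  expect_identical(ratioToAtomFraction(0, "N_cyanide"), 0)
  # the simple convention is a distinct, selectable map
  expect_equal(ratioToAtomFraction(0.02247, "C_dimer", convention = "simple"),
               0.02247 / 1.02247, tolerance = 1e-12)
  expect_error(ratioToAtomFraction(-0.1, "C_dimer"), ">= 0")
})

test_that("ratio <-> atom fraction round-trips to 1e-12 over R in [0, 10]", {
  R <- seq(0, 10, length.out = 401)
  for (sp in c("C_dimer", "N_cyanide")) {
    p <- ratioToAtomFraction(R, sp)
    expect_true(all(p >= 0 & p < 1))
    expect_lt(max(abs(atomFractionToRatio(p, sp) - R)), 1e-12)
  }
  p <- ratioToAtomFraction(R, "C_dimer", convention = "simple")
  expect_lt(max(abs(atomFractionToRatio(p, "C_dimer", convention = "simple") - R)),
            1e-12)
})

test_that("atom percent enrichment is exact arithmetic with a zero at natural", {
  std <- IsotopeStandards()
  expect_identical(apEnrichment(naturalAbundance(std, "C_dimer"),
                                naturalAbundance(std, "C_dimer")), 0)
  expect_identical(apEnrichment(naturalAbundance(std, "N_cyanide"),
                                naturalAbundance(std, "N_cyanide")), 0)
  expect_equal(apEnrichment(0.0611, 0.0111), 5.0, tolerance = 1e-12)
  expect_error(apEnrichment(1.2, 0.01), "\\[0, 1\\]")
})

test_that("killed-control style natural-abundance cells stay below background APE", {
  nat <- 0.02247 / 2.02247
  tr <- data.frame(cell_id = sprintf("k%02d", 1:12), partner = "bacterium",
                   true_p13C = nat, true_p15N = 0.00367 / 1.00367,
                   true_length_um = 2)
  f <- renderSipField(tr, fieldSpec(countsC = 1e5, countsN = 2e4), seed = 17)
  expect_warning(q <- quantifyExperiment(list(f)), "no algal")
  # counting noise alone: ~3 binomial SEs on the APE scale
  expect_lt(max(abs(q$cells$APE_C)), 100 * 6 * sqrt(nat * (1 - nat) / 1e5))
})

test_that("net assimilation formula hits its endpoints and flags excursions", {
  expect_identical(as.numeric(xNet(0.003657, 0.003657, 0.4968)), 0)
  expect_identical(as.numeric(xNet(0.4968, 0.003657, 0.4968)), 1)
  # worked value from the printed label purity and mixing fraction
  Fsub <- 0.5 * 0.99 + 0.5 * 0.003657
  expect_equal(as.numeric(xNet(0.25, 0.003657, Fsub)), 0.4996,
               tolerance = 5e-4)
  x <- xNet(c(0.001, 0.6), 0.003657, 0.4968)
  expect_identical(attr(x, "outOfRange"), c(TRUE, TRUE))
  expect_lt(x[1], 0)           # retained, not clipped
  expect_gt(x[2], 1)
  expect_error(xNet(0.2, 0.1, 0.1), "degenerate")
})

test_that("x_net is strictly increasing in the cell fraction", {
  Fc <- seq(0, 1, length.out = 101)
  x <- as.numeric(xNet(Fc, 0.0111, 0.35))
  expect_true(all(diff(x) > 0))
})

test_that("ROI summation matches a brute-force pixel loop exactly", {
  f <- renderSipField(mixedTruth(), fieldSpec(countsC = 2e4, countsN = 5e3),
                      seed = 23)
  s <- summarizeRois(f$stack, f$rois, minPixels = 1L)
  oracle <- bruteForceRoiSums(f$stack, f$rois)
  for (chn in channelNames(f$stack))
    expect_identical(unname(s[[paste0("counts_", chn)]]),
                     unname(oracle[[chn]][as.character(s$label)]))
})

test_that("ROI summary handles uniform, undersized, and empty inputs", {
  mask <- matrix(0L, 8, 8)
  mask[3, 4:5] <- 1L  # two pixels
  ch <- list(C2 = matrix(50L, 8, 8), C13C = matrix(0L, 8, 8),
             CN = matrix(10L, 8, 8), C15N = matrix(0L, 8, 8))
  stack <- IonImageStack(ch)
  ann <- data.frame(label = 1L, cell_id = "u1", partner = "bacterium",
                    culture = "c", replicate = 1L, timepoint_h = 0)
  s <- summarizeRois(stack, ROISet(mask, ann), minPixels = 1L)
  expect_identical(s$counts_C2, 100)
  # below the size threshold: excluded and reported
  expect_message(s2 <- summarizeRois(stack, ROISet(mask, ann), minPixels = 5L),
                 "below minPixels")
  expect_identical(nrow(s2), 0L)
  expect_identical(attr(s2, "excluded")$label, 1L)
  # empty annotation table warns
  empty <- ROISet(matrix(0L, 8, 8), ann[0, ])
  expect_warning(summarizeRois(stack, empty), "empty")
  # misaligned mask errors with both shapes
  bad <- ROISet(rbind(mask, 0L), ann)
  expect_error(summarizeRois(stack, bad), "does not match image shape")
  # annotating a label absent from the mask is refused at construction
  annBad <- ann; annBad$label <- 7L
  expect_error(ROISet(mask, annBad), "absent from mask")
})

test_that("atom fractions are recovered within binomial error over 200 cells", {
  set.seed(42)
  nCells <- 200L
  p <- seq(0.011, 0.30, length.out = nCells)
  tr <- data.frame(cell_id = sprintf("p%03d", seq_len(nCells)),
                   partner = "bacterium", true_p13C = p, true_p15N = 0.02,
                   true_length_um = 2)
  f <- renderSipField(tr, fieldSpec(widthPx = 600L, heightPx = 600L,
                                    countsC = 1e5, countsN = 1e4), seed = 29)
  s <- summarizeRois(f$stack, f$rois)
  s <- s[order(s$label), ]
  phat <- ratioToAtomFraction(s$counts_C13C / s$counts_C2, "C_dimer")
  err <- abs(phat - p[s$label])
  se <- sqrt(p[s$label] * (1 - p[s$label]) / 1e5)
  expect_identical(nrow(s), nCells)
  expect_lt(median(err / se), 2)
})

test_that("the carbon source estimate is the mean algal composition", {
  rec <- data.frame(partner = c("alga", "alga", "bacterium"),
                    F13C = c(0.1, 0.3, 0.05))
  expect_identical(sourceCarbonFraction(rec)$F_substrate_C, 0.2)
  expect_identical(sourceCarbonFraction(rec)$n_algal_cells, 2L)
  one <- data.frame(partner = "alga", F13C = 0.2)
  expect_identical(sourceCarbonFraction(one)$F_substrate_C, 0.2)
  expect_error(sourceCarbonFraction(data.frame(partner = "bacterium",
                                               F13C = 0.1)),
               "no algal records")
})

test_that("source estimate agrees with generator truth on a synthetic run", {
  sim <- simulateCoculture(defaultScenario("continuous", seed = 19))
  tr <- sim$truth
  alg <- tr[tr$partner == "alga", ]
  est <- mean(alg$true_p13C)
  se <- stats::sd(alg$true_p13C) / sqrt(nrow(alg))
  # time-averaged population truth at the same sampled timepoints
  l <- sim$ledger
  popMean <- mean(vapply(unique(alg$timepoint_h), function(tp)
    l$algal_f13c[which.min(abs(l$time_h - tp))], numeric(1)))
  expect_lt(abs(est - popMean), 3 * se)
})

test_that("whole-experiment quantification keeps cultures separate and pooled", {
  trA <- mixedTruth(); trA$culture <- "dup_rep1"
  trB <- mixedTruth(); trB$culture <- "dup_rep2"; trB$replicate <- 2L
  fA <- renderSipField(trA, fieldSpec(countsC = 5e4, countsN = 1e4), seed = 1)
  fB <- renderSipField(trB, fieldSpec(countsC = 5e4, countsN = 1e4), seed = 2)
  q <- quantifyExperiment(list(fA, fB))
  expect_setequal(unique(q$summary$culture), c("dup_rep1", "dup_rep2"))
  bact <- q$summary[q$summary$partner == "bacterium", ]
  pooledBact <- q$pooled[q$pooled$partner == "bacterium", ]
  expect_identical(sum(pooledBact$n_cells), sum(bact$n_cells))
  # all-natural-abundance field quantifies to ~zero net assimilation
  nat <- 0.02247 / 2.02247; natN <- 0.00367 / 1.00367
  trN <- mixedTruth(p13Alga = 0.3, p13Bact = nat, p15Alga = natN,
                    p15Bact = natN)
  fN <- renderSipField(trN, fieldSpec(countsC = 1e5, countsN = 2e4), seed = 3)
  qN <- quantifyExperiment(list(fN))
  bc <- qN$cells[qN$cells$partner == "bacterium", ]
  expect_lt(max(abs(bc$C_net)), 0.02)
  expect_lt(max(abs(bc$N_net)), 0.02)
})
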