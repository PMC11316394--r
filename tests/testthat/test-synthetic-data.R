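test_that("default continuous scenario plateaus near 4e6 cells/ml, deterministically", {
  sc <- defaultScenario("continuous", seed = 11)
  sim1 <- simulateCoculture(sc)
  sim2 <- simulateCoculture(sc)
  expect_identical(sim1$ledger, sim2$ledger)
  expect_identical(growthData(sim1$growth), growthData(sim2$growth))
  expect_identical(sim1$truth, sim2$truth)
  plateau <- max(sim1$ledger$algal_cells_ml)
  expect_gt(plateau, 3.5e6)
  expect_lt(plateau, 4.5e6)
  # a different seed changes the stochastic layers but not the dynamics
  sim3 <- simulateCoculture(defaultScenario("continuous", seed = 12))
  expect_identical(sim3$ledger, sim1$ledger)
  expect_false(identical(sim3$truth$true_p13C, sim1$truth$true_p13C))
})

test_that("without any released carbon the bacteria cannot grow", {
  sc <- defaultScenario("continuous", seed = 2, exudationRate = 0,
                        lysisFractionPerDay = 0)
  sim <- simulateCoculture(sc)
  expect_true(all(sim$ledger$bacterial_cfu_ml <= sc@bacterialN0 + 1e-9))
})

test_that("bacterial assimilation never exceeds released carbon (conservation)", {
  for (regime in c("continuous", "diurnal_12_12")) {
    sim <- simulateCoculture(defaultScenario(regime, seed = 5))
    l <- sim$ledger
    expect_true(all(l$cum_carbon_consumed_cfu_eq <=
                      l$cum_carbon_supply_cfu_eq + 1e-6))
    expect_true(all(l$carbon_pool_cfu_eq >= -1e-6))
  }
})

test_that("diurnal algal populations double only at dark onset", {
  sim <- simulateCoculture(defaultScenario("diurnal_12_12", seed = 4))
  l <- sim$ledger
  growing <- which(diff(l$algal_cells_ml) > 0)
  tGrow <- l$time_h[growing + 1]
  # every population increase happens in the integration step entering a
  # dark phase (hour 12 of each day)
  expect_true(all(abs((tGrow %% 24) - 12) < 0.11))
  # and the bacterial truth enrichment rises only after the label starts
  sc <- sim$scenario
  expect_true(all(l$bacterial_f13c[l$time_h <= sc@labelStartH] -
                    l$bacterial_f13c[1] < 1e-12))
  expect_gt(max(l$bacterial_f13c), l$bacterial_f13c[1])
})

test_that("bacterial 13C truth approaches a sub-unity fraction of algal truth", {
  sim <- simulateCoculture(defaultScenario("continuous", seed = 6))
  l <- sim$ledger
  end <- nrow(l)
  natC <- 0.02247 / 2.02247
  relEnrich <- (l$bacterial_f13c[end] - natC) / (l$algal_f13c[end] - natC)
  expect_gt(relEnrich, 0.02)
  expect_lt(relEnrich, 1)
})

test_that("rendered ion images partition counts by the dimer model", {
  # a natural-abundance cell yields the standard ratio
  nat <- 0.02247 / 2.02247
  tr <- data.frame(cell_id = "nat1", partner = "alga", true_p13C = nat,
                   true_p15N = 0, true_length_um = 8)
  f <- renderSipField(tr, fieldSpec(countsC = 2e6, countsN = 1e5), seed = 9)
  s <- summarizeRois(f$stack, f$rois)
  R <- s$counts_C13C / s$counts_C2
  expect_equal(R, 0.02247, tolerance = 0.02)
  # zero 15N label: the C15N channel is exactly empty inside the cell
  inCell <- roiMask(f$rois) == 1L
  expect_true(all(ionCounts(f$stack, "C15N")[inCell] == 0L))
})

test_that("quantified atom fraction recovers truth within binomial error", {
  p <- 0.05
  tr <- data.frame(cell_id = "b1", partner = "bacterium", true_p13C = p,
                   true_p15N = 0.01, true_length_um = 2)
  f <- renderSipField(tr, fieldSpec(countsC = 1e5), seed = 13)
  s <- summarizeRois(f$stack, f$rois)
  phat <- ratioToAtomFraction(s$counts_C13C / s$counts_C2, "C_dimer")
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(phat - p), 3 * se)
})

test_that("per-pixel counts are Poisson across many rendered cells", {
  # >= 500 rods; within a cell the expectation is flat, so the per-cell
  # variance/mean ratio of its pixels estimates the Poisson index
  tr <- data.frame(cell_id = sprintf("r%03d", 1:500), partner = "bacterium",
                   true_p13C = 0.05, true_p15N = 0.02, true_length_um = 2)
  f <- renderSipField(tr, fieldSpec(widthPx = 900L, heightPx = 900L,
                                    countsC = 2e4, countsN = 1e4),
                      seed = 21)
  mask <- roiMask(f$rois)
  ch <- ionCounts(f$stack, "C2")
  idx <- split(ch[mask > 0L], mask[mask > 0L])
  vm <- vapply(idx, function(v) stats::var(v) / mean(v), numeric(1))
  expect_gt(mean(vm), 0.9)
  expect_lt(mean(vm), 1.1)
})

test_that("explicitly positioned overlapping cells raise an error naming them", {
  tr <- mixedTruth(nAlga = 0, nBact = 2)
  tr$x_um <- c(10, 10.2)
  tr$y_um <- c(10, 10)
  expect_error(renderSipField(tr, fieldSpec(), seed = 1),
               "overlapping cells.*c001.*c002|overlapping cells.*c002.*c001")
})

test_that("field capacity errors are informative, not silent", {
  tr <- mixedTruth(nAlga = 30, nBact = 0)
  expect_error(renderSipField(tr, fieldSpec(widthPx = 128L, heightPx = 128L),
                              seed = 1),
               "cannot hold")
})

test_that("simulated bioassay plates behave like the two-strain assay", {
  plate <- simulateBioassayPlate(c(0, 50), seed = 31)
  ctrl <- plate[plate$strain == "dmetE_dmetH", ]
  byLevel <- tapply(ctrl$od600, ctrl$sample_id, mean)
  # the control strain cannot respond to B12: level means within noise
  expect_lt(diff(range(byLevel)), 5 * 0.01)
  # no cofactor, no differential growth
  me <- plate[plate$strain == "dmetE", ]
  z <- mean(me$od600[me$sample_id == "sample_01"]) -
    mean(ctrl$od600[ctrl$sample_id == "sample_01"])
  expect_lt(abs(z), 5 * 0.01)
  # negative noiseSd is refused
  expect_error(simulateBioassayPlate(10, noiseSd = -1), "noiseSd")
})

test_that("scenario and image bundles round-trip through disk", {
  sc <- defaultScenario("diurnal_12_12", seed = 8)
  f1 <- tempfile(fileext = ".yaml")
  writeScenarioYaml(sc, f1)
  sc2 <- readScenarioYaml(f1)
  expect_equal(sc2@exudationRate, sc@exudationRate)
  expect_identical(sc2@lightRegime, sc@lightRegime)
  expect_identical(sc2@seed, sc@seed)

  tr <- mixedTruth()
  f <- renderSipField(tr, fieldSpec(), seed = 3)
  pre <- file.path(tempdir(), "fieldio")
  writeIonImageStack(f$stack, pre)
  writeRoiSet(f$rois, pre)
  st2 <- readIonImageStack(pre)
  ro2 <- readRoiSet(pre)
  for (chn in channelNames(f$stack))
    expect_identical(ionCounts(st2, chn), ionCounts(f$stack, chn))
  expect_identical(roiMask(ro2), roiMask(f$rois))
  expect_equal(roiAnnotations(ro2)$cell_id, roiAnnotations(f$rois)$cell_id)
})
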