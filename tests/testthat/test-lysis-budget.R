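test_that("yield per lysed cell reproduces the lysate worked example", {
  y <- yieldPerLysedCell(1.7e8, 0, 1.6e6)
  expect_identical(y$yield, 106.25)
  expect_identical(y$headline, 100)
  expect_true(is.na(y$sd))
  expect_identical(yieldPerLysedCell(5e6, 5e6, 1e6)$yield, 0)
  yr <- yieldPerLysedCell(c(90, 100, 110) * 1e6, 0, 1e6)
  expect_identical(yr$yield, 100)
  expect_identical(yr$sd, 10)
  expect_error(yieldPerLysedCell(1e6, 0, 0), "> 0")
  expect_error(yieldPerLysedCell(1e6, 2e6, 1e6), "baseline exceeds")
})

test_that("required lysed density and fraction are exact ratios", {
  expect_identical(requiredLysedDensity(1.1e7, 100), 1.1e5)
  expect_identical(requiredLysedDensity(0, 100), 0)
  expect_error(requiredLysedDensity(1e6, 0), "> 0")
  expect_equal(requiredLysisFraction(1.1e5, 6.1e6), 1.803279,
               tolerance = 1e-6)
  expect_identical(requiredLysisFraction(0, 1e6), 0)
  expect_identical(requiredLysisFraction(1e6, 1e6), 100)
  expect_error(requiredLysisFraction(1, 0), "> 0")
})

test_that("budget closure and scale invariance hold for arbitrary inputs", {
  set.seed(3)
  for (i in 1:25) {
    prolif <- runif(1, 1e5, 1e8)
    yield <- runif(1, 10, 500)
    req <- requiredLysedDensity(prolif, yield)
    expect_equal(req * yield, prolif, tolerance = 1e-12)
    # doubling both the net CFU gain and the lysed density leaves yield fixed
    cfu <- runif(1, 1e7, 1e9); base <- cfu * runif(1, 0, 0.5)
    dens <- runif(1, 1e5, 1e7)
    y1 <- yieldPerLysedCell(cfu, base, dens)$yield
    y2 <- yieldPerLysedCell(base + 2 * (cfu - base), base, 2 * dens)$yield
    expect_equal(y1, y2, tolerance = 1e-9)
  }
})

test_that("consistency verdicts cover the three regimes", {
  b <- lysisBudget(1.7e8, 0, 1.6e6, 1.1e7, 6.1e6)
  expect_identical(lysisConsistency(b, c(1, 3))$verdict, "consistent")
  bHigh <- lysisBudget(1.7e8, 0, 1.6e6, 6.1e7, 6.1e6)  # 10% required
  vHigh <- lysisConsistency(bHigh, c(1, 3))
  expect_identical(vHigh$verdict, "insufficient_lysis")
  expect_gt(vHigh$margin_pct, 0)
  bLow <- lysisBudget(1.7e8, 0, 1.6e6, 3.05e6, 6.1e6)  # 0.5% required
  expect_identical(lysisConsistency(bLow, c(1, 3))$verdict, "excess_lysis")
})

test_that("the packaged fixture reproduces the published budget numbers", {
  cfg <- yaml::read_yaml(system.file("extdata", "coculture_default.yaml",
                                     package = "sipCoculture"))
  b <- lysisBudget(cfg$cfu_in_lysate, cfg$cfu_baseline,
                   cfg$lysed_algal_density, cfg$observed_proliferation,
                   cfg$algal_density)
  expect_identical(b$yield, 106.25)
  expect_identical(b$yield_headline, 100)
  expect_identical(b$required_lysed_density, 1.1e5)
  expect_equal(b$required_fraction_pct, 1.8, tolerance = 0.01)
  v <- lysisConsistency(b, unlist(cfg$measured_lysis_range_pct))
  expect_identical(v$verdict, "consistent")
})

test_that("replicate uncertainty propagates to the required fraction", {
  b <- lysisBudget(c(1.5e8, 1.7e8, 1.9e8), 0, 1.6e6, 1.1e7, 6.1e6)
  expect_gt(b$yield_sd, 0)
  expect_gt(b$required_fraction_sd_pct, 0)
  # relative sd of the fraction matches the delta-method combination
  relY <- b$yield_sd / b$yield
  expect_equal(b$required_fraction_sd_pct / b$required_fraction_pct, relY,
               tolerance = 1e-9)
})

test_that("inferred lysis matches the generator truth on a lysis-only run", {
  sc <- defaultScenario("continuous", seed = 3, exudationRate = 0,
                        algalK = 6.1e6)
  sim <- simulateCoculture(sc)
  l <- sim$ledger
  end <- nrow(l)
  prolif <- l$bacterial_cfu_ml[end] - l$bacterial_cfu_ml[1]
  inferred <- requiredLysedDensity(prolif, sc@bacterialYieldPerLysedCell)
  trueLysed <- l$cum_lysed_cells_ml[end]
  # the unconsumed carbon pool makes the inference a slight underestimate
  expect_lte(inferred, trueLysed * (1 + 1e-9))
  expect_lt(abs(inferred - trueLysed) / trueLysed, 0.2)
  fracInferred <- requiredLysisFraction(inferred, l$algal_cells_ml[end])
  fracTrue <- 100 * trueLysed / l$algal_cells_ml[end]
  expect_lt(abs(fracInferred - fracTrue), 0.5)
})
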