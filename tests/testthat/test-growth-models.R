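test_that("doublings are log2 fold-changes with decline flagged", {
  expect_identical(as.numeric(doublings(1e6, 2e6)), 1)
  expect_identical(as.numeric(doublings(1e6, 8e6)), 3)
  expect_identical(as.numeric(doublings(5e5, 5e5)), 0)
  d <- doublings(2e6, 1e6)
  expect_identical(as.numeric(d), -1)
  expect_true(attr(d, "declined"))
  expect_error(doublings(0, 1e6), "positive")
})

test_that("expected net synthesis follows 1 - 2^(-d)", {
  expect_identical(expectedXnet(0), 0)
  expect_identical(expectedXnet(5), 0.96875)       # prints as 0.97
  expect_equal(expectedXnet(8), 0.99609375)
  expect_true(all(expectedXnet(seq(8, 13, by = 0.25)) >= 0.99))
  d <- seq(0, 20, by = 0.1)
  e <- expectedXnet(d)
  expect_true(all(diff(e) > 0))    # strictly increasing
  expect_true(all(e < 1))          # asymptote, never reached
  expect_gt(expectedXnet(40), 1 - 1e-10)
  expect_error(expectedXnet(-1), ">= 0")
})

test_that("starved cocultures are flagged for reductive division, balanced growth is not", {
  mkSeries <- function(dens) GrowthSeries(data.frame(
    time_h = rep(c(0, 12, 24, 36), 2), condition = "c",
    replicate = rep(1:2, each = 4), partner = "bacterium",
    density = rep(dens, 2), unit = "CFU/ml"))
  # coculture-like: CFUs multiply but measured assimilation stays low
  co <- mkSeries(c(1e6, 2.7e6, 5.4e6, 8e6))   # d = 1.43, 2.43, 3
  meas <- data.frame(timepoint_h = c(12, 24, 36), xnet = c(0.18, 0.27, 0.34))
  a <- assessSynthesis(co, meas)
  expect_true(all(a$reductive_division_flag))
  expect_true(all(a$expected_xnet > 0.6 & a$expected_xnet < 0.98))
  expect_true(min(a$timepoint_h[a$reductive_division_flag]) <= 24)
  # balanced log-phase growth on sucrose: measured tracks expected
  su <- mkSeries(c(1e6, 4e6, 1.6e7, 6.4e7))
  expd <- expectedXnet(c(2, 4, 6))
  b <- assessSynthesis(su, data.frame(timepoint_h = c(12, 24, 36),
                                      xnet = expd * 0.95))
  expect_false(any(b$reductive_division_flag))
  # exact agreement: zero gap, no flag
  c_ <- assessSynthesis(su, data.frame(timepoint_h = c(12, 24, 36),
                                       xnet = expd))
  expect_equal(c_$gap, rep(0, 3), tolerance = 1e-12)
  expect_false(any(c_$reductive_division_flag))
  expect_error(assessSynthesis(su, data.frame(timepoint_h = 17, xnet = 0.5)),
               "no growth observation")
})

test_that("once released carbon is spent, continued division gets flagged", {
  # sucrose depletion: density keeps rising one more doubling while
  # measured assimilation stalls - the flag turns on only then
  s <- GrowthSeries(data.frame(
    time_h = c(0, 12, 24, 36), condition = "suc", replicate = 1,
    partner = "bacterium", density = c(1e6, 4e6, 1.6e7, 3.2e7),
    unit = "CFU/ml"))
  meas <- data.frame(timepoint_h = c(12, 24, 36),
                     xnet = c(expectedXnet(2), expectedXnet(4), 0.3))
  a <- assessSynthesis(s, meas)
  expect_identical(a$reductive_division_flag, c(FALSE, FALSE, TRUE))
})

test_that("cell length statistics and reductions are exact", {
  st <- lengthStats(c(2, 2, 2))
  expect_identical(st$mean, 2)
  expect_identical(st$sd, 0)
  expect_identical(st$n, 3L)
  expect_equal(percentReduction(2.3, 1.45), 36.95652, tolerance = 1e-5)
  expect_identical(percentReduction(2, 2), 0)
  expect_true(all(percentReduction(2.3, c(0.1, 1, 2.2)) < 100))
  expect_error(lengthStats(numeric(0)), "empty")
  expect_error(lengthStats(c(1, -1)), "positive")
})

test_that("max-density folds use replicate means and check units", {
  mk <- function(dens, unit = "CFU/ml") GrowthSeries(data.frame(
    time_h = rep(c(0, 24, 48), 2), condition = "x",
    replicate = rep(1:2, each = 3), partner = "bacterium",
    density = dens, unit = unit))
  a <- mk(c(1e6, 5e7, 6e7, 1e6, 7e7, 6e7))
  b <- mk(c(1e6, 2e7, 1.5e7, 1e6, 2e7, 2.5e7))
  f <- maxDensityFold(a, b)
  expect_identical(f$fold, 3)  # maxima of replicate means: 6e7 / 2e7
  expect_identical(f$replicate_max_a, c(`1` = 6e7, `2` = 7e7))
  expect_identical(maxDensityFold(a, a)$fold, 1)
  expect_error(maxDensityFold(a, mk(rep(1, 6), unit = "cells/ml")),
               "unit mismatch")
})

test_that("t-test wrapper reproduces the textbook statistic to 1e-12", {
  x <- c(1.2, 3.4, 2.2); y <- c(4.1, 5.0, 3.3)
  got <- tTestTwoTailed(x, y)
  ref <- textbookT(x, y)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
  gotP <- tTestTwoTailed(x, y, paired = TRUE)
  refP <- textbookT(x, y, paired = TRUE)
  expect_equal(gotP$statistic, refP$statistic, tolerance = 1e-12)
  expect_equal(gotP$p_value, refP$p_value, tolerance = 1e-12)
  # degenerate identical samples: the documented t = 0, p = 1 convention
  expect_message(z <- tTestTwoTailed(c(1, 1, 1), c(1, 1, 1)), "zero variance")
  expect_identical(z$p_value, 1)
  expect_identical(z$statistic, 0)
  expect_error(tTestTwoTailed(1, c(1, 2)), "n >= 2")
  expect_error(tTestTwoTailed(c(1, 2), c(1, 2, 3), paired = TRUE),
               "equal n")
})

test_that("the t-test holds its nominal type-I error rate under the null", {
  set.seed(7)
  nRep <- 10000
  n <- 6
  x <- matrix(rnorm(nRep * n), nRep)
  y <- matrix(rnorm(nRep * n), nRep)
  rej <- vapply(seq_len(nRep), function(i)
    tTestTwoTailed(x[i, ], y[i, ])$p_value < 0.05, logical(1))
  rate <- mean(rej)
  mcSe <- sqrt(0.05 * 0.95 / nRep)
  expect_gt(rate, 0.05 - 3 * mcSe)
  expect_lt(rate, 0.05 + 3 * mcSe)
})
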