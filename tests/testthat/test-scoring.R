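test_that("standardize yields exact closed forms and unit moments", {
  # two-point closed form under the default sample-sd convention
  expect_equal(standardize(c(0, 1)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(standardize(c(0, 1), sdType = "population"), c(-1, 1),
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(257, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    z <- standardize(x)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
    expect_identical(order(z), order(x))  # order-preserving
  }
})

test_that("standardize matches an independent one-liner on 1,024 channels", {
  x <- intensities(simulateSpectrum(500, seed = 301)$spectrum)
  expect_equal(standardize(x), (x - mean(x)) / sd(x), tolerance = 1e-12)
})

test_that("standardize rejects degenerate input", {
  expect_error(standardize(rep(2, 10)), "degenerate")
  expect_error(standardize(3), "at least 2")
})

test_that("bandScore windows the spike correctly", {
  wn <- gridPoints(wavenumberGrid())
  z <- numeric(1024)
  z[which.min(abs(wn - 970))] <- 6
  hit <- bandScore(z, wn, c(944, 1005))
  expect_equal(hit$score, 6)
  expect_equal(hit$wavenumber, wn[which.min(abs(wn - 970))])
  # a different window sees only the flat background
  expect_equal(bandScore(z, wn, c(1366, 1373))$score, 0)
  expect_error(bandScore(z, wn, c(2000, 2010)), "no grid points")
})

test_that("bandScore equals an exhaustive in-window scan", {
  set.seed(32)
  wn <- gridPoints(wavenumberGrid())
  for (i in 1:10) {
    z <- rnorm(1024)
    lo <- runif(1, 204, 1900)
    hi <- lo + runif(1, 5, 80)
    expect_equal(bandScore(z, wn, c(lo, hi))$score,
                 scanBandMax(z, wn, lo, hi))
  }
})

test_that("zRatio applies quotient, floor gate and division guard", {
  expect_equal(zRatio(3, 1.5, detectFloor = 1), 2)
  expect_equal(zRatio(0.4, 0.3, detectFloor = 1), 0)   # undetected
  expect_equal(zRatio(5, 1e-9), 0)                     # guard, not Inf
  expect_equal(zRatio(-2, 0.5, detectFloor = 0), -4)   # sign preserved
  expect_error(zRatio(Inf, 1), "finite")
})

test_that("default bands reproduce the published reading intervals", {
  b <- bandSet()
  expect_equal(b@monomerNaphthenic, c(944, 1005))
  expect_equal(b@monomerCarboxylic, c(1366, 1373))
  expect_equal(b@dimerNaphthenic, c(1017, 1033))  # 1025 +/- resolution
  expect_equal(b@dimerCarboxylic, c(1465, 1482))
  expect_equal(bandSet(dimerNaphHalfWindow = 2)@dimerNaphthenic,
               c(1023, 1027))
})

test_that("scoreSample composes ratios, sum and decisions coherently", {
  sim <- simulateSpectrum(700, seed = 33, phi = 0.5)
  sc <- scoreSample(sim$spectrum)
  expect_s4_class(sc, "SampleScore")
  expect_equal(sumScore(sc), sc@ratioMonomer + sc@ratioDimer,
               tolerance = 1e-9)
  # ratios equal the quotient of independently recomputed band maxima
  fit <- airplsBaseline(intensities(sim$spectrum), airplsConfig())
  z <- standardize(corrected(fit))
  wn <- wavenumbers(sim$spectrum)
  zNM <- scanBandMax(z, wn, 944, 1005)
  zCM <- scanBandMax(z, wn, 1366, 1373)
  if (max(zNM, zCM) >= 1)
    expect_equal(sc@ratioMonomer, zNM / zCM, tolerance = 1e-9)
  # deterministic for fixed input
  sc2 <- scoreSample(simulateSpectrum(700, seed = 33, phi = 0.5)$spectrum)
  expect_equal(sumScore(sc2), sumScore(sc))
})

test_that("screening decisions honor thresholds and inclusivity", {
  mk <- function(sum) {
    # build a SampleScore through the public constructor path by scaling
    # the rules instead: decisions are pure functions of sum and rules
    rules <- ruleConfig()
    list(fluct = sum >= rules$fluctuation, high = sum >= rules$rule5)
  }
  expect_true(mk(7.85)$high)
  expect_false(mk(4.62)$high)
  expect_true(mk(4.62)$fluct)
  expect_true(mk(5.00)$high)       # inclusive boundary
  strict <- ruleConfig(inclusive = FALSE)
  expect_false(5.00 > strict$rule5)

  # decision monotonicity on real scored samples: raising the sum never
  # flips high-risk back to low-risk
  sums <- sort(sapply(c(41, 42, 43), function(s)
    sumScore(scoreSample(simulateSpectrum(600, seed = s)$spectrum))))
  flags <- sums >= 5
  expect_true(all(diff(as.integer(flags)) >= 0))
})

test_that("the bundled cohort satisfies printed-rounding additivity", {
  df <- table2Data()
  # half-ULP of the 3-significant-figure entries (10.3 prints A+B = 10.32)
  expect_true(all(abs(df$z_ratio_monomer + df$z_ratio_dimer -
                        df$sum_z_ratio) <= 0.025))
})
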