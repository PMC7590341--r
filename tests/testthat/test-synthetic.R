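test_that("a blank, noiseless, interference-free spectrum is pure baseline", {
  cfg <- syntheticConfig(noiseSd = 0, nInterferencePeaks = 0L)
  sim <- simulateSpectrum(0, cfg, seed = 61)
  v <- gridPoints(cfg@grid)
  expect_equal(intensities(sim$spectrum),
               syntheticBaseline(v, cfg@baselineCoeffs), tolerance = 1e-12)
  expect_true(all(sim$truth$peaks$amplitude[
    sim$truth$peaks$species != "matrix"] == 0))
})

test_that("a noiseless monomer-only spectrum matches its closed form", {
  cfg <- syntheticConfig(noiseSd = 0, nInterferencePeaks = 0L, shiftSd = 0)
  sim <- simulateSpectrum(600, cfg, seed = 62, phi = 1)
  v <- gridPoints(cfg@grid)
  tr <- sim$truth$peaks
  mono <- tr[tr$species == "monomer", ]
  hill <- (600 / 400)^3 / (1 + (600 / 400)^3)
  expect_equal(mono$amplitude[mono$band == "naphthenic"],
               cfg@monomerGain * 600 * hill, tolerance = 1e-12)
  # reconstruct from the truth record
  expected <- syntheticBaseline(v, cfg@baselineCoeffs)
  for (i in seq_len(nrow(tr)))
    expected <- expected + tr$amplitude[i] * tr$gamma[i]^2 /
      ((v - tr$center[i])^2 + tr$gamma[i]^2)
  expect_equal(intensities(sim$spectrum), expected, tolerance = 1e-12)
  # dimer windows hold baseline only (phi = 1 removes the dimer)
  expect_true(all(tr$amplitude[tr$species == "dimer"] == 0))
})

test_that("peak centres always stay inside their reading windows", {
  b <- bandSet()
  wins <- list(monomer.naphthenic = b@monomerNaphthenic,
               monomer.carboxylic = b@monomerCarboxylic,
               dimer.naphthenic = b@dimerNaphthenic,
               dimer.carboxylic = b@dimerCarboxylic)
  for (s in 1:50) {
    tr <- simulateSpectrum(700, seed = 6200 + s)$truth$peaks
    ba <- tr[tr$species != "matrix", ]
    for (i in seq_len(nrow(ba))) {
      w <- wins[[paste(ba$species[i], ba$band[i], sep = ".")]]
      expect_gte(ba$center[i], w[1])
      expect_lte(ba$center[i], w[2])
    }
  }
})

test_that("simulation is reproducible and seeds are independent", {
  a <- simulateSpectrum(400, seed = 63)
  b <- simulateSpectrum(400, seed = 63)
  expect_equal(intensities(a$spectrum), intensities(b$spectrum))
  expect_equal(a$truth$phi, b$truth$phi)
  c <- simulateSpectrum(400, seed = 64)
  expect_false(identical(intensities(a$spectrum), intensities(c$spectrum)))
})

test_that("dose response through the full pipeline rises with concentration", {
  sumAt <- function(conc, seeds) sapply(seeds, function(s)
    sumScore(scoreSample(simulateSpectrum(conc, seed = 7000 + 13 * s +
                                            round(conc))$spectrum)))
  lo <- sumAt(50, 1:30)
  hi <- sumAt(500, 1:30)
  expect_gt(mean(hi), mean(lo))
  expect_gt(median(hi), median(lo) + 3)
})

test_that("no dimer signal is scored below the onset concentration", {
  ratios <- sapply(1:100, function(s) {
    conc <- (s %% 7) * 49  # 0..294 ppm, all below the 350 ppm onset
    zRatios(scoreSample(simulateSpectrum(conc, seed = 7100 + s)$spectrum))["dimer"]
  })
  expect_gte(mean(ratios == 0), 0.99)
})

test_that("simulateCohort reproduces exactly under one seed", {
  a <- simulateCohort(15, seed = 65)
  b <- simulateCohort(15, seed = 65)
  expect_equal(sumScore(a$cohort), sumScore(b$cohort))
  expect_equal(hplcPpm(a$cohort), hplcPpm(b$cohort))
  # degenerate mixture puts every sample at 0 ppm
  z <- simulateCohort(10, mixture = list(zeroWeight = 1), seed = 66)
  expect_true(all(hplcPpm(z$cohort) == 0))
  expect_error(simulateCohort(5, mixture = list(zeroWeight = 2)), "zeroWeight")
})

test_that("calibration recovers an exact line and closed-form limits", {
  co <- labeledCohort(1:6, 0.01 * seq(400, 900, by = 100) + 2,
                      seq(400, 900, by = 100))
  fit <- fitCalibration(co, rangePpm = c(380, 920), blankScores = c(1, 1, 1))
  expect_equal(fit@slope, 0.01, tolerance = 1e-9)
  expect_equal(fit@intercept, 2, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_equal(fit@lodPpm, 0)   # zero blank scatter
  expect_equal(fit@loqPpm, 0)

  # known blank sd and slope give the conventional 3.3/10 sigma limits
  set.seed(67)
  blanks <- rnorm(200, 0, 0.3)
  fit2 <- fitCalibration(co, rangePpm = c(380, 920), blankScores = blanks)
  expect_equal(fit2@lodPpm, 3.3 * sd(blanks) / 0.01, tolerance = 1e-9)
  expect_equal(fit2@loqPpm, 10 * sd(blanks) / 0.01, tolerance = 1e-9)
  expect_gte(fit2@loqPpm, fit2@lodPpm)
  expect_error(fitCalibration(co, c(0, 100), blanks), "at least 3")
})

test_that("airpls recovers the generator's baseline off-peak within 2% RMS", {
  for (s in c(68, 69, 70)) {
    sim <- simulateSpectrum(600, seed = s)
    fit <- airplsBaseline(intensities(sim$spectrum), airplsConfig())
    v <- wavenumbers(sim$spectrum)
    off <- rep(TRUE, length(v))
    tr <- sim$truth$peaks
    for (i in seq_len(nrow(tr)))
      if (tr$amplitude[i] > 0)
        off[abs(v - tr$center[i]) < 6 * tr$gamma[i]] <- FALSE
    rel <- sqrt(mean((baseline(fit)[off] - sim$truth$baseline[off])^2)) /
      sqrt(mean(sim$truth$baseline[off]^2))
    expect_lt(rel, 0.02)
  }
})
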