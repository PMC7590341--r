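test_that("whittakerSmooth leaves penalty null spaces untouched", {
  # constants are penalty-free for any order, lines for order 2
  z <- whittakerSmooth(rep(3.7, 50), rep(1, 50), lambda = 1e4)
  expect_equal(z, rep(3.7, 50), tolerance = 1e-9)

  y <- 2 + 0.5 * seq_len(64)
  z2 <- whittakerSmooth(y, rep(1, 64), lambda = 1e6, diffOrder = 2L)
  expect_equal(z2, y, tolerance = 1e-7)
})

test_that("whittakerSmooth equals the dense normal-equations oracle", {
  set.seed(21)
  for (k in c(1L, 2L)) {
    for (lambda in c(1, 10, 1000)) {
      y <- rnorm(32)
      w <- runif(32, 0.1, 2)
      expect_equal(whittakerSmooth(y, w, lambda, k),
                   as.numeric(denseWhittaker(y, w, lambda, k)),
                   tolerance = 1e-8)
    }
  }
  # mixed zero/positive weights, n up to 64
  y <- rnorm(64)
  w <- rep(c(0, 1), 32)
  expect_equal(whittakerSmooth(y, w, 10, 2L),
               as.numeric(denseWhittaker(y, w, 10, 2L)), tolerance = 1e-8)
})

test_that("whittakerSmooth rejects degenerate input", {
  expect_error(whittakerSmooth(rnorm(10), rep(0, 10), 1), "degenerate")
  expect_error(whittakerSmooth(c(1, NA, 3), rep(1, 3), 1), "finite")
  expect_error(whittakerSmooth(rnorm(10), rep(1, 10), -1), "positive")
  expect_error(whittakerSmooth(rnorm(2), rep(1, 2), 1, 2L), "at least")
})

test_that("large lambda with order 2 converges to the least-squares line", {
  set.seed(22)
  y <- rnorm(100, sd = 2)
  z <- whittakerSmooth(y, rep(1, 100), 1e10, 2L)
  lineFit <- lm(y ~ seq_along(y))
  expect_equal(z, unname(fitted(lineFit)), tolerance = 1e-4)
})

test_that("airplsBaseline removes smooth drift nearly completely", {
  wn <- gridPoints(wavenumberGrid())
  drift <- 3 + 6 * exp(-wn / 700)
  fit <- airplsBaseline(drift, airplsConfig(lambda = 100))
  expect_lt(max(abs(corrected(fit))) / diff(range(drift)), 0.01)
})

test_that("airplsBaseline preserves peaks while tracking drift", {
  wn <- gridPoints(wavenumberGrid())
  drift <- 1 + 0.002 * wn
  lorentz <- function(c0, a) a * 36 / ((wn - c0)^2 + 36)
  peaks <- lorentz(600, 2) + lorentz(1000, 3) + lorentz(1500, 1.5)
  # a stiff penalty keeps the baseline out of the peaks; the flexible
  # default attenuates apexes (both ratio bands alike), see the vignette
  fit <- airplsBaseline(drift + peaks, airplsConfig(lambda = 1e5))
  # apex heights survive within 5%
  for (p in list(c(600, 2), c(1000, 3), c(1500, 1.5))) {
    apex <- corrected(fit)[which.min(abs(wn - p[1]))]
    expect_lt(abs(apex - p[2]) / p[2], 0.05)
  }
  # off-peak baseline tracks the true drift within 2% RMS
  off <- abs(wn - 600) > 60 & abs(wn - 1000) > 60 & abs(wn - 1500) > 60
  rel <- sqrt(mean((baseline(fit)[off] - drift[off])^2)) /
    sqrt(mean(drift[off]^2))
  expect_lt(rel, 0.02)
})

test_that("asymmetric weighting absorbs negative-going features", {
  # points above the fit get weight 0 while points below keep positive
  # weight, so the fit chases downward excursions: dips are swallowed by
  # the baseline instead of surviving subtraction
  wn <- seq(0, 100, length.out = 512)
  dips <- -3 * exp(-((wn - 30) / 3)^2) - 2 * exp(-((wn - 70) / 4)^2)
  y <- 5 + dips
  fit <- airplsBaseline(y, airplsConfig(lambda = 1000))
  # residual dip depth is a small fraction of the input depth of 3
  expect_gt(min(corrected(fit)), -0.15 * 3)
  # the baseline is dragged well below the plateau at both dip centres
  for (c0 in c(30, 70))
    expect_lt(baseline(fit)[which.min(abs(wn - c0))], 4)
  # while the plateau itself stays essentially at or above the fit
  # (small smoothness ripples aside)
  plateau <- abs(wn - 30) > 15 & abs(wn - 70) > 15
  expect_gt(mean(corrected(fit)[plateau] >= -0.05), 0.95)
})

test_that("iteration weights are zero above the baseline, positive below", {
  set.seed(23)
  wn <- gridPoints(wavenumberGrid())
  y <- 2 + 4 * exp(-wn / 600) + 3 * 36 / ((wn - 900)^2 + 36) +
    rnorm(1024, sd = 0.01)
  fit <- airplsBaseline(y, airplsConfig(), keepWeights = TRUE)
  expect_gte(length(fit@weightHistory), 2L)
  for (t in 2:length(fit@weightHistory)) {
    w <- fit@weightHistory[[t]]
    zPrev <- whittakerSmooth(y, fit@weightHistory[[t - 1]], 100, 2L)
    d <- y - zPrev
    inner <- 2:1023  # endpoints follow their own rule
    expect_true(all(w[inner][d[inner] >= 0] == 0))
    expect_true(all(w[inner][d[inner] < 0] > 0))
  }
})

test_that("airplsBaseline is scale-equivariant", {
  set.seed(24)
  wn <- gridPoints(wavenumberGrid())
  y <- 1 + 3 * exp(-wn / 500) + 2 * 36 / ((wn - 1200)^2 + 36) +
    rnorm(1024, sd = 0.01)
  f1 <- airplsBaseline(y, airplsConfig())
  f2 <- airplsBaseline(7.5 * y, airplsConfig())
  expect_equal(baseline(f2), 7.5 * baseline(f1), tolerance = 1e-6)
  expect_equal(corrected(f2), 7.5 * corrected(f1), tolerance = 1e-6)
})

test_that("convergence flag and iteration count are reported honestly", {
  wn <- gridPoints(wavenumberGrid())
  smooth <- 2 + 3 * exp(-wn / 800)
  f <- airplsBaseline(smooth, airplsConfig(maxIter = 15L))
  expect_true(f@converged)
  expect_lte(f@nIter, 15L)
  # a single permitted iteration cannot satisfy the tolerance on peaky data
  peaky <- smooth + 5 * 36 / ((wn - 1000)^2 + 36)
  f2 <- airplsBaseline(peaky, airplsConfig(maxIter = 1L, tolRatio = 1e-6))
  expect_false(f2@converged)
  expect_identical(f2@nIter, 1L)
  expect_equal(corrected(f2), peaky - baseline(f2))
})
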