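# Independent reference implementations used to cross-check the package.
# Each is written from the mathematical definition, not from the package
# code paths it checks.

# dense normal-equations solve of the Whittaker problem
denseWhittaker <- function(y, w, lambda, k = 2L) {
  n <- length(y)
  D <- diff(diag(n), differences = k)
  solve(diag(w) + lambda * t(D) %*% D, w * y)
}

# AUC as explicit pairwise probability over all pos x neg pairs
pairCountAuc <- function(scores, positive) {
  p <- scores[positive]
  q <- scores[!positive]
  wins <- 0
  for (a in p) for (b in q)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(p) * length(q))
}

# textbook product-moment correlation
textbookPearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# exhaustive scan for the in-window maximum
scanBandMax <- function(z, wn, lo, hi) {
  best <- -Inf
  for (i in seq_along(z))
    if (wn[i] >= lo && wn[i] <= hi && z[i] > best) best <- z[i]
  best
}

# piecewise-linear interpolation from the definition
linInterp <- function(x, y, x0) {
  i <- findInterval(x0, x, all.inside = TRUE)
  y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
}

writeSpectrumFile <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
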