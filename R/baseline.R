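#' AirPLS configuration constructor
#'
#' Defaults follow the algorithm's originating publication: lambda = 100,
#' at most 15 iterations, termination when the negative-residual mass drops
#' below 0.1% of the total absolute signal, second-order difference penalty,
#' exponential endpoint weighting.
#'
#' @param lambda smoothness penalty (> 0); larger values give stiffer
#'   baselines
#' @param maxIter iteration cap
#' @param tolRatio termination threshold relative to sum(|y|)
#' @param diffOrder difference-penalty order (1 or 2)
#' @param endpointWeights "exp" or "zero", see [AirplsConfig-class]
#' @return an [AirplsConfig-class].
#' @export
airplsConfig <- function(lambda = 100, maxIter = 15L, tolRatio = 0.001,
                         diffOrder = 2L,
                         endpointWeights = c("exp", "zero")) {
  new("AirplsConfig", lambda = as.numeric(lambda),
      maxIter = as.integer(maxIter), tolRatio = as.numeric(tolRatio),
      diffOrder = as.integer(diffOrder),
      endpointWeights = match.arg(endpointWeights))
}

# k-th order difference matrix D ((n-k) x n) as a sparse band matrix;
# rows hold the alternating binomial coefficients of the k-th forward
# difference.
.diffMatrix <- function(n, k) {
  coefs <- choose(k, 0:k) * (-1)^(0:k)
  Matrix::bandSparse(n - k, n, k = 0:k,
                     diagonals = lapply(coefs, rep, n - k))
}

#' Whittaker smoother
#'
#' Solves the penalized weighted least-squares problem
#' minimize sum_i w_i (y_i - z_i)^2 + lambda * sum_j (D^k z)_j^2,
#' i.e. the linear system (W + lambda D'D) z = W y, with D the k-th order
#' finite-difference matrix on the (uniform) grid. The system is banded
#' (5 diagonals for k = 2) and solved sparsely, keeping 1,024-point spectra
#' interactive.
#'
#' @param y intensity vector
#' @param w non-negative weights, same length as `y`, at least one positive
#' @param lambda smoothness penalty (> 0)
#' @param diffOrder difference order k (1 or 2)
#' @return the smoothed vector z.
#' @examples
#' y <- sin(seq(0, 4, length.out = 64)) + rnorm(64, sd = 0.1)
#' z <- whittakerSmooth(y, rep(1, 64), lambda = 10)
#' @export
whittakerSmooth <- function(y, w, lambda, diffOrder = 2L) {
  n <- length(y)
  if (length(w) != n) stop("y and w differ in length")
  if (n < diffOrder + 1L)
    stop("need at least diffOrder + 1 points")
  if (any(!is.finite(y)) || any(!is.finite(w)))
    stop("non-finite input")
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("all weights zero: system is degenerate")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  D <- .diffMatrix(n, as.integer(diffOrder))
  .whittakerSolve(y, w, lambda * Matrix::crossprod(D))
}

# solve (diag(w) + P) z = w y for a precomputed penalty P = lambda D'D;
# the penalty is constant across AirPLS iterations, only the weights move
.whittakerSolve <- function(y, w, P) {
  A <- Matrix::Diagonal(length(y), x = w) + P
  as.numeric(Matrix::solve(A, w * y, sparse = TRUE))
}

#' AirPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares. Starting from
#' unit weights, each iteration fits a Whittaker-smoothed baseline z, forms
#' the residual d = y - z, and measures the negative-residual mass
#' s = sum(|d[d < 0]|). Points at or above the baseline (peaks) get weight
#' 0; points below get weight exp(t |d_i| / s), which grows with the
#' iteration counter t so the fit progressively hugs the signal-free lower
#' envelope. The two endpoints get exp(t max|d-| / s) (configurable) to
#' prevent droop at the spectrum edges. Iteration stops when
#' s < tolRatio * sum(|y|) or at the iteration cap.
#'
#' @param y intensity vector (a spectrum's intensities)
#' @param config an [AirplsConfig-class]
#' @param keepWeights store each iteration's weight vector in the result
#'   (for diagnostics/testing)
#' @return a [BaselineFit-class]; `corrected(fit)` is `y - baseline(fit)`,
#'   not clipped at zero.
#' @examples
#' wn <- gridPoints(wavenumberGrid())
#' drift <- 2 + 5 * exp(-wn / 800)
#' peak <- 3 / (1 + ((wn - 1000) / 6)^2)
#' fit <- airplsBaseline(drift + peak, airplsConfig(lambda = 100))
#' max(abs(corrected(fit) - peak)) / 3  # small
#' @export
airplsBaseline <- function(y, config = airplsConfig(), keepWeights = FALSE) {
  stopifnot(is(config, "AirplsConfig"))
  n <- length(y)
  if (any(!is.finite(y))) stop("non-finite input")
  if (n < config@diffOrder + 1L) stop("spectrum too short")
  totalAbs <- sum(abs(y))
  D <- .diffMatrix(n, config@diffOrder)
  P <- config@lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  s <- NA_real_
  converged <- FALSE
  history <- if (keepWeights) vector("list", config@maxIter) else list()
  t <- 0L
  for (t in seq_len(config@maxIter)) {
    if (keepWeights) history[[t]] <- w
    z <- .whittakerSolve(y, w, P)
    d <- y - z
    neg <- d < 0
    s <- sum(abs(d[neg]))
    if (s < config@tolRatio * totalAbs || s == 0) {
      converged <- TRUE
      break
    }
    if (t == config@maxIter) break
    w <- numeric(n)                    # d >= 0: signal, weight 0
    w[neg] <- exp(t * abs(d[neg]) / s)
    if (config@endpointWeights == "exp") {
      wEnd <- if (any(neg)) exp(t * max(abs(d[neg])) / s) else 1
      w[1L] <- wEnd
      w[n] <- wEnd
    }
  }
  if (keepWeights) history <- history[seq_len(t)]
  new("BaselineFit", baseline = z, corrected = y - z, nIter = t,
      converged = converged, residualNegativeMass = s,
      weightHistory = history)
}
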