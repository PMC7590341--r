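#' Default benzoic-acid marker bands
#'
#' The published reading intervals: monomer naphthenic 944-1,005 cm^-1 and
#' carboxylic 1,366-1,373 cm^-1; dimer naphthenic 1,025 cm^-1 (widened to a
#' symmetric window of one instrument resolution unit) and carboxylic
#' 1,465-1,482 cm^-1.
#'
#' @param dimerNaphHalfWindow half-width (cm^-1) applied to the single
#'   1,025 cm^-1 dimer ring position; default 8, the system resolution.
#'   A single grid channel would be brittle under the documented
#'   peak-shift effect.
#' @return a [BandSet-class].
#' @export
bandSet <- function(dimerNaphHalfWindow = 8) {
  new("BandSet",
      monomerNaphthenic = c(944, 1005),
      monomerCarboxylic = c(1366, 1373),
      dimerNaphthenic = c(1025 - dimerNaphHalfWindow,
                          1025 + dimerNaphHalfWindow),
      dimerCarboxylic = c(1465, 1482))
}

#' Standardize a corrected spectrum to Z-scores
#'
#' Each intensity is centred and scaled by the mean and standard deviation
#' of the same spectrum's own points, so every channel becomes a standard
#' score relative to that sample's intensity distribution.
#'
#' @param x baseline-corrected intensities (length >= 2, non-constant)
#' @param sdType "sample" (n-1 denominator, default) or "population"; at
#'   1,024 channels the two differ by < 0.05%, below the precision the
#'   scores are reported at
#' @return numeric vector with mean 0 and sd 1 (under the chosen
#'   convention), order-preserving.
#' @export
standardize <- function(x, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  n <- length(x)
  if (n < 2L) stop("need at least 2 points")
  if (any(!is.finite(x))) stop("non-finite input")
  m <- mean(x)
  s <- sd(x)
  if (sdType == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0)
    stop("degenerate spectrum: zero intensity variance")
  (x - m) / s
}

#' Maximum Z-score inside a band interval
#'
#' The band statistic is the maximum (not mean or integral) of the
#' standardized intensities at grid points falling in the closed interval:
#' peak maxima are tolerant to the documented peak-position drift within
#' the window.
#'
#' @param z standard-score vector on the grid
#' @param wavenumbers matching wavenumber vector (cm^-1)
#' @param interval closed interval c(lower, upper) in cm^-1
#' @return list with `score` (the in-window maximum) and `wavenumber`
#'   (its location, for diagnostics).
#' @export
bandScore <- function(z, wavenumbers, interval) {
  if (length(z) != length(wavenumbers))
    stop("z and wavenumbers differ in length")
  if (length(interval) != 2L || interval[1L] > interval[2L])
    stop("interval must be c(lower, upper)")
  inBand <- wavenumbers >= interval[1L] & wavenumbers <= interval[2L]
  if (!any(inBand))
    stop(sprintf("no grid points inside band [%g, %g] cm^-1",
                 interval[1L], interval[2L]))
  idx <- which(inBand)[which.max(z[inBand])]
  list(score = z[idx], wavenumber = wavenumbers[idx])
}

#' Z-ratio of a species' two marker bands
#'
#' Ratio of the naphthenic (ring) band Z-score to the carboxylic band
#' Z-score. A species whose bands both stay below the detection floor is
#' treated as undetected and scores 0 (the screening table records such
#' samples as 0.00); a detected species whose carboxylic score sits within
#' the division guard of zero is likewise reported as 0 rather than an
#' unbounded ratio. Negative ratios are passed through unmodified.
#'
#' @param zNaph naphthenic-band Z-score
#' @param zCarb carboxylic-band Z-score
#' @param detectFloor detection floor on max(zNaph, zCarb); default 1
#'   standard score
#' @param guard |zCarb| below this yields 0 instead of dividing
#' @return unitless ratio.
#' @export
zRatio <- function(zNaph, zCarb, detectFloor = 1, guard = 1e-6) {
  if (!is.finite(zNaph) || !is.finite(zCarb)) stop("non-finite Z-scores")
  if (detectFloor < 0) stop("detectFloor must be >= 0")
  if (max(zNaph, zCarb) < detectFloor) return(0)
  if (abs(zCarb) < guard) return(0)
  zNaph / zCarb
}

#' Rule thresholds for screening decisions
#'
#' @param fluctuation summed Z-ratio at or above which BA is called present
#'   (default 1.5)
#' @param rule5 summed Z-ratio defining a high-risk sample referred to
#'   confirmatory HPLC (default 5)
#' @param inclusive apply the Rule-5 cut as `sum >= rule5` (default) or
#'   strictly `sum > rule5`
#' @param detectFloor detection floor passed to [zRatio()]
#' @return plain list of thresholds used by [scoreSample()].
#' @export
ruleConfig <- function(fluctuation = 1.5, rule5 = 5, inclusive = TRUE,
                       detectFloor = 1) {
  list(fluctuation = fluctuation, rule5 = rule5, inclusive = inclusive,
       detectFloor = detectFloor)
}

#' Score one spectrum end to end
#'
#' Runs the full per-sample chain: resample onto the standard grid (if not
#' already on it), AirPLS baseline correction, per-spectrum Z-score
#' standardisation, band maxima in the four marker windows, monomer and
#' dimer Z-ratios, their sum, and the two screening flags.
#'
#' @param s a [Spectrum-class]
#' @param config an [AirplsConfig-class]
#' @param bands a [BandSet-class]
#' @param rules a list from [ruleConfig()]
#' @param grid the standard [WavenumberGrid-class]
#' @param sdType sd convention for [standardize()]
#' @return a [SampleScore-class].
#' @export
scoreSample <- function(s, config = airplsConfig(), bands = bandSet(),
                        rules = ruleConfig(), grid = wavenumberGrid(),
                        sdType = "sample") {
  stopifnot(is(s, "Spectrum"), is(bands, "BandSet"))
  if (!isOnGrid(s, grid)) s <- resampleToGrid(s, grid)
  fit <- airplsBaseline(s@intensities, config)
  z <- standardize(fit@corrected, sdType = sdType)
  wn <- s@wavenumbers
  bNM <- bandScore(z, wn, bands@monomerNaphthenic)
  bCM <- bandScore(z, wn, bands@monomerCarboxylic)
  bND <- bandScore(z, wn, bands@dimerNaphthenic)
  bCD <- bandScore(z, wn, bands@dimerCarboxylic)
  rM <- zRatio(bNM$score, bCM$score, detectFloor = rules$detectFloor)
  rD <- zRatio(bND$score, bCD$score, detectFloor = rules$detectFloor)
  sumScore <- rM + rD
  high <- if (rules$inclusive) sumScore >= rules$rule5
          else sumScore > rules$rule5
  new("SampleScore", sampleId = s@sampleId,
      zScores = c(naphMonomer = bNM$score, carbMonomer = bCM$score,
                  naphDimer = bND$score, carbDimer = bCD$score),
      peakWavenumbers = c(naphMonomer = bNM$wavenumber,
                          carbMonomer = bCM$wavenumber,
                          naphDimer = bND$wavenumber,
                          carbDimer = bCD$wavenumber),
      ratioMonomer = rM, ratioDimer = rD, sumScore = sumScore,
      fluctuationSignificant = sumScore >= rules$fluctuation,
      rule5HighRisk = high)
}

#' Construct a labeled cohort
#'
#' @param sampleId sample identifiers
#' @param sumScore summed Z-ratio screening scores
#' @param hplcPpm reference HPLC concentrations (ppm)
#' @param regulatoryLimit positive-class cutoff (ppm); samples strictly
#'   above it are the positives
#' @return a [LabeledCohort-class].
#' @export
labeledCohort <- function(sampleId, sumScore, hplcPpm,
                          regulatoryLimit = 600) {
  new("LabeledCohort", sampleId = as.character(sampleId),
      sumScore = as.numeric(sumScore), hplcPpm = as.numeric(hplcPpm),
      regulatoryLimit = as.numeric(regulatoryLimit))
}

#' Score a list of spectra into a labeled cohort
#'
#' @param spectra list of [Spectrum-class] objects
#' @param hplcPpm reference concentrations, one per spectrum
#' @param regulatoryLimit positive-class cutoff (ppm)
#' @param ... passed to [scoreSample()]
#' @return list with `cohort` (a [LabeledCohort-class]) and `scores`
#'   (list of [SampleScore-class]).
#' @export
scoreCohort <- function(spectra, hplcPpm, regulatoryLimit = 600, ...) {
  stopifnot(length(spectra) == length(hplcPpm))
  scores <- lapply(spectra, scoreSample, ...)
  cohort <- labeledCohort(
    vapply(scores, sampleId, character(1L)),
    vapply(scores, sumScore, numeric(1L)),
    hplcPpm, regulatoryLimit = regulatoryLimit)
  list(cohort = cohort, scores = scores)
}
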