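#' @import methods
#' @importFrom stats approx sd cor quantile lm coef residuals rnorm rbeta rlnorm runif
#'   setNames var
#' @importFrom utils read.table write.table packageVersion
NULL

#' Wavenumber grid of a Raman acquisition
#'
#' Describes the instrument's fixed, evenly spaced Raman-shift axis. The
#' default matches the handheld acquisition geometry used throughout the
#' package: 1,024 channels spanning 204 to 1,986 cm^-1.
#'
#' @slot start first grid point (cm^-1)
#' @slot stop last grid point (cm^-1)
#' @slot nPoints number of channels
#'
#' @seealso [wavenumberGrid()], [gridPoints()]
#' @exportClass WavenumberGrid
setClass("WavenumberGrid",
  representation(start = "numeric", stop = "numeric", nPoints = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@start) != 1L || length(object@stop) != 1L ||
        length(object@nPoints) != 1L)
      msg <- c(msg, "start, stop and nPoints must be scalars")
    else {
      if (!is.finite(object@start) || !is.finite(object@stop))
        msg <- c(msg, "grid limits must be finite")
      if (object@start >= object@stop)
        msg <- c(msg, "start must be < stop")
      if (object@nPoints < 2L)
        msg <- c(msg, "nPoints must be >= 2")
    }
    if (length(msg)) msg else TRUE
  })

#' A single Raman/SERS spectrum
#'
#' One sample's wavenumber and intensity arrays. Wavenumbers are strictly
#' increasing and finite; intensities may be negative (baseline-corrected
#' spectra routinely go below zero and are accepted as-is).
#'
#' @slot sampleId sample identifier
#' @slot wavenumbers Raman shift axis (cm^-1), strictly increasing
#' @slot intensities intensities (arbitrary units), same length
#' @slot metadata free-form key/value list
#'
#' @seealso [readSpectrum()], [resampleToGrid()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(sampleId = "character", wavenumbers = "numeric",
                 intensities = "numeric", metadata = "list"),
  prototype(sampleId = NA_character_, metadata = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@wavenumbers) != length(object@intensities))
      msg <- c(msg, "wavenumbers and intensities differ in length")
    if (length(object@wavenumbers) < 2L)
      msg <- c(msg, "a spectrum needs at least 2 points")
    if (anyNA(object@wavenumbers) || any(!is.finite(object@wavenumbers)))
      msg <- c(msg, "non-finite wavenumbers")
    if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
      msg <- c(msg, "non-finite intensities")
    if (length(object@wavenumbers) >= 2L &&
        all(is.finite(object@wavenumbers)) &&
        any(diff(object@wavenumbers) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Marker-band intervals for benzoic acid scoring
#'
#' The four wavenumber windows read out of each corrected spectrum: the
#' naphthenic (ring) and carboxylic-group bands of the BA monomer and of the
#' hydrogen-bonded BA dimer. Defaults are the published reading intervals;
#' the dimer ring band is tabulated as the single position 1,025 cm^-1 and
#' is widened to a symmetric window of one instrument resolution unit
#' (+/- 8 cm^-1) so the documented peak-shift effect cannot move it off a
#' single channel.
#'
#' @slot monomerNaphthenic closed interval (cm^-1), default 944-1005
#' @slot monomerCarboxylic closed interval (cm^-1), default 1366-1373
#' @slot dimerNaphthenic closed interval (cm^-1), default 1025 +/- 8
#' @slot dimerCarboxylic closed interval (cm^-1), default 1465-1482
#'
#' @seealso [bandSet()], [bandScore()]
#' @exportClass BandSet
setClass("BandSet",
  representation(monomerNaphthenic = "numeric", monomerCarboxylic = "numeric",
                 dimerNaphthenic = "numeric", dimerCarboxylic = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in c("monomerNaphthenic", "monomerCarboxylic",
                 "dimerNaphthenic", "dimerCarboxylic")) {
      iv <- slot(object, nm)
      if (length(iv) != 2L || anyNA(iv) || any(!is.finite(iv)))
        msg <- c(msg, sprintf("%s must be a finite interval of length 2", nm))
      else if (iv[1L] > iv[2L])
        msg <- c(msg, sprintf("%s lower bound exceeds upper bound", nm))
    }
    if (length(msg)) msg else TRUE
  })

#' AirPLS configuration
#'
#' Controls for the adaptive iteratively reweighted penalized least-squares
#' baseline estimator: the Whittaker smoothness penalty lambda, the
#' difference-penalty order, the iteration cap, the termination threshold
#' (relative to the total absolute signal), and the endpoint weighting rule.
#'
#' @slot lambda smoothness penalty (> 0)
#' @slot maxIter iteration cap (>= 1)
#' @slot tolRatio termination threshold as a fraction of sum(|y|), in (0, 1)
#' @slot diffOrder finite-difference order of the penalty, 1 or 2
#' @slot endpointWeights "exp" (default: endpoints get exp(t * max|d-|/s),
#'   preventing baseline droop at the spectrum edges) or "zero"
#'
#' @seealso [airplsConfig()], [airplsBaseline()]
#' @exportClass AirplsConfig
setClass("AirplsConfig",
  representation(lambda = "numeric", maxIter = "integer",
                 tolRatio = "numeric", diffOrder = "integer",
                 endpointWeights = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
        object@lambda <= 0)
      msg <- c(msg, "lambda must be a positive scalar")
    if (length(object@maxIter) != 1L || object@maxIter < 1L)
      msg <- c(msg, "maxIter must be >= 1")
    if (length(object@tolRatio) != 1L || !is.finite(object@tolRatio) ||
        object@tolRatio <= 0 || object@tolRatio >= 1)
      msg <- c(msg, "tolRatio must lie in (0, 1)")
    if (length(object@diffOrder) != 1L || !object@diffOrder %in% c(1L, 2L))
      msg <- c(msg, "diffOrder must be 1 or 2")
    if (length(object@endpointWeights) != 1L ||
        !object@endpointWeights %in% c("exp", "zero"))
      msg <- c(msg, "endpointWeights must be 'exp' or 'zero'")
    if (length(msg)) msg else TRUE
  })

#' Result of an AirPLS baseline fit
#'
#' @slot baseline fitted baseline (a.u.)
#' @slot corrected input minus baseline (a.u.)
#' @slot nIter iterations performed
#' @slot converged TRUE iff the negative-residual mass fell below tolerance
#'   before the iteration cap
#' @slot residualNegativeMass final sum of |negative residuals| (a.u.), the
#'   quantity driving the adaptive reweighting
#' @slot weightHistory list of the weight vector used at each iteration
#'   (empty unless requested)
#'
#' @seealso [airplsBaseline()]
#' @exportClass BaselineFit
setClass("BaselineFit",
  representation(baseline = "numeric", corrected = "numeric",
                 nIter = "integer", converged = "logical",
                 residualNegativeMass = "numeric", weightHistory = "list"),
  prototype(weightHistory = list()),
  validity = function(object) {
    if (length(object@baseline) != length(object@corrected))
      "baseline and corrected differ in length" else TRUE
  })

#' Per-sample screening scores
#'
#' Z-scores at the four marker bands, the monomer and dimer Z-ratios
#' (ring band divided by carboxylic band), their sum, and the two screening
#' decisions: significant fluctuation (BA detected, sum >= 1.5 by default)
#' and Rule-5 high risk (referred to confirmatory HPLC, sum >= 5 by
#' default).
#'
#' @slot sampleId sample identifier
#' @slot zScores named standard scores at the four bands
#'   (naphMonomer, carbMonomer, naphDimer, carbDimer)
#' @slot peakWavenumbers named argmax wavenumbers of the four band maxima
#'   (diagnostics)
#' @slot ratioMonomer monomer Z-ratio (unitless)
#' @slot ratioDimer dimer Z-ratio (unitless)
#' @slot sumScore ratioMonomer + ratioDimer
#' @slot fluctuationSignificant BA-detected flag
#' @slot rule5HighRisk confirmatory-HPLC referral flag
#'
#' @seealso [scoreSample()]
#' @exportClass SampleScore
setClass("SampleScore",
  representation(sampleId = "character", zScores = "numeric",
                 peakWavenumbers = "numeric",
                 ratioMonomer = "numeric", ratioDimer = "numeric",
                 sumScore = "numeric", fluctuationSignificant = "logical",
                 rule5HighRisk = "logical"),
  validity = function(object) {
    msg <- character()
    if (abs(object@sumScore - (object@ratioMonomer + object@ratioDimer)) >
        1e-9)
      msg <- c(msg, "sumScore must equal ratioMonomer + ratioDimer")
    if (length(msg)) msg else TRUE
  })

#' A scored cohort with reference HPLC labels
#'
#' Sample identifiers, summed Z-ratio screening scores, and reference HPLC
#' concentrations (ppm), together with the regulatory limit that defines
#' the positive class (concentration strictly above the limit).
#'
#' @slot sampleId sample identifiers
#' @slot sumScore summed Z-ratios (unitless)
#' @slot hplcPpm reference HPLC concentrations (ppm, >= 0)
#' @slot regulatoryLimit positive-class cutoff (ppm), default 600
#'
#' @seealso [labeledCohort()], [loadTable2()], [empiricalRoc()]
#' @exportClass LabeledCohort
setClass("LabeledCohort",
  representation(sampleId = "character", sumScore = "numeric",
                 hplcPpm = "numeric", regulatoryLimit = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@sampleId)
    if (n < 1L) msg <- c(msg, "cohort must be non-empty")
    if (length(object@sumScore) != n || length(object@hplcPpm) != n)
      msg <- c(msg, "sampleId, sumScore and hplcPpm differ in length")
    if (anyNA(object@hplcPpm) || any(object@hplcPpm < 0))
      msg <- c(msg, "hplcPpm must be >= 0")
    if (anyNA(object@sumScore) || any(!is.finite(object@sumScore)))
      msg <- c(msg, "sumScore must be finite")
    if (length(object@regulatoryLimit) != 1L ||
        !is.finite(object@regulatoryLimit) || object@regulatoryLimit < 0)
      msg <- c(msg, "regulatoryLimit must be a non-negative scalar")
    if (length(msg)) msg else TRUE
  })

#' Empirical ROC analysis result
#'
#' Operating points (one per candidate threshold, with the flag taken as
#' score >= threshold, plus the flag-everything and flag-nothing limits),
#' the Mann-Whitney pair-count AUC (ties count one half), and the optimal
#' screening threshold: the one reaching sensitivity 1.0 with maximal
#' specificity.
#'
#' @slot points data.frame with columns threshold, sensitivity, specificity
#' @slot auc area under the curve, in [0, 1]
#' @slot optimalThreshold selected screening threshold
#' @slot nPos,nNeg class counts
#'
#' @seealso [empiricalRoc()]
#' @exportClass RocResult
setClass("RocResult",
  representation(points = "data.frame", auc = "numeric",
                 optimalThreshold = "numeric", nPos = "integer",
                 nNeg = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(c("threshold", "sensitivity", "specificity") %in%
             names(object@points)))
      msg <- c(msg, "points needs threshold/sensitivity/specificity columns")
    if (length(object@auc) != 1L || is.na(object@auc) ||
        object@auc < 0 || object@auc > 1)
      msg <- c(msg, "auc must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Bootstrap triage-risk simulation result
#'
#' @slot nIter number of bootstrap iterations
#' @slot seed RNG seed used
#' @slot fnRateMean mean false-negative rate among true positives
#' @slot fpTriageMean mean flag (triage) fraction among sub-limit samples
#' @slot fnRateQuantiles,fpTriageQuantiles named 2.5/50/97.5% quantiles
#'
#' @seealso [monteCarloTriage()]
#' @exportClass MonteCarloResult
setClass("MonteCarloResult",
  representation(nIter = "integer", seed = "integer",
                 fnRateMean = "numeric", fpTriageMean = "numeric",
                 fnRateQuantiles = "numeric", fpTriageQuantiles = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in c("fnRateMean", "fpTriageMean")) {
      v <- slot(object, nm)
      if (!is.na(v) && (v < 0 || v > 1))
        msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
    }
    if (length(msg)) msg else TRUE
  })

#' Synthetic SERS spectrum generator configuration
#'
#' Parameters of the generative model: Lorentzian BA marker peaks inside
#' the four reading windows with truncated position jitter, a
#' concentration-dependent monomer/dimer amplitude split, a smooth
#' fluorescence-like baseline, random matrix interference peaks, and
#' additive Gaussian noise.
#'
#' @slot grid the wavenumber grid spectra are generated on
#' @slot peakWidthGamma Lorentzian half-width at half-maximum (cm^-1)
#' @slot monomerGain,dimerGain peak amplitude per ppm (a.u./ppm) at full
#'   surface coverage
#' @slot hillK,hillH half-saturation concentration (ppm) and cooperativity
#'   exponent of the adsorption response scaling the effective amplitude
#' @slot dimerOnsetPpm concentration below which no dimer signal appears
#' @slot bindingAlpha,bindingBeta Beta-distribution shape parameters of the
#'   per-sample monomer binding fraction phi
#' @slot carbRelAmplitude carboxylic-band amplitude relative to the
#'   naphthenic band of the same species (sets the saturated Z-ratio scale)
#' @slot baselineCoeffs named (b0, b1, b2, theta) of
#'   b(v) = b0 + b1 v + b2 exp(-v / theta)
#' @slot nInterferencePeaks number of random matrix peaks
#' @slot interferenceAmplitude maximal interference peak amplitude (a.u.)
#' @slot noiseSd additive Gaussian noise sd (a.u.)
#' @slot shiftSd peak-position jitter sd (cm^-1), truncated to the window
#'
#' @seealso [syntheticConfig()], [simulateSpectrum()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(grid = "WavenumberGrid", peakWidthGamma = "numeric",
                 monomerGain = "numeric", dimerGain = "numeric",
                 hillK = "numeric", hillH = "numeric",
                 dimerOnsetPpm = "numeric", bindingAlpha = "numeric",
                 bindingBeta = "numeric", carbRelAmplitude = "numeric",
                 baselineCoeffs = "numeric",
                 nInterferencePeaks = "integer",
                 interferenceAmplitude = "numeric",
                 noiseSd = "numeric", shiftSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@peakWidthGamma <= 0)
      msg <- c(msg, "peakWidthGamma must be > 0")
    if (object@monomerGain < 0 || object@dimerGain < 0)
      msg <- c(msg, "gains must be >= 0")
    if (object@hillK <= 0 || object@hillH <= 0)
      msg <- c(msg, "hillK and hillH must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@shiftSd < 0) msg <- c(msg, "shiftSd must be >= 0")
    if (!all(c("b0", "b1", "b2", "theta") %in% names(object@baselineCoeffs)))
      msg <- c(msg, "baselineCoeffs needs named b0, b1, b2, theta")
    if (object@nInterferencePeaks < 0L)
      msg <- c(msg, "nInterferencePeaks must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Calibration line with detection limits
#'
#' Ordinary least-squares fit of the summed Z-ratio on concentration within
#' a stated linear range, plus limit of detection and quantification by the
#' 3.3 sigma/slope and 10 sigma/slope blank-based conventions.
#'
#' @slot slope score per ppm
#' @slot intercept score at 0 ppm
#' @slot rSquared coefficient of determination
#' @slot lodPpm limit of detection, 3.3 sd(blanks)/slope
#' @slot loqPpm limit of quantification, 10 sd(blanks)/slope
#' @slot rangePpm the fitted linear range
#'
#' @seealso [fitCalibration()]
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", lodPpm = "numeric",
                 loqPpm = "numeric", rangePpm = "numeric"),
  validity = function(object) {
    if (!is.na(object@lodPpm) && !is.na(object@loqPpm) &&
        object@loqPpm < object@lodPpm - 1e-12)
      "loqPpm must be >= lodPpm" else TRUE
  })
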