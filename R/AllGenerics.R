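#' Accessors for SERSscreen objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a SERSscreen S4 object
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("baseline", function(object) standardGeneric("baseline"))
#' @rdname accessors
#' @export
setGeneric("corrected", function(object) standardGeneric("corrected"))
#' @rdname accessors
#' @export
setGeneric("sumScore", function(object) standardGeneric("sumScore"))
#' @rdname accessors
#' @export
setGeneric("zRatios", function(object) standardGeneric("zRatios"))
#' @rdname accessors
#' @export
setGeneric("isHighRisk", function(object) standardGeneric("isHighRisk"))
#' @rdname accessors
#' @export
setGeneric("hplcPpm", function(object) standardGeneric("hplcPpm"))
#' @rdname accessors
#' @export
setGeneric("regulatoryLimit",
           function(object) standardGeneric("regulatoryLimit"))
#' @rdname accessors
#' @export
setGeneric("positiveLabels",
           function(object) standardGeneric("positiveLabels"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("optimalThreshold",
           function(object) standardGeneric("optimalThreshold"))

setMethod("sampleId", "Spectrum", function(object) object@sampleId)
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumbers)
setMethod("intensities", "Spectrum", function(object) object@intensities)

setMethod("baseline", "BaselineFit", function(object) object@baseline)
setMethod("corrected", "BaselineFit", function(object) object@corrected)

setMethod("sampleId", "SampleScore", function(object) object@sampleId)
setMethod("sumScore", "SampleScore", function(object) object@sumScore)
setMethod("zRatios", "SampleScore", function(object)
  c(monomer = object@ratioMonomer, dimer = object@ratioDimer))
setMethod("isHighRisk", "SampleScore", function(object) object@rule5HighRisk)

setMethod("sampleId", "LabeledCohort", function(object) object@sampleId)
setMethod("sumScore", "LabeledCohort", function(object) object@sumScore)
setMethod("hplcPpm", "LabeledCohort", function(object) object@hplcPpm)
setMethod("regulatoryLimit", "LabeledCohort",
          function(object) object@regulatoryLimit)
setMethod("positiveLabels", "LabeledCohort",
          function(object) object@hplcPpm > object@regulatoryLimit)

setMethod("auc", "RocResult", function(object) object@auc)
setMethod("rocPoints", "RocResult", function(object) object@points)
setMethod("optimalThreshold", "RocResult",
          function(object) object@optimalThreshold)

#' @describeIn accessors number of points in a Spectrum
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavenumbers))

#' @describeIn accessors number of samples in a LabeledCohort
#' @export
setMethod("length", "LabeledCohort", function(x) length(x@sampleId))

#' Coerce a LabeledCohort to a data.frame
#'
#' @param x a [LabeledCohort-class]
#' @param row.names,optional,... passed through (unused)
#' @return data.frame with sample_id, sum_score, hplc_ppm and the derived
#'   logical positive column (hplc_ppm > regulatory limit).
#' @export
as.data.frame.LabeledCohort <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(sample_id = x@sampleId, sum_score = x@sumScore,
             hplc_ppm = x@hplcPpm,
             positive = x@hplcPpm > x@regulatoryLimit,
             stringsAsFactors = FALSE)
}

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum", sQuote(object@sampleId), "\n")
  cat(sprintf("  %d points, %.1f-%.1f cm^-1, intensity range [%.4g, %.4g]\n",
              length(object@wavenumbers), min(object@wavenumbers),
              max(object@wavenumbers), min(object@intensities),
              max(object@intensities)))
})

setMethod("show", "BaselineFit", function(object) {
  cat(sprintf(
    "AirPLS BaselineFit: %d points, %d iteration(s), %s (residual |d-| mass %.4g)\n",
    length(object@baseline), object@nIter,
    if (object@converged) "converged" else "iteration cap reached",
    object@residualNegativeMass))
})

setMethod("show", "SampleScore", function(object) {
  cat("SampleScore", sQuote(object@sampleId), "\n")
  cat(sprintf("  Z-ratio monomer %.3f, dimer %.3f, sum %.3f\n",
              object@ratioMonomer, object@ratioDimer, object@sumScore))
  cat(sprintf("  BA detected: %s; Rule-5 high risk: %s\n",
              object@fluctuationSignificant, object@rule5HighRisk))
})

setMethod("show", "LabeledCohort", function(object) {
  pos <- sum(object@hplcPpm > object@regulatoryLimit)
  cat(sprintf(
    "LabeledCohort: %d samples (%d above the %g ppm limit), scores [%.3g, %.3g]\n",
    length(object@sampleId), pos, object@regulatoryLimit,
    min(object@sumScore), max(object@sumScore)))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "RocResult: %d+/%d- samples, AUC %.4f, optimal threshold %.4g\n",
    object@nPos, object@nNeg, object@auc, object@optimalThreshold))
})

setMethod("show", "MonteCarloResult", function(object) {
  cat(sprintf(
    "MonteCarloResult (%d iterations, seed %d)\n", object@nIter, object@seed))
  cat(sprintf("  false-negative rate mean %.4f; sub-limit triage mean %.4f\n",
              object@fnRateMean, object@fpTriageMean))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit (%g-%g ppm): slope %.4g/ppm, intercept %.4g, R^2 %.4f\n",
    object@rangePpm[1L], object@rangePpm[2L], object@slope, object@intercept,
    object@rSquared))
  cat(sprintf("  LOD %.3g ppm, LOQ %.3g ppm\n", object@lodPpm, object@loqPpm))
})
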