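#' Synthetic SERS generator configuration
#'
#' Defaults emulate the acquisition and signal structure the scoring method
#' was designed for: the 1,024-channel 204-1,986 cm^-1 grid; Lorentzian
#' marker peaks of half-width 6 cm^-1 (just under the 8 cm^-1 system
#' resolution) centred in the four reading windows with truncated position
#' jitter; a per-sample monomer/dimer amplitude split phi ~ Beta(0.5, 0.5)
#' (U-shaped, so most samples present predominantly one species, as seen in
#' screening practice); a cooperative adsorption response
#' Hill(c) = (c/K)^h / (1 + (c/K)^h) scaling the effective amplitude --
#' SERS intensity tracks nanoparticle surface coverage, not bulk
#' concentration, which is what makes the reference cohort's dose-response
#' so steep (quiet at 130 ppm yet fully developed at 380 ppm); no dimer
#' signal below 350 ppm (the lowest concentration at which dimer bands are
#' observed in the reference cohort is 380 ppm); a smooth
#' fluorescence-like baseline
#' b(v) = b0 + b1 v + b2 exp(-v/theta); a few random matrix interference
#' peaks; and additive Gaussian noise.
#'
#' @param grid [WavenumberGrid-class] to generate on
#' @param peakWidthGamma Lorentzian half-width at half-maximum (cm^-1)
#' @param monomerGain,dimerGain naphthenic-band amplitude per ppm
#'   (a.u./ppm) at full surface coverage
#' @param hillK,hillH adsorption half-saturation concentration (ppm) and
#'   cooperativity exponent
#' @param dimerOnsetPpm concentration below which no dimer bands appear
#' @param bindingAlpha,bindingBeta Beta shapes of the monomer fraction phi
#' @param carbRelAmplitude carboxylic-band amplitude as a fraction of the
#'   same species' naphthenic band; its reciprocal sets the saturated
#'   Z-ratio scale
#' @param baselineCoeffs named c(b0, b1, b2, theta)
#' @param nInterferencePeaks number of random matrix peaks per spectrum
#' @param interferenceAmplitude maximal matrix peak amplitude (a.u.)
#' @param noiseSd additive Gaussian noise sd (a.u.)
#' @param shiftSd peak-position jitter sd (cm^-1), truncated so centres stay
#'   inside their reading windows
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(grid = wavenumberGrid(),
                            peakWidthGamma = 6,
                            monomerGain = 2e-3, dimerGain = 2e-3,
                            hillK = 400, hillH = 3,
                            dimerOnsetPpm = 350,
                            bindingAlpha = 0.5, bindingBeta = 0.5,
                            carbRelAmplitude = 0.2,
                            baselineCoeffs = c(b0 = 0.5, b1 = 2e-4,
                                               b2 = 5, theta = 600),
                            nInterferencePeaks = 12L,
                            interferenceAmplitude = 0.5,
                            noiseSd = 0.008, shiftSd = 2) {
  new("SyntheticConfig", grid = grid, peakWidthGamma = peakWidthGamma,
      monomerGain = monomerGain, dimerGain = dimerGain,
      hillK = hillK, hillH = hillH,
      dimerOnsetPpm = dimerOnsetPpm, bindingAlpha = bindingAlpha,
      bindingBeta = bindingBeta, carbRelAmplitude = carbRelAmplitude,
      baselineCoeffs = baselineCoeffs,
      nInterferencePeaks = as.integer(nInterferencePeaks),
      interferenceAmplitude = interferenceAmplitude,
      noiseSd = noiseSd, shiftSd = shiftSd)
}

# unit-apex Lorentzian
.lorentzian <- function(v, center, gamma) {
  gamma^2 / ((v - center)^2 + gamma^2)
}

# normal draw truncated to [lo, hi] by rejection (falls back to the
# clamped mean; only reachable for pathological shiftSd)
.truncNorm <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:100) {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Synthetic baseline function
#'
#' @param v wavenumbers (cm^-1)
#' @param coeffs named c(b0, b1, b2, theta)
#' @return b0 + b1 v + b2 exp(-v/theta), the generator's fluorescence-like
#'   drift.
#' @export
syntheticBaseline <- function(v, coeffs) {
  coeffs[["b0"]] + coeffs[["b1"]] * v +
    coeffs[["b2"]] * exp(-v / coeffs[["theta"]])
}

#' Simulate one SERS spectrum with known ground truth
#'
#' Intensity = baseline + sum of Lorentzian peaks + Gaussian noise. The
#' monomer contributes ring and carboxylic peaks inside 944-1,005 and
#' 1,366-1,373 cm^-1 with naphthenic amplitude monomerGain * conc * phi;
#' the dimer contributes peaks inside the 1,025-window and 1,465-1,482
#' cm^-1 with amplitude dimerGain * conc * (1 - phi) * ramp, where the
#' ramp is 0 below the dimer onset and rises linearly to 1 at the top of
#' the screening range (820 ppm) -- dimerisation becomes progressively
#' easier to observe as concentration grows. Each carboxylic peak is
#' carbRelAmplitude times its species' naphthenic peak. Peak centres are
#' jittered with a truncated normal so they never leave their reading
#' windows.
#'
#' @param concPpm benzoic-acid concentration (ppm, >= 0)
#' @param cfg a [SyntheticConfig-class]
#' @param seed RNG seed
#' @param phi optional fixed monomer binding fraction in [0, 1]; drawn from
#'   Beta(bindingAlpha, bindingBeta) when `NULL`
#' @param bands the [BandSet-class] whose windows constrain peak centres
#' @return list with `spectrum` (a [Spectrum-class]) and `truth`: the
#'   noiseless baseline vector, a peak table (species, band, center,
#'   amplitude, gamma), phi, and the concentration.
#' @export
simulateSpectrum <- function(concPpm, cfg = syntheticConfig(), seed = 1L,
                             phi = NULL, bands = bandSet()) {
  stopifnot(concPpm >= 0, is(cfg, "SyntheticConfig"))
  set.seed(seed)
  v <- gridPoints(cfg@grid)
  if (is.null(phi)) phi <- rbeta(1L, cfg@bindingAlpha, cfg@bindingBeta)
  # surface-coverage response: amplitudes follow the adsorbed fraction,
  # giving the steep detection onset the reference cohort shows
  hill <- if (concPpm > 0)
    (concPpm / cfg@hillK)^cfg@hillH /
      (1 + (concPpm / cfg@hillK)^cfg@hillH) else 0
  aMono <- cfg@monomerGain * concPpm * hill * phi
  # dimerisation grows with concentration: zero below the onset, then a
  # linear ramp reaching full strength at the top of the screening range
  ramp <- if (concPpm < cfg@dimerOnsetPpm) 0 else
    min(1, (concPpm - cfg@dimerOnsetPpm) / (820 - cfg@dimerOnsetPpm))
  aDim <- cfg@dimerGain * concPpm * hill * (1 - phi) * ramp
  windows <- list(
    list(species = "monomer", band = "naphthenic",
         win = bands@monomerNaphthenic, amp = aMono),
    list(species = "monomer", band = "carboxylic",
         win = bands@monomerCarboxylic, amp = aMono * cfg@carbRelAmplitude),
    list(species = "dimer", band = "naphthenic",
         win = bands@dimerNaphthenic, amp = aDim),
    list(species = "dimer", band = "carboxylic",
         win = bands@dimerCarboxylic, amp = aDim * cfg@carbRelAmplitude))
  peaks <- do.call(rbind, lapply(windows, function(p) {
    center <- .truncNorm(mean(p$win), cfg@shiftSd, p$win[1L], p$win[2L])
    data.frame(species = p$species, band = p$band, center = center,
               amplitude = p$amp, gamma = cfg@peakWidthGamma,
               stringsAsFactors = FALSE)
  }))
  if (cfg@nInterferencePeaks > 0L) {
    # matrix bands land outside the four reading windows: the windows were
    # picked because the matrix is quiet there, and the reference cohort
    # shows no dimer signal at all below the onset concentration
    margin <- 4 * cfg@peakWidthGamma  # keep Lorentzian tails out too
    inWindow <- function(x) {
      near <- function(win) x >= win[1L] - margin & x <= win[2L] + margin
      near(bands@monomerNaphthenic) | near(bands@monomerCarboxylic) |
        near(bands@dimerNaphthenic) | near(bands@dimerCarboxylic)
    }
    ic <- numeric(0)
    while (length(ic) < cfg@nInterferencePeaks) {
      cand <- runif(cfg@nInterferencePeaks, cfg@grid@start, cfg@grid@stop)
      ic <- c(ic, cand[!inWindow(cand)])
    }
    ic <- ic[seq_len(cfg@nInterferencePeaks)]
    ia <- runif(cfg@nInterferencePeaks, 0, cfg@interferenceAmplitude)
    peaks <- rbind(peaks, data.frame(
      species = "matrix", band = "interference", center = ic,
      amplitude = ia, gamma = cfg@peakWidthGamma, stringsAsFactors = FALSE))
  }
  base <- syntheticBaseline(v, cfg@baselineCoeffs)
  signal <- base
  for (i in seq_len(nrow(peaks)))
    signal <- signal + peaks$amplitude[i] *
      .lorentzian(v, peaks$center[i], peaks$gamma[i])
  noise <- if (cfg@noiseSd > 0) rnorm(length(v), 0, cfg@noiseSd) else 0
  s <- spectrum(v, signal + noise,
                sampleId = sprintf("synth_%gppm_seed%d", concPpm, seed),
                metadata = list(concPpm = concPpm, seed = seed))
  list(spectrum = s,
       truth = list(baseline = base, peaks = peaks, phi = phi,
                    concPpm = concPpm, noiseSd = cfg@noiseSd))
}

#' Simulate a labeled screening cohort
#'
#' Concentrations are drawn from a mixture of a point mass at 0 ppm (the
#' BA-free samples that dominate retail cohorts) and a log-normal for
#' contaminated samples; the default mixture (57.5% zero, log-normal
#' meanlog log(400), sdlog 0.8) mimics the reference cohort's 23/40 zero
#' rows and 0-820 ppm range. Each spectrum is generated with its own seed
#' derived from `seed` and scored through the full pipeline; the true
#' concentrations become the cohort's reference labels.
#'
#' @param n cohort size
#' @param mixture list(zeroWeight, meanlog, sdlog)
#' @param cfg a [SyntheticConfig-class]
#' @param seed master RNG seed
#' @param regulatoryLimit positive-class cutoff (ppm)
#' @param ... passed to [scoreSample()]
#' @return list with `cohort` (a [LabeledCohort-class] whose hplc_ppm are
#'   the true concentrations), `spectra`, `scores`, and `truth` (per-sample
#'   generator records).
#' @export
simulateCohort <- function(n, mixture = list(zeroWeight = 0.575,
                                             meanlog = log(400),
                                             sdlog = 0.8),
                           cfg = syntheticConfig(), seed = 1L,
                           regulatoryLimit = 600, ...) {
  stopifnot(n >= 1L)
  if (is.null(mixture$zeroWeight) || mixture$zeroWeight < 0 ||
      mixture$zeroWeight > 1)
    stop("mixture$zeroWeight must lie in [0, 1]")
  set.seed(seed)
  isZero <- runif(n) < mixture$zeroWeight
  conc <- ifelse(isZero, 0, rlnorm(n, mixture$meanlog, mixture$sdlog))
  # per-sample sub-seeds, kept within 32-bit integer range
  subSeeds <- sample.int(.Machine$integer.max - n, n) + seq_len(n) - 1L
  sims <- lapply(seq_len(n), function(i)
    simulateSpectrum(conc[i], cfg, seed = subSeeds[i]))
  spectra <- lapply(sims, `[[`, "spectrum")
  for (i in seq_len(n)) spectra[[i]]@sampleId <- sprintf("synth_%03d", i)
  sc <- scoreCohort(spectra, hplcPpm = conc,
                    regulatoryLimit = regulatoryLimit, ...)
  list(cohort = sc$cohort, spectra = spectra, scores = sc$scores,
       truth = lapply(sims, `[[`, "truth"))
}

#' Fit a calibration line with blank-based detection limits
#'
#' Ordinary least squares of the summed Z-ratio on concentration over the
#' stated linear range, with limits of detection and quantification from
#' the blank-score scatter by the usual conventions:
#' LOD = 3.3 sd(blanks)/slope, LOQ = 10 sd(blanks)/slope.
#'
#' @param cohort a [LabeledCohort-class]
#' @param rangePpm inclusive linear range, default c(380, 820)
#' @param blankScores summed Z-ratios of blank (0 ppm) samples, >= 3 values
#' @return a [CalibrationFit-class].
#' @export
fitCalibration <- function(cohort, rangePpm = c(380, 820), blankScores) {
  stopifnot(is(cohort, "LabeledCohort"), length(rangePpm) == 2L)
  inRange <- cohort@hplcPpm >= rangePpm[1L] & cohort@hplcPpm <= rangePpm[2L]
  if (sum(inRange) < 3L)
    stop("need at least 3 cohort entries inside the calibration range")
  if (length(blankScores) < 3L) stop("need at least 3 blank scores")
  fit <- lm(score ~ ppm, data = data.frame(
    score = cohort@sumScore[inRange], ppm = cohort@hplcPpm[inRange]))
  slope <- unname(coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) stop("degenerate fit: zero slope")
  sdBlank <- sd(blankScores)
  sc <- cohort@sumScore[inRange]
  rsq <- 1 - sum(residuals(fit)^2) / sum((sc - mean(sc))^2)
  new("CalibrationFit", slope = slope,
      intercept = unname(coef(fit)[1L]),
      rSquared = rsq,
      lodPpm = 3.3 * sdBlank / slope, loqPpm = 10 * sdBlank / slope,
      rangePpm = as.numeric(rangePpm))
}
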