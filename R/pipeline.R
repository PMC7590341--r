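#' Read a key = value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments.
#' Recognised keys (all optional, shown with defaults): lambda = 100,
#' max_iter = 15, tol_ratio = 0.001, diff_order = 2, detect_floor = 1,
#' fluctuation = 1.5, rule5 = 5, inclusive = TRUE, limit = 600,
#' mc_iters = 10000, seed = 1, dimer_half_window = 8, plus band overrides
#' monomer_naph / monomer_carb / dimer_naph / dimer_carb as
#' "lower:upper".
#'
#' @param path config file, or `NULL` for all defaults
#' @return named list of settings merged over the defaults.
#' @export
readConfig <- function(path = NULL) {
  cfg <- list(lambda = 100, max_iter = 15L, tol_ratio = 0.001,
              diff_order = 2L, detect_floor = 1, fluctuation = 1.5,
              rule5 = 5, inclusive = TRUE, limit = 600,
              mc_iters = 10000L, seed = 1L, dimer_half_window = 8)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
                  else if (toupper(val) %in% c("TRUE", "FALSE"))
                    as.logical(toupper(val))
                  else val
  }
  cfg
}

.bandsFromConfig <- function(cfg) {
  bands <- bandSet(dimerNaphHalfWindow = cfg$dimer_half_window)
  parseIv <- function(s) as.numeric(strsplit(s, ":", fixed = TRUE)[[1L]])
  if (!is.null(cfg$monomer_naph))
    bands@monomerNaphthenic <- parseIv(cfg$monomer_naph)
  if (!is.null(cfg$monomer_carb))
    bands@monomerCarboxylic <- parseIv(cfg$monomer_carb)
  if (!is.null(cfg$dimer_naph))
    bands@dimerNaphthenic <- parseIv(cfg$dimer_naph)
  if (!is.null(cfg$dimer_carb))
    bands@dimerCarboxylic <- parseIv(cfg$dimer_carb)
  validObject(bands)
  bands
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full screening pipeline on a cohort table
#'
#' The cohort table is a CSV with a `sample_id` column, a reference
#' `hplc_ppm` column, and either a `spectrum_path` column (spectra mode:
#' each file is read, regridded, baseline-corrected and scored) or
#' precomputed `z_ratio_monomer`/`z_ratio_dimer` columns (score-table
#' mode). Writes `scores.csv`, `evaluation.json` and `run_log.txt` into the
#' output directory; outputs carry no timestamps, so identical inputs,
#' configuration and seed give byte-identical files. On a stage failure the
#' partially written outputs are removed and the error names the stage.
#'
#' @param input path to the cohort CSV
#' @param outputDir directory for the three outputs (created if needed)
#' @param configFile optional key = value config file, see [readConfig()]
#' @param seed RNG seed for the bootstrap stage (overrides the config)
#' @return invisibly, a list with the cohort, scores data.frame, ROC
#'   result, confusion, Pearson r and bootstrap summary.
#' @export
runPipeline <- function(input, outputDir, configFile = NULL, seed = NULL) {
  cfg <- .stage("config", readConfig(configFile))
  if (!is.null(seed)) cfg$seed <- seed
  if (!file.exists(input)) stop("pipeline input not found: ", input)
  tbl <- .stage("input", {
    x <- read.table(input, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
    if (!all(c("sample_id", "hplc_ppm") %in% names(x)))
      stop("cohort table needs sample_id and hplc_ppm columns")
    if (nrow(x) < 1L) stop("empty cohort table: ", input)
    x
  })
  rules <- ruleConfig(fluctuation = cfg$fluctuation, rule5 = cfg$rule5,
                      inclusive = isTRUE(cfg$inclusive),
                      detectFloor = cfg$detect_floor)
  if ("spectrum_path" %in% names(tbl)) {
    scoresTbl <- .stage("scoring", {
      air <- airplsConfig(lambda = cfg$lambda, maxIter = cfg$max_iter,
                          tolRatio = cfg$tol_ratio,
                          diffOrder = cfg$diff_order)
      bands <- .bandsFromConfig(cfg)
      paths <- ifelse(file.exists(tbl$spectrum_path), tbl$spectrum_path,
                      file.path(dirname(input), tbl$spectrum_path))
      sc <- lapply(seq_len(nrow(tbl)), function(i) {
        s <- readSpectrum(paths[i], sampleId = tbl$sample_id[i])
        scoreSample(s, config = air, bands = bands, rules = rules)
      })
      data.frame(sample_id = tbl$sample_id,
                 z_ratio_monomer = vapply(sc, slot, numeric(1L),
                                          "ratioMonomer"),
                 z_ratio_dimer = vapply(sc, slot, numeric(1L),
                                        "ratioDimer"),
                 sum_z_ratio = vapply(sc, sumScore, numeric(1L)),
                 hplc_ppm = tbl$hplc_ppm, stringsAsFactors = FALSE)
    })
  } else {
    scoresTbl <- .stage("scoring", {
      if (!all(c("z_ratio_monomer", "z_ratio_dimer") %in% names(tbl)))
        stop("cohort table needs spectrum_path or z_ratio_* columns")
      data.frame(sample_id = tbl$sample_id,
                 z_ratio_monomer = tbl$z_ratio_monomer,
                 z_ratio_dimer = tbl$z_ratio_dimer,
                 sum_z_ratio = tbl$z_ratio_monomer + tbl$z_ratio_dimer,
                 hplc_ppm = tbl$hplc_ppm, stringsAsFactors = FALSE)
    })
  }
  scoresTbl$significant_fluctuation <-
    scoresTbl$sum_z_ratio >= cfg$fluctuation
  scoresTbl$rule5_high_risk <- if (isTRUE(cfg$inclusive))
    scoresTbl$sum_z_ratio >= cfg$rule5 else scoresTbl$sum_z_ratio > cfg$rule5

  cohort <- .stage("cohort", labeledCohort(
    scoresTbl$sample_id, scoresTbl$sum_z_ratio, scoresTbl$hplc_ppm,
    regulatoryLimit = cfg$limit))
  roc <- .stage("roc", empiricalRoc(cohort))
  conf <- .stage("confusion", confusionAtThreshold(
    cohort, cfg$rule5, inclusive = isTRUE(cfg$inclusive)))
  r <- .stage("pearson", pearsonCorrelation(cohort))
  mc <- .stage("monte-carlo", monteCarloTriage(
    cohort, threshold = cfg$rule5, nIter = cfg$mc_iters,
    seed = cfg$seed, inclusive = isTRUE(cfg$inclusive)))

  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  outScores <- file.path(outputDir, "scores.csv")
  outJson <- file.path(outputDir, "evaluation.json")
  outLog <- file.path(outputDir, "run_log.txt")
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  .stage("write", {
    write.table(scoresTbl, outScores, sep = ",", row.names = FALSE,
                quote = FALSE)
    written <- c(written, outScores)
    report <- list(
      n_samples = length(cohort),
      regulatory_limit_ppm = cfg$limit,
      rule5_threshold = cfg$rule5,
      inclusive = isTRUE(cfg$inclusive),
      auc = auc(roc),
      optimal_threshold = optimalThreshold(roc),
      roc_points = rocPoints(roc),
      confusion = conf,
      pearson_r = r,
      monte_carlo = list(
        n_iter = mc@nIter, seed = mc@seed,
        fn_rate_mean = mc@fnRateMean,
        fp_triage_mean = mc@fpTriageMean,
        fn_rate_quantiles = as.list(mc@fnRateQuantiles),
        fp_triage_quantiles = as.list(mc@fpTriageQuantiles)))
    jsonlite::write_json(report, outJson, auto_unbox = TRUE, digits = NA,
                         na = "null")
    written <- c(written, outJson)
    writeLines(c(
      paste0("SERSscreen ", as.character(packageVersion("SERSscreen"))),
      paste0("input: ", basename(input)),
      paste0("mode: ", if ("spectrum_path" %in% names(tbl)) "spectra"
             else "score-table"),
      paste0("seed: ", cfg$seed),
      "effective config:",
      paste0("  ", names(cfg), " = ",
             vapply(cfg, function(x) paste(format(x), collapse = ":"),
                    character(1L)))),
      outLog)
    written <- c(written, outLog)
  })
  ok <- TRUE
  invisible(list(cohort = cohort, scores = scoresTbl, roc = roc,
                 confusion = conf, pearson = r, monteCarlo = mc,
                 config = cfg,
                 files = c(scores = outScores, evaluation = outJson,
                           log = outLog)))
}
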