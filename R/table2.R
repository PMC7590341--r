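# md5 of the shipped cohort fixture; guards against silent corruption of
# the screening reference data
.TABLE2_MD5 <- "e2abc5a4b774d63e8744f1fe88c58efc"

#' The bundled 40-sample screening cohort as a data frame
#'
#' The published reference cohort of 40 pickled-vegetable samples: monomer
#' Z-ratio (column A), dimer Z-ratio (column B), their sum, and the
#' reference HPLC benzoic-acid concentration in ppm. Stored as checksummed
#' delimited text inside the package; the checksum is verified on every
#' load.
#'
#' @param checkChecksum verify the fixture's md5 before parsing
#' @return data.frame with columns no, z_ratio_monomer, z_ratio_dimer,
#'   sum_z_ratio, hplc_ppm (40 rows).
#' @export
table2Data <- function(checkChecksum = TRUE) {
  path <- system.file("extdata", "table2_ba_cohort.tsv",
                      package = "SERSscreen", mustWork = TRUE)
  if (checkChecksum) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, .TABLE2_MD5))
      stop("cohort fixture is corrupted: md5 ", got,
           " does not match expected ", .TABLE2_MD5)
  }
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (nrow(df) != 40L) stop("cohort fixture must have exactly 40 rows")
  df
}

#' Load the bundled screening cohort
#'
#' @param regulatoryLimit positive-class cutoff in ppm (default 600, the
#'   regulatory standard the screen is evaluated against)
#' @param checkChecksum verify the fixture's md5
#' @return a [LabeledCohort-class] with the summed Z-ratio as score and the
#'   HPLC concentration as reference label.
#' @examples
#' cohort <- loadTable2()
#' pearsonCorrelation(cohort)
#' @export
loadTable2 <- function(regulatoryLimit = 600, checkChecksum = TRUE) {
  df <- table2Data(checkChecksum = checkChecksum)
  labeledCohort(sampleId = as.character(df$no),
                sumScore = df$sum_z_ratio,
                hplcPpm = df$hplc_ppm,
                regulatoryLimit = regulatoryLimit)
}
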