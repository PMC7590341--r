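#' Construct a wavenumber grid
#'
#' @param start,stop grid limits (cm^-1)
#' @param nPoints number of evenly spaced channels
#' @return a [WavenumberGrid-class]. The default is the instrument axis used
#'   throughout: 1,024 channels from 204 to 1,986 cm^-1.
#' @examples
#' g <- wavenumberGrid()
#' head(gridPoints(g))
#' @export
wavenumberGrid <- function(start = 204, stop = 1986, nPoints = 1024L) {
  new("WavenumberGrid", start = as.numeric(start), stop = as.numeric(stop),
      nPoints = as.integer(nPoints))
}

#' Evaluate the points of a wavenumber grid
#'
#' @param grid a [WavenumberGrid-class]
#' @return numeric vector of the grid's wavenumbers, strictly increasing and
#'   evenly spaced.
#' @export
gridPoints <- function(grid) {
  stopifnot(is(grid, "WavenumberGrid"))
  seq(grid@start, grid@stop, length.out = grid@nPoints)
}

#' Construct a Spectrum
#'
#' @param wavenumbers Raman shifts (cm^-1); sorted ascending if needed
#' @param intensities matching intensities (a.u.)
#' @param sampleId sample identifier
#' @param metadata free-form key/value list
#' @return a validated [Spectrum-class], sorted by ascending wavenumber.
#'   Duplicate wavenumbers are rejected.
#' @export
spectrum <- function(wavenumbers, intensities, sampleId = NA_character_,
                     metadata = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities differ in length")
  o <- order(wavenumbers)
  wavenumbers <- wavenumbers[o]
  intensities <- intensities[o]
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers: ",
         paste(unique(wavenumbers[duplicated(wavenumbers)]), collapse = ", "))
  new("Spectrum", sampleId = as.character(sampleId),
      wavenumbers = wavenumbers, intensities = intensities,
      metadata = metadata)
}

# pick the delimiter that actually yields >= 2 numeric fields on a data
# line; a lone header line must not decide for the whole file
.detectDelimiter <- function(lines) {
  probe <- utils::head(lines, 5L)
  for (d in c(",", "\t", ";", "")) {
    for (ln in probe) {
      f <- if (d == "") strsplit(trimws(ln), "\\s+")[[1L]]
           else trimws(strsplit(ln, d, fixed = TRUE)[[1L]])
      if (length(f) >= 2L &&
          !anyNA(suppressWarnings(as.numeric(f[1:2])))) return(d)
    }
  }
  ""  # fall back to whitespace
}

#' Read a two-column delimited spectrum file
#'
#' Reads wavenumber/intensity text as exported by field Raman instruments.
#' Lines starting with `#` are comments; a single leading non-numeric header
#' line is tolerated. The delimiter is auto-detected among comma, tab,
#' semicolon and whitespace unless given.
#'
#' @param path file path
#' @param delimiter single delimiter character, or `NULL` to auto-detect
#'   (`""` means any whitespace)
#' @param sampleId identifier for the resulting spectrum; defaults to the
#'   file name without extension
#' @return a [Spectrum-class] sorted by ascending wavenumber.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("# demo", "1000,5.0", "1001,6.0"), f)
#' readSpectrum(f)
#' @export
readSpectrum <- function(path, delimiter = NULL, sampleId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineNo <- which(keep)
  if (!length(lines)) stop("no data rows in ", path)
  if (is.null(delimiter)) delimiter <- .detectDelimiter(lines)
  splitOne <- function(s) {
    if (delimiter == "") strsplit(trimws(s), "\\s+")[[1L]]
    else trimws(strsplit(s, delimiter, fixed = TRUE)[[1L]])
  }
  fields <- lapply(lines, splitOne)
  asNum <- function(f) suppressWarnings(as.numeric(f[1:2]))
  vals <- lapply(fields, asNum)
  bad <- vapply(seq_along(vals), function(i)
    length(fields[[i]]) < 2L || anyNA(vals[[i]]), logical(1L))
  # tolerate one header line at the top
  if (bad[1L] && length(bad) > 1L) {
    vals <- vals[-1L]; bad <- bad[-1L]; lineNo <- lineNo[-1L]
  }
  if (any(bad))
    stop("unparseable spectrum row at line ", lineNo[which(bad)[1L]],
         " of ", path)
  wn <- vapply(vals, `[`, numeric(1L), 1L)
  it <- vapply(vals, `[`, numeric(1L), 2L)
  if (length(wn) < 2L) stop("spectrum has fewer than 2 points: ", path)
  if (any(!is.finite(wn)) || any(!is.finite(it)))
    stop("non-finite values in ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  spectrum(wn, it, sampleId = sampleId, metadata = list(source = path))
}

#' Write a spectrum to two-column delimited text
#'
#' @param s a [Spectrum-class]
#' @param path output file
#' @param delimiter column separator
#' @return `path`, invisibly. Full double precision is written so a
#'   read/write round trip reproduces the numeric content.
#' @export
writeSpectrum <- function(s, path, delimiter = ",") {
  stopifnot(is(s, "Spectrum"))
  writeLines(c(paste0("# spectrum ", s@sampleId),
               paste(format(s@wavenumbers, digits = 17, trim = TRUE),
                     format(s@intensities, digits = 17, trim = TRUE),
                     sep = delimiter)),
             path)
  invisible(path)
}

#' Resample a spectrum onto a fixed wavenumber grid
#'
#' Linear interpolation onto the grid points, so that field spectra acquired
#' on slightly different axes can be scored on the standard 1,024-channel
#' instrument grid. Values at input knots are preserved where a knot
#' coincides with a grid point.
#'
#' @param s a [Spectrum-class]
#' @param grid target [WavenumberGrid-class]
#' @param edgeHold if `TRUE`, grid points outside the spectrum's support
#'   take the nearest edge value; if `FALSE` (default) insufficient coverage
#'   is an error
#' @return a [Spectrum-class] on exactly the grid's points.
#' @export
resampleToGrid <- function(s, grid, edgeHold = FALSE) {
  stopifnot(is(s, "Spectrum"), is(grid, "WavenumberGrid"))
  x <- gridPoints(grid)
  lo <- min(s@wavenumbers); hi <- max(s@wavenumbers)
  if (!edgeHold && (grid@start < lo - 1e-9 || grid@stop > hi + 1e-9))
    stop(sprintf(
      "spectrum support [%g, %g] does not cover grid [%g, %g]; set edgeHold = TRUE to hold edge values",
      lo, hi, grid@start, grid@stop))
  y <- approx(s@wavenumbers, s@intensities, xout = x, method = "linear",
              rule = 2)$y
  spectrum(x, y, sampleId = s@sampleId, metadata = s@metadata)
}

#' Is a spectrum already on a given grid?
#'
#' @param s a [Spectrum-class]
#' @param grid a [WavenumberGrid-class]
#' @param tol wavenumber tolerance (cm^-1)
#' @return logical scalar.
#' @export
isOnGrid <- function(s, grid, tol = 1e-6) {
  length(s@wavenumbers) == grid@nPoints &&
    max(abs(s@wavenumbers - gridPoints(grid))) <= tol
}
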