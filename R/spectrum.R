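#' Spectrum curve: wavenumber/intensity table
#'
#' @param wavenumber strictly increasing wavenumbers, cm^-1 (sorted if given
#'   out of order; ties are an error)
#' @param intensity intensities, arbitrary absorbance units
#' @param label optional label (e.g. a temperature)
#' @return object of class `spectrum_curve`
#' @export
spectrum_curve <- function(wavenumber, intensity, label = NULL) {
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length")
  if (!all(is.finite(wavenumber)) || !all(is.finite(intensity)))
    stop("non-finite values in spectrum")
  o <- order(wavenumber)
  wavenumber <- wavenumber[o]; intensity <- intensity[o]
  if (any(diff(wavenumber) <= 0)) stop("duplicate wavenumbers in spectrum")
  structure(list(wavenumber = wavenumber, intensity = intensity, label = label),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("spectrum_curve%s: %d points, %.6g..%.6g cm^-1\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Read a two-column wavenumber/intensity CSV
#'
#' Header row optional. Rows are sorted by wavenumber; duplicate wavenumbers
#' and non-numeric cells are format errors.
#'
#' @param path CSV file path
#' @param label optional label attached to the curve
#' @return a [spectrum_curve()]
#' @export
read_spectrum <- function(path, label = NULL) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[-0-9.eE+[:space:]]+,", first)
  df <- utils::read.csv(path, header = has_header,
                        colClasses = c("character", "character"))
  if (ncol(df) < 2) stop("spectrum CSV must have two columns")
  wn <- suppressWarnings(as.numeric(df[[1]]))
  it <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(wn) || anyNA(it)) stop("non-numeric cell in spectrum CSV")
  spectrum_curve(wn, it, label = label)
}

#' Write a spectrum curve as CSV
#' @param spectrum a [spectrum_curve()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_curve"))
  utils::write.csv(
    data.frame(`wavenumber_cm.1` = spectrum$wavenumber,
               intensity = spectrum$intensity),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linearly resample a spectrum onto a new wavenumber grid
#' @param spectrum a [spectrum_curve()]
#' @param grid target wavenumbers, cm^-1 (must lie inside the spectrum range)
#' @return a [spectrum_curve()] on `grid`
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "spectrum_curve"))
  if (min(grid) < min(spectrum$wavenumber) - 1e-9 ||
      max(grid) > max(spectrum$wavenumber) + 1e-9)
    stop("target grid extends beyond the spectrum range")
  y <- stats::approx(spectrum$wavenumber, spectrum$intensity, xout = grid)$y
  spectrum_curve(grid, y, label = spectrum$label)
}
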