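#' Wavelength grid
#'
#' A strictly increasing vector of wavelengths in nanometres, shared by all
#' spectra of a measurement. Construction validates monotonicity and
#' positivity; duplicated wavelengths are rejected.
#'
#' @param values numeric vector of wavelengths (nm).
#' @return numeric vector with class `otos_grid`.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    otos_abort("wavelength grid must be non-empty and free of NA", "otos_grid_error")
  }
  if (any(values <= 0)) {
    otos_abort("wavelengths must be positive (nm)", "otos_grid_error")
  }
  if (anyDuplicated(values)) {
    otos_abort("duplicate wavelengths in grid", "otos_duplicate_wavelength_error")
  }
  if (is.unsorted(values, strictly = TRUE)) {
    otos_abort("wavelength grid must be strictly increasing", "otos_grid_error")
  }
  structure(values, class = "otos_grid")
}

#' Intensity spectrum
#'
#' Raw or processed detector counts on a wavelength grid. `role` records the
#' measurement the spectrum came from: the sample reflection (`sample_RR`),
#' the dark reading with an empty port (`dark_R0`), the reference-standard
#' reading (`reference_R1`), or `other`.
#'
#' @param grid wavelengths (nm), coerced with [wavelength_grid()].
#' @param counts non-negative detector counts, same length as `grid`.
#' @param role one of `"sample_RR"`, `"dark_R0"`, `"reference_R1"`, `"other"`.
#' @return object of class `otos_spectrum`.
#' @export
intensity_spectrum <- function(grid, counts, role = "other") {
  grid <- wavelength_grid(grid)
  counts <- as.numeric(counts)
  role <- match.arg(role, c("sample_RR", "dark_R0", "reference_R1", "other"))
  if (length(counts) != length(grid)) {
    otos_abort("counts length must equal grid length", "otos_spectrum_error")
  }
  if (anyNA(counts) || any(counts < 0)) {
    otos_abort("counts must be non-negative and free of NA", "otos_spectrum_error")
  }
  structure(list(grid = grid, counts = counts, role = role),
            class = "otos_spectrum")
}

#' @export
print.otos_spectrum <- function(x, ...) {
  cat(sprintf("<otos_spectrum role=%s, %d points, %.1f-%.1f nm>\n",
              x$role, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Read a two-column spectrum file
#'
#' Parses plain-text spectra with one `wavelength<delim>counts` pair per
#' line; the delimiter may be a comma and/or whitespace. Lines starting with
#' `#` are comments. Rows are sorted by wavelength; duplicated wavelengths
#' are an error.
#'
#' @param path file path.
#' @param role spectrum role, see [intensity_spectrum()].
#' @return an `otos_spectrum`.
#' @export
read_spectrum <- function(path, role = "other") {
  if (!file.exists(path)) {
    otos_abort(sprintf("spectrum file not found: %s", path), "otos_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    otos_abort(sprintf("no data rows in %s", path), "otos_parse_error")
  }
  parts <- strsplit(trimws(lines[idx]), "[,\\s]+")
  bad_len <- vapply(parts, length, 1L) != 2L
  if (any(bad_len)) {
    otos_abort(sprintf("malformed row at line %d of %s (expected 2 columns)",
                       idx[which(bad_len)[1L]], path), "otos_parse_error")
  }
  mat <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE))
  bad_num <- rowSums(is.na(mat)) > 0L
  if (any(bad_num)) {
    otos_abort(sprintf("non-numeric value at line %d of %s",
                       idx[which(bad_num)[1L]], path), "otos_parse_error")
  }
  ord <- order(mat[, 1L])
  if (anyDuplicated(mat[, 1L])) {
    otos_abort(sprintf("duplicate wavelengths in %s", path),
               "otos_duplicate_wavelength_error")
  }
  intensity_spectrum(mat[ord, 1L], mat[ord, 2L], role = role)
}

#' Write a spectrum to a two-column text file
#'
#' Emits comma-delimited `wavelength_nm,counts` rows with a `# role:` header
#' line, the format accepted by [read_spectrum()].
#'
#' @param spectrum an `otos_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "otos_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# role: %s", spectrum$role),
               "# columns: wavelength_nm,counts"), con)
  writeLines(sprintf("%.6g,%.10g", as.numeric(spectrum$grid), spectrum$counts), con)
  invisible(path)
}

#' Average repeated acquisitions
#'
#' Pointwise arithmetic mean of spectra taken on identical grids with
#' identical roles, emulating the averaging of several spectrometer readings
#' per measurement.
#'
#' @param spectra list of `otos_spectrum` objects.
#' @return an `otos_spectrum` on the common grid.
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    otos_abort("need at least one spectrum", "otos_spectrum_error")
  }
  stopifnot(all(vapply(spectra, inherits, TRUE, "otos_spectrum")))
  g <- as.numeric(spectra[[1L]]$grid)
  role <- spectra[[1L]]$role
  for (s in spectra[-1L]) {
    if (length(s$grid) != length(g) || any(as.numeric(s$grid) != g)) {
      otos_abort("spectra are not on identical wavelength grids",
                 "otos_grid_mismatch_error")
    }
    if (s$role != role) {
      otos_abort("spectra to average must share a role", "otos_spectrum_error")
    }
  }
  counts <- rowMeans(vapply(spectra, `[[`, numeric(length(g)), "counts"))
  intensity_spectrum(g, counts, role = role)
}

#' Boxcar (moving-average) smoothing
#'
#' Moving average over a window of `2 * half_width + 1` pixels. The vendor
#' convention for the spectrometer "boxcar width" setting is a half-width,
#' so the acquisition setting of 50 corresponds to a 101-pixel window. At
#' the spectrum ends the window shrinks (truncated window) rather than
#' extending beyond the grid.
#'
#' @param spectrum an `otos_spectrum`.
#' @param half_width non-negative integer half-width in pixels; default 50,
#'   the acquisition setting used with a ~0.25 nm/pixel spectrometer.
#' @return smoothed `otos_spectrum` on the same grid.
#' @export
boxcar_smooth <- function(spectrum, half_width = 50L) {
  stopifnot(inherits(spectrum, "otos_spectrum"))
  hw <- as.integer(half_width)
  n <- length(spectrum$counts)
  if (is.na(hw) || hw < 0L) {
    otos_abort("half_width must be a non-negative integer", "otos_smooth_error")
  }
  if (2L * hw + 1L > n) {
    otos_abort("boxcar window exceeds spectrum length", "otos_smooth_error")
  }
  if (hw == 0L) return(spectrum)
  cs <- cumsum(c(0, spectrum$counts))
  i <- seq_len(n)
  lo <- pmax(i - hw, 1L)
  hi <- pmin(i + hw, n)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  intensity_spectrum(as.numeric(spectrum$grid), smoothed, role = spectrum$role)
}
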