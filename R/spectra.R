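#' Construct an emission spectrum
#'
#' Container for a single fluorescence emission scan recorded at a fixed
#' excitation wavelength, temperature and ligand concentration. The scan at
#' zero ligand concentration serves as the reference (\eqn{F_0}) of a
#' titration.
#'
#' @param wavelengths Numeric vector of emission wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of fluorescence intensities (a.u.),
#'   non-negative, same length as `wavelengths`.
#' @param excitation_wavelength Excitation wavelength in nm.
#' @param temperature Temperature in K (> 0). See [celsius_to_kelvin()].
#' @param ligand_concentration Ligand concentration in mol/L (>= 0).
#'
#' @return An object of class `emission_spectrum`.
#' @export
#' @examples
#' sp <- emission_spectrum(300:500, rep(100, 201), 295, 298.15, 0)
#' intensity_at(sp, 340)
emission_spectrum <- function(wavelengths, intensities, excitation_wavelength,
                              temperature, ligand_concentration) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L || length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length >= 2")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive (K)")
  if (!is.finite(ligand_concentration) || ligand_concentration < 0)
    stop("ligand_concentration must be non-negative (mol/L)")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         excitation_wavelength = as.numeric(excitation_wavelength),
         temperature = as.numeric(temperature),
         ligand_concentration = as.numeric(ligand_concentration)),
    class = "emission_spectrum")
}

#' Convert degrees Celsius to Kelvin
#'
#' @param celsius Temperature in degrees C.
#' @return Temperature in K (`celsius + 273.15`).
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' Assemble a titration series
#'
#' Collects emission spectra of one protein titrated with increasing ligand
#' concentrations at a shared temperature and excitation wavelength. Exactly
#' one spectrum must be the ligand-free reference; spectra are stored sorted
#' by ascending concentration.
#'
#' @param spectra List of [emission_spectrum()] objects sharing wavelength
#'   grid, excitation wavelength and temperature; concentrations must be
#'   unique and include exactly one zero.
#'
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra) {
  if (!length(spectra) || !all(vapply(spectra, inherits, TRUE, "emission_spectrum")))
    stop("spectra must be a non-empty list of emission_spectrum objects")
  conc <- vapply(spectra, function(s) s$ligand_concentration, 0)
  if (anyDuplicated(conc)) stop("duplicate ligand concentrations in titration")
  if (sum(conc == 0) != 1L) stop("no reference spectrum: exactly one spectrum must have zero ligand concentration")
  ord <- order(conc)
  spectra <- spectra[ord]
  ref <- spectra[[1L]]
  for (s in spectra[-1L]) {
    if (!isTRUE(all.equal(s$wavelengths, ref$wavelengths)))
      stop("all spectra must share the same wavelength grid")
    if (s$excitation_wavelength != ref$excitation_wavelength)
      stop("all spectra must share the excitation wavelength")
    if (s$temperature != ref$temperature)
      stop("all spectra must share the temperature")
  }
  structure(list(spectra = spectra,
                 excitation_wavelength = ref$excitation_wavelength,
                 temperature = ref$temperature),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  conc <- concentrations(x)
  cat(sprintf("titration_series: %d spectra, T = %.2f K, ex %.0f nm\n",
              length(x$spectra), x$temperature, x$excitation_wavelength))
  cat("  [ligand] mol/L:", paste(signif(conc, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Ligand concentrations of a titration series
#' @param series A `titration_series`.
#' @return Numeric vector of concentrations (mol/L), ascending.
#' @export
concentrations <- function(series) {
  vapply(series$spectra, function(s) s$ligand_concentration, 0)
}

detect_delim <- function(lines) {
  # choose the delimiter that splits the header into the most fields
  if (!length(lines)) return(",")
  n_tab <- lengths(regmatches(lines[1L], gregexpr("\t", lines[1L], fixed = TRUE)))
  n_com <- lengths(regmatches(lines[1L], gregexpr(",", lines[1L], fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a titration series from a delimited text file
#'
#' Expected layout: a header row whose first field is a wavelength label and
#' whose remaining fields are ligand concentrations in mol/L; one row per
#' emission wavelength with the corresponding intensities. Comma or tab
#' delimited (auto-detected); lines starting with `#` are ignored. One file
#' holds one temperature.
#'
#' @param path Path to the file.
#' @param excitation_wavelength Excitation wavelength in nm.
#' @param temperature Temperature in K (or use `temperature_c`).
#' @param temperature_c Temperature in degrees C; converted via
#'   [celsius_to_kelvin()]. Give exactly one of the two.
#'
#' @return A [titration_series()] with spectra sorted by ascending
#'   concentration.
#' @export
read_titration <- function(path, excitation_wavelength = 295,
                           temperature = NULL, temperature_c = NULL) {
  if (is.null(temperature) == is.null(temperature_c))
    stop("give exactly one of temperature (K) or temperature_c (degrees C)")
  if (is.null(temperature)) temperature <- celsius_to_kelvin(temperature_c)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) < 3L) stop("titration file needs a header and at least 2 data rows")
  delim <- detect_delim(lines)
  fields <- strsplit(lines, delim, fixed = TRUE)
  header <- trimws(fields[[1L]])
  ncol <- length(header)
  if (ncol < 2L) stop("titration file needs at least one concentration column")
  conc <- suppressWarnings(as.numeric(header[-1L]))
  if (any(is.na(conc)))
    stop("non-numeric concentration in header: ",
         paste(header[-1L][is.na(conc)], collapse = ", "))
  if (anyDuplicated(conc)) stop("duplicate concentrations in header")
  if (!any(conc == 0)) stop("no reference spectrum: a concentration-0 column is required")
  body <- fields[-1L]
  bad <- which(lengths(body) != ncol)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 lineno[-1L][bad[1L]], ncol, lengths(body)[bad[1L]]))
  mat <- suppressWarnings(vapply(body, as.numeric, numeric(ncol)))
  if (anyNA(mat)) {
    bad_row <- which(colSums(is.na(mat)) > 0)[1L]
    stop(sprintf("parse error at line %d: non-numeric cell", lineno[-1L][bad_row]))
  }
  mat <- t(mat)                      # rows = wavelengths
  wl <- mat[, 1L]
  spectra <- lapply(seq_along(conc), function(j)
    emission_spectrum(wl, mat[, j + 1L], excitation_wavelength, temperature, conc[j]))
  titration_series(spectra)
}

#' Write a titration series to a delimited text file
#'
#' Emits the same dialect [read_titration()] consumes (header of
#' concentrations in mol/L, one wavelength per row) at full precision, so a
#' read/write round trip is lossless.
#'
#' @param series A `titration_series`.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path, delim = ",") {
  conc <- concentrations(series)
  wl <- series$spectra[[1L]]$wavelengths
  mat <- vapply(series$spectra, function(s) s$intensities, numeric(length(wl)))
  header <- paste(c("wavelength_nm", format(conc, digits = 17, trim = TRUE, scientific = TRUE)),
                  collapse = delim)
  rows <- apply(cbind(wl, mat), 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = delim))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Intensity of a spectrum at a wavelength
#'
#' Exact grid value when the wavelength lies on the grid; linear
#' interpolation between the bracketing grid points otherwise.
#'
#' @param spectrum An `emission_spectrum`.
#' @param wavelength Query wavelength in nm, inside the grid range.
#' @return Intensity in a.u.
#' @export
intensity_at <- function(spectrum, wavelength) {
  wl <- spectrum$wavelengths
  if (wavelength < wl[1L] || wavelength > wl[length(wl)])
    stop(sprintf("wavelength %g nm outside grid [%g, %g]",
                 wavelength, wl[1L], wl[length(wl)]))
  stats::approx(wl, spectrum$intensities, xout = wavelength)$y
}

#' Fluorescence change per ligand concentration
#'
#' Computes \eqn{\Delta F = F - F_0} at the analysis wavelength for every
#' non-zero ligand concentration, where \eqn{F_0} is the reference spectrum.
#' Pairs with \eqn{\Delta F \le 0} cannot enter the double-reciprocal fit
#' (their reciprocal is undefined or unphysical) and are returned separately
#' in the `"excluded"` attribute rather than raising an error.
#'
#' @param series A `titration_series`.
#' @param wavelength Analysis wavelength in nm; default 340, the tryptophan
#'   emission convention for lysozyme.
#' @return A data frame with columns `concentration` (mol/L) and `delta_f`
#'   (a.u.), one row per retained concentration; excluded pairs in
#'   `attr(, "excluded")`.
#' @export
delta_f_series <- function(series, wavelength = 340) {
  conc <- concentrations(series)
  f0 <- intensity_at(series$spectra[[which(conc == 0)]], wavelength)
  nz <- which(conc > 0)
  df <- vapply(series$spectra[nz], function(s) intensity_at(s, wavelength) - f0, 0)
  out <- data.frame(concentration = conc[nz], delta_f = df)
  keep <- out$delta_f > 0
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) < 3L)
    stop("insufficient points for the double-reciprocal fit: need >= 3 with positive delta F")
  attr(res, "excluded") <- out[!keep, , drop = FALSE]
  res
}

#' Rayleigh light scattering intensities
#'
#' Extracts relative scattering intensities from synchronous-scan records in
#' which excitation equals emission wavelength (350 nm by convention).
#' Intensities are normalized to the ligand-free record when one exists;
#' otherwise raw values are returned with attribute `normalized = FALSE`.
#'
#' @param records Data frame with columns `concentration` (mol/L),
#'   `excitation` (nm), `emission` (nm) and `intensity` (a.u.).
#' @param wavelength Synchronous wavelength in nm (default 350).
#' @return Data frame with columns `concentration` and `intensity`
#'   (normalized or raw), sorted by concentration; attribute `normalized`.
#' @export
rls_intensity <- function(records, wavelength = 350) {
  need <- c("concentration", "excitation", "emission", "intensity")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad <- which(records$excitation != records$emission)
  if (length(bad))
    stop(sprintf("not a synchronous record: row %d has excitation %g != emission %g",
                 bad[1L], records$excitation[bad[1L]], records$emission[bad[1L]]))
  rec <- records[records$excitation == wavelength, , drop = FALSE]
  if (!nrow(rec)) stop("no records at the synchronous wavelength ", wavelength, " nm")
  rec <- rec[order(rec$concentration), , drop = FALSE]
  ref <- rec$intensity[rec$concentration == 0]
  normalized <- length(ref) == 1L && ref > 0
  out <- data.frame(concentration = rec$concentration,
                    intensity = if (normalized) rec$intensity / ref else rec$intensity)
  rownames(out) <- NULL
  attr(out, "normalized") <- normalized
  out
}
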