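#' Construct a spectrum
#'
#' A spectrum is a set of values (absorbance in OD, or difference absorbance
#' in mOD) on a strictly increasing wavelength grid in nanometres.
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly increasing.
#' @param values Numeric vector of the same length as `wavelengths`.
#' @param label Free-text label (e.g. `"S_dark"`).
#' @param unit Value unit, `"OD"` or `"mOD"`.
#'
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths`, `values`, `label` and `unit`.
#' @examples
#' s <- spectrum(seq(500, 700, by = 2), dnorm(seq(500, 700, by = 2), 600, 20))
#' print(s)
#' @export
spectrum <- function(wavelengths, values, label = "", unit = "OD") {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) == 0L)
    stop("spectrum: empty wavelength grid", call. = FALSE)
  if (length(wavelengths) != length(values))
    stop("spectrum: wavelengths and values must have equal length", call. = FALSE)
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("spectrum: wavelengths must be strictly increasing", call. = FALSE)
  structure(
    list(wavelengths = wavelengths, values = values,
         label = as.character(label), unit = match.arg(unit, c("OD", "mOD"))),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.1f-%.1f nm [%s]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$unit))
  invisible(x)
}

#' Interpolate a spectrum at arbitrary wavelengths
#'
#' Linear interpolation; wavelengths outside the grid are an error.
#'
#' @param s A [spectrum()].
#' @param wl Wavelengths (nm) at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
spectrum_at <- function(s, wl) {
  stopifnot(inherits(s, "spectrum"))
  if (any(wl < min(s$wavelengths) | wl > max(s$wavelengths)))
    stop("spectrum_at: wavelength outside the spectrum's grid", call. = FALSE)
  stats::approx(s$wavelengths, s$values, xout = wl)$y
}

#' Gaussian absorption band
#'
#' A single Gaussian band parameterised by its centre (nm), full width at
#' half maximum (nm) and peak amplitude. Amplitudes carry whatever scale the
#' containing spectrum uses: extinction (mM^-1 cm^-1) for species spectra,
#' mOD for pump-probe signal components; negative amplitudes are allowed for
#' signed difference components.
#'
#' @param center Band centre (nm), within 250-900 nm.
#' @param fwhm Full width at half maximum (nm), > 0.
#' @param amplitude Peak amplitude (sign allowed).
#' @return An object of class `"gaussian_band"`.
#' @export
gaussian_band <- function(center, fwhm, amplitude) {
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("gaussian_band: fwhm must be > 0", call. = FALSE)
  if (!is.finite(center) || center < 250 || center > 900)
    stop("gaussian_band: center must lie within [250, 900] nm", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude),
            class = "gaussian_band")
}

#' Species spectrum built from Gaussian bands
#'
#' Named collection of Gaussian bands describing one chemical species'
#' extinction spectrum (free bilin, non-covalent intermediate, covalent
#' holo-protein, dark state or photoproduct) or one pump-probe signal
#' component. Absorbing species must evaluate non-negative on any grid,
#' which is guaranteed by requiring non-negative band amplitudes for them.
#'
#' @param name Species name; one of `"free_bilin"`, `"noncovalent"`,
#'   `"covalent"`, `"dark_state"`, `"photoproduct"`, or a free-text label for
#'   signed pump-probe components.
#' @param bands List of [gaussian_band()] objects (at least one).
#' @return An object of class `"species_spectrum"`.
#' @export
species_spectrum <- function(name, bands) {
  if (inherits(bands, "gaussian_band")) bands <- list(bands)
  if (length(bands) == 0L)
    stop("species_spectrum: at least one band is required", call. = FALSE)
  stopifnot(all(vapply(bands, inherits, logical(1), "gaussian_band")))
  absorbing <- c("free_bilin", "noncovalent", "covalent",
                 "dark_state", "photoproduct")
  if (name %in% absorbing &&
      any(vapply(bands, function(b) b$amplitude, numeric(1)) < 0))
    stop("species_spectrum: absorbing species '", name,
         "' must have non-negative band amplitudes", call. = FALSE)
  structure(list(name = name, bands = bands), class = "species_spectrum")
}

#' Evaluate Gaussian bands on a wavelength grid
#'
#' The value at wavelength lambda is the sum over bands of
#' `amplitude * exp(-4 log(2) (lambda - center)^2 / fwhm^2)`.
#'
#' @param bands A list of [gaussian_band()]s, a single band, or a
#'   [species_spectrum()].
#' @param grid Strictly increasing wavelength grid (nm).
#' @param label,unit Passed to [spectrum()].
#' @return A [spectrum()] on `grid`. An empty band list yields all zeros.
#' @export
gaussian_spectrum <- function(bands, grid, label = "", unit = "OD") {
  if (inherits(bands, "species_spectrum")) {
    if (!nzchar(label)) label <- bands$name
    bands <- bands$bands
  }
  if (inherits(bands, "gaussian_band")) bands <- list(bands)
  if (length(grid) == 0L)
    stop("gaussian_spectrum: empty wavelength grid", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("gaussian_spectrum: grid must be strictly increasing", call. = FALSE)
  v <- numeric(length(grid))
  for (b in bands)
    v <- v + b$amplitude * exp(-4 * log(2) * (grid - b$center)^2 / b$fwhm^2)
  spectrum(grid, v, label = label, unit = unit)
}
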