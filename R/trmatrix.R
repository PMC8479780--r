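#' Time-resolved absorbance matrix
#'
#' The primary measured object: (difference) absorbance on a time x
#' wavelength grid. Times are in seconds (assembly experiments) or
#' picoseconds (pump-probe), carried as a unit tag; values are OD or mOD.
#'
#' @param times Strictly increasing time grid.
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param values Numeric matrix, `length(times)` rows x
#'   `length(wavelengths)` columns.
#' @param time_unit `"s"` or `"ps"`.
#' @param value_unit `"OD"` or `"mOD"`.
#' @param metadata Named list of provenance (scenario parameters, seeds, ...).
#' @return An object of class `"trmatrix"`.
#' @export
trmatrix <- function(times, wavelengths, values, time_unit = "s",
                     value_unit = "OD", metadata = list()) {
  times <- as.numeric(times)
  wavelengths <- as.numeric(wavelengths)
  values <- as.matrix(values)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("trmatrix: times must be strictly increasing", call. = FALSE)
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("trmatrix: wavelengths must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(times) || ncol(values) != length(wavelengths))
    stop(sprintf(
      "trmatrix: values must be %d x %d (time x wavelength), got %d x %d",
      length(times), length(wavelengths), nrow(values), ncol(values)),
      call. = FALSE)
  structure(
    list(times = times, wavelengths = wavelengths, values = unname(values),
         time_unit = match.arg(time_unit, c("s", "ps")),
         value_unit = match.arg(value_unit, c("OD", "mOD")),
         metadata = metadata),
    class = "trmatrix"
  )
}

#' @export
print.trmatrix <- function(x, ...) {
  cat(sprintf(
    "<trmatrix> %d times (%.4g-%.4g %s) x %d wavelengths (%.1f-%.1f nm) [%s]\n",
    length(x$times), min(x$times), max(x$times), x$time_unit,
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$value_unit))
  invisible(x)
}

#' @export
dim.trmatrix <- function(x) dim(x$values)

#' Extract the spectrum at the grid time nearest to `t`
#'
#' Nearest-grid-point lookup (not interpolation), matching discrete
#' acquisition.
#'
#' @param m A [trmatrix()].
#' @param t Time in the matrix's time unit; must lie within the data range.
#' @return A [spectrum()] (the matrix row), labelled with the actual grid time.
#' @export
time_slice <- function(m, t) {
  stopifnot(inherits(m, "trmatrix"))
  if (t < min(m$times) || t > max(m$times))
    stop(sprintf("time_slice: t = %g outside data range [%g, %g] %s",
                 t, min(m$times), max(m$times), m$time_unit), call. = FALSE)
  i <- which.min(abs(m$times - t))
  spectrum(m$wavelengths, m$values[i, ],
           label = sprintf("t = %g %s", m$times[i], m$time_unit),
           unit = m$value_unit)
}

# --- delimited text dialect -------------------------------------------------
# Row 1: unit tag "time_unit|value_unit" in cell (1,1), then wavelengths.
# Column 1 (rows 2..n): times. Tab-separated, full double precision.

#' Write a time-resolved matrix to delimited text
#'
#' Dialect: tab-separated; first row holds the unit tag
#' `"<time_unit>|<value_unit>"` followed by the wavelength grid; the first
#' column of subsequent rows holds the times. Values are written with 17
#' significant digits so that a read/write round trip is lossless.
#'
#' @param m A [trmatrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "trmatrix"))
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(c(paste0(m$time_unit, "|", m$value_unit),
                    fmt(m$wavelengths)), collapse = "\t")
  rows <- vapply(seq_along(m$times), function(i)
    paste(c(fmt(m$times[i]), fmt(m$values[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a time-resolved matrix from delimited text
#'
#' Inverse of [write_matrix()]; validates axis monotonicity and row lengths,
#' naming the offending row or column on failure.
#'
#' @param path File path.
#' @return A [trmatrix()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    stop("read_matrix: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("read_matrix: file must contain a header row and at least one data row",
         call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  tag <- strsplit(cells[[1]][1], "|", fixed = TRUE)[[1]]
  if (length(tag) != 2L)
    stop("read_matrix: cell (1,1) must be a unit tag 'time_unit|value_unit'",
         call. = FALSE)
  wl <- as.numeric(cells[[1]][-1])
  ncol_expect <- length(wl) + 1L
  bad <- which(vapply(cells[-1], length, integer(1)) != ncol_expect)
  if (length(bad))
    stop("read_matrix: ragged row ", bad[1] + 1L, " (expected ",
         ncol_expect, " fields)", call. = FALSE)
  body <- do.call(rbind, lapply(cells[-1], as.numeric))
  times <- body[, 1]
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("read_matrix: time column is not strictly increasing at row ",
         which(diff(times) <= 0)[1] + 2L, call. = FALSE)
  if (length(wl) > 1L && any(diff(wl) <= 0))
    stop("read_matrix: wavelength row is not strictly increasing at column ",
         which(diff(wl) <= 0)[1] + 2L, call. = FALSE)
  trmatrix(times, wl, body[, -1, drop = FALSE],
           time_unit = tag[1], value_unit = tag[2])
}

#' Write / read a two-column spectrum file
#'
#' Tab-separated, one header line `wavelength_nm<TAB><unit>`, then
#' wavelength/value pairs at 17 significant digits.
#'
#' @param s A [spectrum()].
#' @param path File path.
#' @return `path` invisibly (write); a [spectrum()] (read).
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  writeLines(c(paste0("wavelength_nm\t", s$unit),
               sprintf("%.17g\t%.17g", s$wavelengths, s$values)), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    stop("read_spectrum: file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- do.call(rbind, lapply(strsplit(lines[-1], "\t", fixed = TRUE),
                                as.numeric))
  spectrum(body[, 1], body[, 2], unit = header[2])
}

#' Bin a matrix along the wavelength axis
#'
#' Consecutive non-overlapping groups of `n_pixels` detector pixels are
#' averaged (both the values and the wavelength coordinates); a trailing
#' remainder group shorter than `n_pixels` is averaged as-is so no data are
#' dropped.
#'
#' @param m A [trmatrix()].
#' @param n_pixels Pixels per bin (>= 1, <= number of wavelength points).
#' @return A [trmatrix()] with `ceiling(n_wl / n_pixels)` wavelength points.
#' @export
bin_wavelength <- function(m, n_pixels) {
  stopifnot(inherits(m, "trmatrix"))
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 1L)
    stop("bin_wavelength: n_pixels must be >= 1", call. = FALSE)
  nw <- length(m$wavelengths)
  if (n_pixels > nw)
    stop("bin_wavelength: n_pixels (", n_pixels,
         ") exceeds the wavelength grid size (", nw, ")", call. = FALSE)
  if (n_pixels == 1L) return(m)
  grp <- (seq_len(nw) - 1L) %/% n_pixels
  wl <- as.numeric(tapply(m$wavelengths, grp, mean))
  vals <- t(apply(m$values, 1, function(row) tapply(row, grp, mean)))
  if (length(wl) == 1L) vals <- matrix(vals, ncol = 1L)
  trmatrix(m$times, wl, vals, time_unit = m$time_unit,
           value_unit = m$value_unit, metadata = m$metadata)
}

#' Bin a matrix logarithmically along the time axis
#'
#' Times are grouped into log-spaced bins covering the data range with
#' `points_per_decade` bins per decade; each output row is the arithmetic
#' mean of its member rows and the representative time is the geometric mean
#' of the member times (the natural representative on a log axis). Empty
#' bins are dropped.
#'
#' @param m A [trmatrix()] with all times > 0.
#' @param points_per_decade Bins per decade of time (>= 1).
#' @return A [trmatrix()].
#' @export
bin_time_log <- function(m, points_per_decade) {
  stopifnot(inherits(m, "trmatrix"))
  if (any(m$times <= 0))
    stop("bin_time_log: all times must be > 0", call. = FALSE)
  ppd <- as.integer(points_per_decade)
  if (ppd < 1L)
    stop("bin_time_log: points_per_decade must be >= 1", call. = FALSE)
  lt <- log10(m$times)
  # bin index on a log grid anchored at the first time
  grp <- floor((lt - lt[1]) * ppd + 1e-12)
  keep <- sort(unique(grp))
  times <- vapply(keep, function(g) exp(mean(log(m$times[grp == g]))),
                  numeric(1))
  vals <- do.call(rbind, lapply(keep, function(g)
    colMeans(m$values[grp == g, , drop = FALSE])))
  trmatrix(times, m$wavelengths, vals, time_unit = m$time_unit,
           value_unit = m$value_unit, metadata = m$metadata)
}
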