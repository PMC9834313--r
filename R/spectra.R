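#' Spectrum container
#'
#' A wavenumber grid plus per-point values, tagged as apparent absorbance
#' (`"absorbance"`) or extinction efficiency (`"qext"`).  Absorbance values
#' are not forced non-negative: raw experimental baselines may dip below
#' zero.
#'
#' @param nu Strictly increasing positive wavenumber grid (cm\eqn{^{-1}}).
#' @param value Finite numeric values, one per grid point.
#' @param kind `"absorbance"` or `"qext"`.
#' @return An object of class `spectrum` (list with `nu`, `value`, `kind`).
#' @export
#' @examples
#' spectrum(seq(500, 4000, 4), rep(0.1, 876), kind = "absorbance")
spectrum <- function(nu, value, kind = c("qext", "absorbance")) {
  kind <- match.arg(kind)
  nu <- validate_grid(nu)
  stopifnot(is.numeric(value))
  if (length(value) != length(nu))
    stop("`value` must have one entry per grid point", call. = FALSE)
  if (anyNA(value) || any(!is.finite(value)))
    stop("spectrum values must be finite", call. = FALSE)
  structure(list(nu = nu, value = as.numeric(value), kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kind = %s, %d points, %.6g..%.6g cm^-1, value range [%.4g, %.4g]\n",
              x$kind, length(x$nu), min(x$nu), max(x$nu),
              min(x$value), max(x$value)))
  invisible(x)
}

check_kind <- function(spec, kind) {
  stopifnot(inherits(spec, "spectrum"))
  if (!identical(spec$kind, kind))
    stop(sprintf("expected a '%s' spectrum, got '%s'", kind, spec$kind),
         call. = FALSE)
  invisible(spec)
}

#' Convert apparent absorbance to extinction efficiency
#'
#' \deqn{Q_{ext}(\tilde\nu) = \frac{G}{g}\left(1 - 10^{-\mathcal{A}(\tilde\nu)}\right)}
#' where \eqn{G/g > 1} is the ratio of the detector reception area to the
#' sphere's geometric cross section.  With a single-element detector the two
#' representations carry the same information; which one is convenient
#' depends on whether the data came from a transmission measurement
#' (absorbance) or a scattering computation (efficiency).
#'
#' @param spec An absorbance [spectrum()].
#' @param g_ratio \eqn{G/g}, dimensionless, must exceed 1.
#' @return A [spectrum()] of kind `"qext"` on the same grid.
#' @export
absorbance_to_qext <- function(spec, g_ratio) {
  check_kind(spec, "absorbance")
  stopifnot(is.numeric(g_ratio), length(g_ratio) == 1L, is.finite(g_ratio))
  if (g_ratio <= 1) stop("`g_ratio` (G/g) must be > 1", call. = FALSE)
  spectrum(spec$nu, g_ratio * (1 - 10^(-spec$value)), kind = "qext")
}

#' Convert extinction efficiency to apparent absorbance
#'
#' Inverse of [absorbance_to_qext()]:
#' \eqn{\mathcal{A} = -\log_{10}(1 - Q_{ext}\,g/G)}.  Requires
#' \eqn{Q_{ext} < G/g} pointwise; values at or above the saturation bound
#' signal that the supplied `g_ratio` is too small for the data.
#'
#' @param spec A qext [spectrum()].
#' @inheritParams absorbance_to_qext
#' @return A [spectrum()] of kind `"absorbance"`.
#' @export
qext_to_absorbance <- function(spec, g_ratio) {
  check_kind(spec, "qext")
  stopifnot(is.numeric(g_ratio), length(g_ratio) == 1L, is.finite(g_ratio))
  if (g_ratio <= 1) stop("`g_ratio` (G/g) must be > 1", call. = FALSE)
  if (any(spec$value >= g_ratio))
    stop("Q_ext >= G/g at some points: `g_ratio` too small for these data",
         call. = FALSE)
  spectrum(spec$nu, -log10(1 - spec$value / g_ratio), kind = "absorbance")
}

#' Experimental distortion parameters
#'
#' Models the systematic errors of raw absorbance spectra as a multiplicative
#' scaling plus a quadratic additive baseline in the centred, range-normalized
#' wavenumber coordinate
#' \eqn{u = (\tilde\nu - \tilde\nu_{mid})/(\tilde\nu_{max}-\tilde\nu_{min})
#' \in [-1/2, 1/2]}:
#' \deqn{\mathcal{A}_{obs} = s\,\mathcal{A} + c_0 + c_1 u + c_2 u^2.}
#' The constant term is the baseline shift, the linear term the tilt, the
#' quadratic term the curvature; normalizing `u` keeps all four parameters
#' O(1) and weakly correlated in fits.
#'
#' @param scale Multiplicative scale \eqn{s > 0}.
#' @param shift Baseline shift \eqn{c_0} (absorbance units).
#' @param tilt Tilt \eqn{c_1} (absorbance units per unit `u`).
#' @param curvature Curvature \eqn{c_2} (absorbance units per unit `u^2`).
#' @return An object of class `distortion_params`.
#' @export
distortion_params <- function(scale = 1, shift = 0, tilt = 0, curvature = 0) {
  vals <- c(scale, shift, tilt, curvature)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  structure(list(scale = as.numeric(scale), shift = as.numeric(shift),
                 tilt = as.numeric(tilt), curvature = as.numeric(curvature)),
            class = "distortion_params")
}

#' @export
print.distortion_params <- function(x, ...) {
  cat(sprintf("<distortion_params> scale %.4g, shift %.4g, tilt %.4g, curvature %.4g\n",
              x$scale, x$shift, x$tilt, x$curvature))
  invisible(x)
}

normalized_coordinate <- function(nu) {
  if (length(nu) < 2L)
    stop("distortion needs a grid of at least 2 points", call. = FALSE)
  (nu - (min(nu) + max(nu)) / 2) / (max(nu) - min(nu))
}

#' Apply a distortion to an absorbance spectrum
#'
#' @param spec An absorbance [spectrum()] with at least 2 grid points.
#' @param d A [distortion_params()].
#' @return The distorted absorbance [spectrum()].
#' @seealso [remove_distortion()] for the exact inverse.
#' @export
apply_distortion <- function(spec, d) {
  check_kind(spec, "absorbance")
  stopifnot(inherits(d, "distortion_params"))
  u <- normalized_coordinate(spec$nu)
  spectrum(spec$nu,
           d$scale * spec$value + d$shift + d$tilt * u + d$curvature * u^2,
           kind = "absorbance")
}

#' Remove a distortion from an absorbance spectrum
#'
#' Exact inverse of [apply_distortion()] (the map is affine and `scale > 0`).
#'
#' @inheritParams apply_distortion
#' @return The undistorted absorbance [spectrum()].
#' @export
remove_distortion <- function(spec, d) {
  check_kind(spec, "absorbance")
  stopifnot(inherits(d, "distortion_params"))
  u <- normalized_coordinate(spec$nu)
  spectrum(spec$nu,
           (spec$value - d$shift - d$tilt * u - d$curvature * u^2) / d$scale,
           kind = "absorbance")
}

# ---- file I/O ---------------------------------------------------------------

parse_numeric_table <- function(path, ncol_expected) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L)
    stop(sprintf("'%s': no data rows", path), call. = FALSE)
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(trimws(body[i]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < ncol_expected || anyNA(vals[seq_len(ncol_expected)]))
      stop(sprintf("'%s' line %d: expected %d numeric columns, got '%s'",
                   path, lineno[i], ncol_expected, body[i]), call. = FALSE)
    vals[seq_len(ncol_expected)]
  })
  do.call(rbind, rows)
}

#' Read a spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-delimited text with `#` comment lines;
#' column 1 is the wavenumber in cm\eqn{^{-1}}, column 2 the value.
#' Descending wavenumber order is re-sorted ascending with a warning;
#' duplicate wavenumbers are an error.
#'
#' @param path File path.
#' @param kind `"qext"` or `"absorbance"`.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, kind = c("qext", "absorbance")) {
  kind <- match.arg(kind)
  tab <- parse_numeric_table(path, 2L)
  nu <- tab[, 1]; val <- tab[, 2]
  if (anyDuplicated(nu))
    stop(sprintf("'%s': duplicate wavenumbers", path), call. = FALSE)
  if (is.unsorted(nu)) {
    warning("wavenumbers not ascending; re-sorting", call. = FALSE)
    o <- order(nu); nu <- nu[o]; val <- val[o]
  }
  spectrum(nu, val, kind = kind)
}

#' Write a spectrum to a two-column text file
#'
#' Values are written with 15 significant digits, giving a lossless
#' round-trip with [read_spectrum()] to better than 12 digits.
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  unit <- if (spec$kind == "qext") "Q_ext" else "apparent_absorbance"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# wavenumber_cm-1  %s", unit), con)
  writeLines(sprintf("%.15g %.15g", spec$nu, spec$value), con)
  invisible(path)
}

#' Read a tabulated complex refractive index
#'
#' Three-column text (`#` comments allowed): wavenumber in cm\eqn{^{-1}},
#' real part \eqn{n}, imaginary part \eqn{k \ge 0}.
#'
#' @param path File path.
#' @return An object of class `index_table`: list with `nu` (ascending) and
#'   complex `index`.
#' @export
read_index_table <- function(path) {
  tab <- parse_numeric_table(path, 3L)
  nu <- tab[, 1]
  if (anyDuplicated(nu))
    stop(sprintf("'%s': duplicate wavenumbers", path), call. = FALSE)
  if (is.unsorted(nu)) {
    o <- order(nu); tab <- tab[o, , drop = FALSE]; nu <- tab[, 1]
  }
  if (any(tab[, 3] < 0))
    stop(sprintf("'%s': negative imaginary index", path), call. = FALSE)
  structure(list(nu = nu, index = complex(real = tab[, 2], imaginary = tab[, 3])),
            class = "index_table")
}

#' Write a complex refractive index table
#'
#' @param nu Wavenumber grid.
#' @param index Complex index values on `nu`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(nu, index, path) {
  nu <- validate_grid(nu)
  stopifnot(length(index) == length(nu))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# wavenumber_cm-1  n  k", con)
  writeLines(sprintf("%.15g %.15g %.15g", nu, Re(index), Im(index)), con)
  invisible(path)
}

#' Interpolate a tabulated index onto a wavenumber grid
#'
#' Linear interpolation in both real and imaginary parts; extrapolation
#' beyond the table range is refused.
#'
#' @param table An [read_index_table()] result (class `index_table`).
#' @param nu Target grid, must lie within the table span.
#' @return Complex vector on `nu`.
#' @export
interpolate_index <- function(table, nu) {
  stopifnot(inherits(table, "index_table"))
  nu <- validate_grid(nu)
  if (min(nu) < min(table$nu) || max(nu) > max(table$nu))
    stop("requested grid extends beyond the index table span; refusing to extrapolate",
         call. = FALSE)
  complex(real = stats::approx(table$nu, Re(table$index), xout = nu)$y,
          imaginary = stats::approx(table$nu, Im(table$index), xout = nu)$y)
}
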