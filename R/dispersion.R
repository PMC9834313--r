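#' Anti-symmetrized Lorentzian absorption band
#'
#' One infrared absorption band of a voxel's dispersion model.  The imaginary
#' refractive index contributed by the band is a Lorentzian centred at
#' `center` minus its mirror image at `-center`, which makes the imaginary
#' index an odd function of wavenumber and guarantees that the corresponding
#' real part is available in closed form through the Kramers-Kronig
#' relations.
#'
#' @param center Band centre \eqn{\tilde\nu_m} in cm\eqn{^{-1}}; must be positive.
#' @param height Peak height \eqn{h_m} (dimensionless, units of imaginary
#'   refractive index); must be non-negative.
#' @param width Half-width \eqn{\Gamma_m} in cm\eqn{^{-1}}; must be positive.
#'
#' @return An object of class `lorentzian_band`.
#' @seealso [voxel_dispersion()], [imag_index()], [real_index()]
#' @export
#' @examples
#' lorentzian_band(center = 1730, height = 0.25, width = 15)
lorentzian_band <- function(center, height, width) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(height), length(height) == 1L, is.finite(height),
            is.numeric(width),  length(width)  == 1L, is.finite(width))
  if (center <= 0) stop("band `center` must be > 0 (cm^-1)", call. = FALSE)
  if (width <= 0)  stop("band `width` must be > 0 (cm^-1)", call. = FALSE)
  if (height < 0)  stop("band `height` must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center),
                 height = as.numeric(height),
                 width  = as.numeric(width)),
            class = "lorentzian_band")
}

#' Dispersion model of one voxel
#'
#' Collects `M` anti-symmetrized Lorentzian bands together with the real
#' baseline index `n_infinity`, the contribution of resonances outside the
#' fitted spectral window (for mid-IR work, chiefly electronic transitions in
#' the visible/UV).  Bands are stored in canonical order: ascending centre,
#' ties broken by descending height, which makes recovered band sets
#' comparable across fits.
#'
#' @param bands A list of [lorentzian_band()] objects (or a single band).
#' @param n_infinity Baseline real refractive index \eqn{n_\infty}; must be
#'   at least 1.
#' @param basis Basis-function family; only `"lorentzian"` is implemented.
#' @param allow_empty Internal switch permitting a band-free model (used by
#'   tests and degenerate forward computations); public use requires at least
#'   one band.
#'
#' @return An object of class `voxel_dispersion` with elements `bands`,
#'   `n_infinity` and `basis`.
#' @export
#' @examples
#' voxel_dispersion(
#'   bands = list(lorentzian_band(1730, 0.25, 15),
#'                lorentzian_band(2950, 0.05, 30)),
#'   n_infinity = 1.48
#' )
voxel_dispersion <- function(bands, n_infinity = 1.5, basis = "lorentzian",
                             allow_empty = FALSE) {
  if (inherits(bands, "lorentzian_band")) bands <- list(bands)
  stopifnot(is.list(bands))
  if (!identical(basis, "lorentzian"))
    stop("only the 'lorentzian' basis is implemented", call. = FALSE)
  if (length(bands) == 0L && !allow_empty)
    stop("a voxel dispersion needs at least one band", call. = FALSE)
  ok <- vapply(bands, inherits, logical(1), what = "lorentzian_band")
  if (!all(ok)) stop("all `bands` must be lorentzian_band objects", call. = FALSE)
  stopifnot(is.numeric(n_infinity), length(n_infinity) == 1L, is.finite(n_infinity))
  if (n_infinity < 1)
    stop("`n_infinity` must be >= 1 (passive dielectric)", call. = FALSE)
  if (length(bands) > 1L) {
    centers <- vapply(bands, `[[`, numeric(1), "center")
    heights <- vapply(bands, `[[`, numeric(1), "height")
    bands <- bands[order(centers, -heights)]
  }
  structure(list(bands = bands,
                 n_infinity = as.numeric(n_infinity),
                 basis = basis),
            class = "voxel_dispersion")
}

#' @export
print.voxel_dispersion <- function(x, ...) {
  cat(sprintf("<voxel_dispersion> %d band(s), n_inf = %.4g\n",
              length(x$bands), x$n_infinity))
  if (length(x$bands)) {
    df <- band_table(x)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Band parameters of a dispersion model as a data frame
#'
#' @param model A [voxel_dispersion()].
#' @return A data frame with columns `center`, `height`, `width`.
#' @export
band_table <- function(model) {
  stopifnot(inherits(model, "voxel_dispersion"))
  data.frame(center = vapply(model$bands, `[[`, numeric(1), "center"),
             height = vapply(model$bands, `[[`, numeric(1), "height"),
             width  = vapply(model$bands, `[[`, numeric(1), "width"))
}

# validate a wavenumber grid: positive, strictly increasing, finite
validate_grid <- function(nu, allow_any_sign = FALSE) {
  if (!is.numeric(nu) || length(nu) == 0L)
    stop("wavenumber grid must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(nu) || any(!is.finite(nu)))
    stop("wavenumber grid must be finite", call. = FALSE)
  if (!allow_any_sign && any(nu <= 0))
    stop("wavenumbers must be > 0 (cm^-1)", call. = FALSE)
  if (length(nu) > 1L && any(diff(nu) <= 0))
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  as.numeric(nu)
}

# shared evaluation core: formal evaluation at arbitrary (even negative)
# wavenumbers; used by the symmetry tests
eval_imag <- function(model, nu) {
  out <- numeric(length(nu))
  for (b in model$bands) {
    um <- (nu - b$center) / b$width
    up <- (nu + b$center) / b$width
    out <- out + b$height / (1 + um^2) - b$height / (1 + up^2)
  }
  out
}

eval_real_increment <- function(model, nu) {
  out <- numeric(length(nu))
  for (b in model$bands) {
    um <- (nu - b$center) / b$width
    up <- (nu + b$center) / b$width
    out <- out - (b$height * um / (1 + um^2) - b$height * up / (1 + up^2))
  }
  out
}

#' Imaginary refractive index of a dispersion model
#'
#' Evaluates the sum of anti-symmetrized Lorentzians
#' \deqn{k(\tilde\nu) = \sum_m \left[
#'   \frac{h_m}{1+((\tilde\nu-\tilde\nu_m)/\Gamma_m)^2} -
#'   \frac{h_m}{1+((\tilde\nu+\tilde\nu_m)/\Gamma_m)^2} \right]}
#' on a wavenumber grid.  The subtracted mirror term makes \eqn{k} odd in
#' \eqn{\tilde\nu}, the causality requirement that gives the real part its
#' closed form.
#'
#' @param model A [voxel_dispersion()] with at least one band.
#' @param nu Strictly increasing positive wavenumber grid (cm\eqn{^{-1}}).
#' @param .formal If `TRUE`, skip grid validation and evaluate at arbitrary
#'   (possibly negative) wavenumbers; used to check the anti-symmetry.
#' @return Numeric vector of imaginary refractive index values.
#' @export
imag_index <- function(model, nu, .formal = FALSE) {
  stopifnot(inherits(model, "voxel_dispersion"))
  if (length(model$bands) == 0L && !.formal && length(nu))
    return(numeric(length(validate_grid(nu))))
  if (!.formal) nu <- validate_grid(nu)
  eval_imag(model, nu)
}

#' Real refractive index of a dispersion model
#'
#' The exact Kramers-Kronig transform of [imag_index()]:
#' \deqn{n(\tilde\nu) = n_\infty - \sum_m \left[
#'   \frac{h_m (\tilde\nu-\tilde\nu_m)/\Gamma_m}{1+((\tilde\nu-\tilde\nu_m)/\Gamma_m)^2} -
#'   \frac{h_m (\tilde\nu+\tilde\nu_m)/\Gamma_m}{1+((\tilde\nu+\tilde\nu_m)/\Gamma_m)^2}
#'   \right].}
#' No numerical Hilbert transform is needed: for this basis the principal-value
#' integral has the closed form above, which is what makes band fitting over a
#' finite spectral window causally consistent.
#'
#' @inheritParams imag_index
#' @return Numeric vector of real refractive index values; tends to
#'   `n_infinity` far from all bands.
#' @export
real_index <- function(model, nu, .formal = FALSE) {
  stopifnot(inherits(model, "voxel_dispersion"))
  if (!.formal) nu <- validate_grid(nu)
  model$n_infinity + eval_real_increment(model, nu)
}

#' Complex refractive index of a dispersion model
#'
#' @inheritParams imag_index
#' @return Complex vector `real_index(model, nu) + 1i * imag_index(model, nu)`.
#' @export
complex_index <- function(model, nu) {
  stopifnot(inherits(model, "voxel_dispersion"))
  nu <- validate_grid(nu)
  complex(real = model$n_infinity + eval_real_increment(model, nu),
          imaginary = eval_imag(model, nu))
}

#' Numerical Kramers-Kronig transform (principal-value oracle)
#'
#' Brute-force numerical evaluation of the Hilbert-transform increment
#' \deqn{n(\tilde\nu)-n_\infty = \frac{1}{\pi}\,\mathrm{PV}\!\!
#'   \int_{-\infty}^{\infty} \frac{k(\tilde\nu')}{\tilde\nu'-\tilde\nu}\,
#'   d\tilde\nu'}
#' from tabulated imaginary-index values on a wide, dense, equally spaced
#' grid.  The integrand is extended anti-symmetrically to negative
#' wavenumbers and the singularity is removed by subtracting
#' \eqn{k(\tilde\nu)} (the subtracted term integrates to a logarithm in
#' closed form), after which the integral is evaluated by the trapezoid rule.
#' This is deliberately independent of [real_index()] and serves as its
#' correctness oracle; production code never needs it because the transform
#' of the Lorentzian basis is analytic.
#'
#' @param nu_wide Equally spaced, strictly increasing wavenumber grid
#'   starting at (or near) 0 and extending well beyond the highest band
#'   (\eqn{\gtrsim 20\times} the largest band centre for 3-digit accuracy).
#' @param k_wide Imaginary-index values on `nu_wide` (positive-wavenumber
#'   branch; the negative branch is implied by anti-symmetry).
#' @param nu_eval Evaluation wavenumbers; must lie below half the top of
#'   `nu_wide` (points further out suffer edge truncation and are refused).
#' @return Numeric vector: the real-part increment over \eqn{n_\infty} at
#'   `nu_eval`.
#' @export
kk_numeric_transform <- function(nu_wide, k_wide, nu_eval) {
  nu_wide <- validate_grid(nu_wide, allow_any_sign = TRUE)
  if (any(nu_wide < 0)) stop("`nu_wide` must be non-negative", call. = FALSE)
  stopifnot(is.numeric(k_wide), length(k_wide) == length(nu_wide))
  h <- diff(nu_wide)
  if (max(h) - min(h) > 1e-9 * max(h))
    stop("`nu_wide` must be equally spaced", call. = FALSE)
  nu_eval <- as.numeric(nu_eval)
  top <- max(nu_wide)
  if (any(nu_eval <= 0) || any(nu_eval > top / 2))
    stop("evaluation points must lie in (0, max(nu_wide)/2]; ",
         "points beyond suffer edge truncation", call. = FALSE)
  h <- h[1]
  # full anti-symmetric extension: grid -top..top
  nu_full <- c(-rev(nu_wide), nu_wide)
  k_full  <- c(-rev(k_wide), k_wide)
  if (nu_wide[1] == 0) {            # drop the duplicated zero sample
    nlen <- length(nu_wide)
    nu_full <- c(-rev(nu_wide[-1]), nu_wide)
    k_full  <- c(-rev(k_wide[-1]), k_wide)
  }
  vapply(seq_along(nu_eval), function(i) {
    v <- nu_eval[i]
    # k at v by linear interpolation of the tabulated branch
    kv <- stats::approx(nu_wide, k_wide, xout = v, rule = 2)$y
    d <- nu_full - v
    integrand <- (k_full - kv) / d
    # where the grid point coincides with v, use the local derivative
    hit <- abs(d) < h * 1e-8
    if (any(hit)) {
      dv <- stats::approx(nu_wide, k_wide, xout = c(v - h / 2, v + h / 2),
                          rule = 2)$y
      integrand[hit] <- (dv[2] - dv[1]) / h
    }
    trap <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) * h
    (trap + kv * log((top - v) / (top + v))) / pi
  }, numeric(1))
}

#' Serialize a dispersion model to YAML
#'
#' Writes (or returns) a key-value document with fields `n_infinity`, `basis`
#' and `bands` (a list of `center_cm1` / `height` / `width_cm1` records).
#'
#' @param model A [voxel_dispersion()].
#' @param path Optional file path; if `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string when `path` is `NULL`.
#' @export
write_dispersion <- function(model, path = NULL) {
  stopifnot(inherits(model, "voxel_dispersion"))
  doc <- list(
    n_infinity = model$n_infinity,
    basis = model$basis,
    bands = lapply(model$bands, function(b)
      list(center_cm1 = b$center, height = b$height, width_cm1 = b$width))
  )
  txt <- yaml::as.yaml(doc, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a dispersion model from YAML
#'
#' @param path File path, or a YAML string produced by [write_dispersion()].
#' @return A [voxel_dispersion()].
#' @export
read_dispersion <- function(path) {
  doc <- if (length(path) == 1L && file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  if (is.null(doc$bands) || is.null(doc$n_infinity))
    stop("not a dispersion document (need `bands` and `n_infinity`)", call. = FALSE)
  bands <- lapply(doc$bands, function(b)
    lorentzian_band(b$center_cm1, b$height, b$width_cm1))
  voxel_dispersion(bands, n_infinity = doc$n_infinity,
                   basis = if (is.null(doc$basis)) "lorentzian" else doc$basis)
}
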