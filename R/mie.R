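#' Sphere geometry
#'
#' Defines the scatterer: a homogeneous sphere (one voxel) or a two-layer
#' core-shell sphere (two voxels, concentric).  Radii are in micrometres.
#'
#' @param outer_radius Outer radius in \eqn{\mu}m; must be positive.
#' @param core_radius Optional core radius in \eqn{\mu}m; if given, must lie
#'   strictly between 0 and `outer_radius`.
#' @return An object of class `sphere_geometry` with elements `outer_radius`,
#'   `core_radius` (possibly `NULL`) and the voxel count `J` (1 or 2).
#' @export
#' @examples
#' sphere_geometry(10)            # homogeneous, 10 um
#' sphere_geometry(10, 8)         # 8 um core inside a 10 um sphere
sphere_geometry <- function(outer_radius, core_radius = NULL) {
  stopifnot(is.numeric(outer_radius), length(outer_radius) == 1L,
            is.finite(outer_radius))
  if (outer_radius <= 0) stop("`outer_radius` must be > 0 (um)", call. = FALSE)
  if (!is.null(core_radius)) {
    stopifnot(is.numeric(core_radius), length(core_radius) == 1L,
              is.finite(core_radius))
    if (core_radius <= 0 || core_radius >= outer_radius)
      stop("`core_radius` must satisfy 0 < core < outer", call. = FALSE)
  }
  structure(list(outer_radius = as.numeric(outer_radius),
                 core_radius = if (is.null(core_radius)) NULL
                               else as.numeric(core_radius),
                 J = if (is.null(core_radius)) 1L else 2L),
            class = "sphere_geometry")
}

#' @export
print.sphere_geometry <- function(x, ...) {
  if (x$J == 1L)
    cat(sprintf("<sphere_geometry> homogeneous, outer radius %.4g um\n",
                x$outer_radius))
  else
    cat(sprintf("<sphere_geometry> core-shell, core %.4g um / outer %.4g um\n",
                x$core_radius, x$outer_radius))
  invisible(x)
}

#' Mie size parameter
#'
#' \eqn{x = 2\pi r \tilde\nu} with the radius converted to cm so that the
#' product with a wavenumber in cm\eqn{^{-1}} is dimensionless
#' (\eqn{x = 2\pi r/\lambda}).
#'
#' @param radius Radius in \eqn{\mu}m (non-negative).
#' @param nu Wavenumber(s) in cm\eqn{^{-1}} (positive).
#' @return Numeric vector of size parameters.
#' @export
#' @examples
#' size_parameter(10, 1000)  # 2*pi
size_parameter <- function(radius, nu) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)
  if (any(nu <= 0)) stop("wavenumbers must be > 0", call. = FALSE)
  2 * pi * (radius * 1e-4) * as.numeric(nu)
}

#' Mie series truncation order
#'
#' Wiscombe-style criterion \eqn{N = \lceil x + 4x^{1/3} + 2 \rceil},
#' clamped below at 3.
#'
#' @param x Size parameter(s), positive.
#' @return Integer vector of series lengths.
#' @export
truncation_order <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  pmax(3L, as.integer(ceiling(x + 4 * x^(1 / 3) + 2)))
}

# recycle / validate a per-grid complex index vector
check_index <- function(m, L, what = "index") {
  m <- as.complex(m)
  if (length(m) == 1L) m <- rep(m, L)
  if (length(m) != L)
    stop(sprintf("`%s` must have length 1 or match the grid", what), call. = FALSE)
  if (anyNA(m) || any(!is.finite(Re(m))) || any(!is.finite(Im(m))))
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  if (any(Im(m) < -1e-12))
    stop(sprintf("`%s` has negative imaginary part; the absorbing convention here is k >= 0",
                 what), call. = FALSE)
  m
}


mie_result <- function(q_ext, q_sca, radius, nu) {
  q_abs <- q_ext - q_sca
  structure(list(q_ext = q_ext, q_sca = q_sca, q_abs = q_abs,
                 geometric_cross_section = pi * radius^2,
                 radius = radius, nu = nu),
            class = "mie_result")
}

#' Extinction, scattering and absorption efficiencies of a homogeneous sphere
#'
#' Lorenz-Mie partial-wave series for a homogeneous sphere in vacuum/air:
#' \deqn{Q_{ext} = \frac{2}{x^2}\sum_n (2n+1)\,\mathrm{Re}(a_n+b_n),\qquad
#'       Q_{sca} = \frac{2}{x^2}\sum_n (2n+1)(|a_n|^2+|b_n|^2),}
#' truncated at [truncation_order()].  The coefficients use the logarithmic
#' derivative of the internal Riccati-Bessel function, computed by downward
#' recurrence (seeded 15 orders above the truncation) for stability at
#' complex argument; the external Riccati-Bessel functions follow the
#' standard two-term upward recurrence at real argument.
#'
#' @param m Complex refractive index, a scalar or one value per grid point;
#'   convention \eqn{\eta = n + ik} with \eqn{k \ge 0} absorbing.
#' @param radius Sphere radius in \eqn{\mu}m, positive.
#' @param nu Strictly increasing positive wavenumber grid (cm\eqn{^{-1}}).
#' @return An object of class `mie_result`: list with per-grid `q_ext`,
#'   `q_sca`, `q_abs`, plus `geometric_cross_section` (\eqn{\mu}m\eqn{^2}).
#' @export
#' @examples
#' res <- qext_homogeneous(1.5 + 0.02i, radius = 10, nu = seq(500, 4000, 50))
#' head(res$q_ext)
qext_homogeneous <- function(m, radius, nu) {
  nu <- validate_grid(nu)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  L <- length(nu)
  m <- check_index(m, L)
  x <- size_parameter(radius, nu)
  ncut <- truncation_order(x)
  res <- .mie_homog_cpp(m, x, ncut)
  mie_result(q_ext = res$q_ext, q_sca = res$q_sca, radius = radius, nu = nu)
}


#' Efficiencies of a two-layer (coated) sphere
#'
#' Aden-Kerker scattering by a concentric core-shell sphere, evaluated with a
#' ratio-stabilized elimination of the interior coefficients: the core enters
#' only through the logarithmic derivative of its internal Riccati-Bessel
#' function (downward recurrence, stable for absorbing cores), and the shell
#' through the regular/irregular Riccati-Bessel pair, combined into an
#' effective logarithmic derivative at the outer surface.  Efficiencies are
#' referenced to the OUTER geometric cross section, so a coated sphere and a
#' homogeneous sphere of the same outer radius are directly comparable.
#'
#' A vanishingly small core (outer size parameter of the core below 0.1) is
#' treated as absent and the sphere computed as homogeneous shell material;
#' the neglected core contribution scales as the cube of its size parameter.
#'
#' @param m_core,m_shell Complex refractive indexes of core and shell
#'   (scalar or per-grid), \eqn{k \ge 0}.
#' @param geometry A [sphere_geometry()] with a core.
#' @param nu Strictly increasing positive wavenumber grid (cm\eqn{^{-1}}).
#' @return A `mie_result` (see [qext_homogeneous()]).
#' @export
qext_coated <- function(m_core, m_shell, geometry, nu) {
  stopifnot(inherits(geometry, "sphere_geometry"))
  if (geometry$J != 2L)
    stop("`geometry` must have a core (use sphere_geometry(outer, core))",
         call. = FALSE)
  nu <- validate_grid(nu)
  L <- length(nu)
  m1 <- check_index(m_core, L, "m_core")
  m2 <- check_index(m_shell, L, "m_shell")
  r1 <- geometry$core_radius; r2 <- geometry$outer_radius
  x1 <- size_parameter(r1, nu)
  x2 <- size_parameter(r2, nu)
  # degenerate limits: negligible core / negligible shell
  if (max(x1) < 0.1) {
    res <- qext_homogeneous(m2, r2, nu); return(res)
  }
  if ((r2 - r1) / r2 < 1e-12) {
    res <- qext_homogeneous(m1, r2, nu); return(res)
  }
  ncut <- truncation_order(x2)
  res <- .mie_coated_cpp(m1, m2, x1, x2, ncut)
  mie_result(q_ext = res$q_ext, q_sca = res$q_sca, radius = r2, nu = nu)
}


#' Extinction-efficiency spectrum predicted by dispersion models
#'
#' The forward map at the heart of the inverse problem: evaluates each
#' voxel's [complex_index()] on the grid and runs the matching Mie solver
#' ([qext_homogeneous()] for one voxel, [qext_coated()] for core-shell).
#'
#' @param models A single [voxel_dispersion()] or a list of one or two
#'   (core first, then shell); the count must match `geometry$J`.
#' @param geometry A [sphere_geometry()].
#' @param nu Wavenumber grid (cm\eqn{^{-1}}).
#' @return A [spectrum()] of kind `"qext"`.
#' @export
qext_from_dispersion <- function(models, geometry, nu) {
  stopifnot(inherits(geometry, "sphere_geometry"))
  if (inherits(models, "voxel_dispersion")) models <- list(models)
  if (length(models) != geometry$J)
    stop(sprintf("geometry has J = %d voxel(s) but %d dispersion model(s) given",
                 geometry$J, length(models)), call. = FALSE)
  nu <- validate_grid(nu)
  if (geometry$J == 1L) {
    m <- complex_index(models[[1L]], nu)
    res <- qext_homogeneous(m, geometry$outer_radius, nu)
  } else {
    mc <- complex_index(models[[1L]], nu)
    ms <- complex_index(models[[2L]], nu)
    res <- qext_coated(mc, ms, geometry, nu)
  }
  spectrum(nu, res$q_ext, kind = "qext")
}
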