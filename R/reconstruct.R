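#' Fit configuration
#'
#' Collects everything the inverse fit needs besides the data: band counts,
#' box constraints, which nuisance parameters are free, optimizer controls
#' and the seed.  Defaults follow the package's standard protocol: centres
#' are confined to the data range plus one initialization bin, heights to
#' `[0, 1]`, widths to `[2, 400]` cm^-1, `n_infinity` to `[1, 2]`; radii, when
#' free, to +/-50% of their starting value unless explicit bounds are given.
#'
#' @param bands_per_voxel Integer vector, bands `M` per voxel (length 1 for a
#'   homogeneous sphere, 2 for core-shell: core first).
#' @param height_bounds,width_bounds,center_bounds,n_infinity_bounds Box
#'   constraints; `center_bounds = NULL` means data range widened by one bin.
#' @param allow_negative_heights If `TRUE`, the height lower bound is the
#'   negative of `height_bounds[2]` (gain bands); default keeps absorption
#'   bands non-negative.
#' @param fit_distortion Fit baseline shift/tilt/curvature/scaling of an
#'   absorbance spectrum alongside the dispersion.
#' @param fit_outer_radius,fit_core_radius Treat the radii as free
#'   parameters.
#' @param outer_radius_start,core_radius_start Starting radii in
#'   \eqn{\mu}m; default to the geometry passed to [fit_dispersion()].
#' @param outer_radius_bounds,core_radius_bounds Optional explicit bounds.
#' @param g_ratio \eqn{G/g} for absorbance-space fitting; defaults to 100
#'   when a distortion is fitted without a known value (the fitted scale then
#'   absorbs the mismatch).
#' @param comparison_space `"auto"` (space of the given data), `"qext"`, or
#'   `"absorbance"`.
#' @param seed Master seed; every random ingredient of the fit derives from
#'   it.
#' @param n_starts Number of multi-start repetitions (distinct sub-seeds for
#'   the random initial heights/widths); the best-objective start wins, ties
#'   go to the earliest start.
#' @param max_iterations,step_tolerance,residual_tolerance
#'   Levenberg-Marquardt controls (per start).
#' @param init_height_range,init_width_range Ranges for the random initial
#'   heights and widths.
#' @param relax_identifiability Demote the "at least 10 data points per free
#'   parameter" guard from error to warning.
#' @param n_reseeds Maximum number of band-reseeding refinement rounds per
#'   start (see Details).
#' @param denoise `"auto"` (default), `"never"` or `"always"`: whether the
#'   optimizer targets a Savitzky-Golay filtered copy of the data (order 3,
#'   21 points).  Exact least squares on noisy points chases the noise into
#'   spurious narrow bands; the filter suppresses the noise while keeping
#'   band shapes.  `"auto"` engages the filter only when the second
#'   differences of the data decorrelate like white noise and the grid is
#'   dense enough (spacing at most 5 cm^-1) for the filter window to be
#'   narrow on the band scale.  The reported objective is always the raw
#'   sum of squares.
#' @param perfect_floor Objective value, as a fraction of
#'   \eqn{\sum_l (Q^{given}_l)^2}, below which a start counts as a perfect
#'   fit: reseeding stops and remaining starts are skipped.
#'
#' @details After each Levenberg-Marquardt run the fit applies a greedy
#' repair common in multi-peak fitting: the band with the smallest integrated
#' absorption (height times width) is relocated to the wavenumber where the
#' smoothed absolute residual is largest, and the solver re-runs from there;
#' the move is kept only when the objective improves.  This rescues starts in
#' which a band initialized far from any true absorption feature loses its
#' gradient signal and dies while two overlapping true bands are covered by a
#' single broad one.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bands_per_voxel,
                       height_bounds = c(0, 1),
                       width_bounds = c(2, 400),
                       center_bounds = NULL,
                       n_infinity_bounds = c(1, 2),
                       allow_negative_heights = FALSE,
                       fit_distortion = FALSE,
                       fit_outer_radius = FALSE,
                       fit_core_radius = FALSE,
                       outer_radius_start = NULL,
                       core_radius_start = NULL,
                       outer_radius_bounds = NULL,
                       core_radius_bounds = NULL,
                       g_ratio = NULL,
                       comparison_space = c("auto", "qext", "absorbance"),
                       seed = 1L,
                       n_starts = 3L,
                       max_iterations = 400L,
                       step_tolerance = 1e-10,
                       residual_tolerance = 1e-10,
                       init_height_range = c(0.001, 0.1),
                       init_width_range = c(5, 50),
                       relax_identifiability = FALSE,
                       n_reseeds = 6L,
                       perfect_floor = 1e-10,
                       denoise = c("auto", "never", "always")) {
  bands_per_voxel <- as.integer(bands_per_voxel)
  stopifnot(length(bands_per_voxel) %in% 1:2, all(bands_per_voxel >= 1L),
            n_starts >= 1L, max_iterations >= 1L,
            height_bounds[1] < height_bounds[2],
            width_bounds[1] < width_bounds[2], width_bounds[1] > 0,
            n_infinity_bounds[1] < n_infinity_bounds[2],
            n_infinity_bounds[1] >= 1)
  if (!is.null(center_bounds))
    stopifnot(center_bounds[1] < center_bounds[2], center_bounds[1] > 0)
  structure(list(bands_per_voxel = bands_per_voxel,
                 height_bounds = height_bounds,
                 width_bounds = width_bounds,
                 center_bounds = center_bounds,
                 n_infinity_bounds = n_infinity_bounds,
                 allow_negative_heights = isTRUE(allow_negative_heights),
                 fit_distortion = isTRUE(fit_distortion),
                 fit_outer_radius = isTRUE(fit_outer_radius),
                 fit_core_radius = isTRUE(fit_core_radius),
                 outer_radius_start = outer_radius_start,
                 core_radius_start = core_radius_start,
                 outer_radius_bounds = outer_radius_bounds,
                 core_radius_bounds = core_radius_bounds,
                 g_ratio = g_ratio,
                 comparison_space = match.arg(comparison_space),
                 seed = as.integer(seed),
                 n_starts = as.integer(n_starts),
                 max_iterations = as.integer(max_iterations),
                 step_tolerance = step_tolerance,
                 residual_tolerance = residual_tolerance,
                 init_height_range = init_height_range,
                 init_width_range = init_width_range,
                 relax_identifiability = isTRUE(relax_identifiability),
                 n_reseeds = as.integer(n_reseeds),
                 perfect_floor = perfect_floor,
                 denoise = match.arg(denoise)),
            class = "fit_config")
}

# deterministic, prefix-stable sub-seed sequence for multi-starts
sub_seeds <- function(seed, n) {
  (abs(as.numeric(seed)) + 77777 * seq_len(n)) %% (2^31 - 1)
}

# ---- parameter packing ------------------------------------------------------

param_layout <- function(config, J) {
  M <- config$bands_per_voxel
  if (length(M) != J)
    stop("`bands_per_voxel` length must equal the voxel count J", call. = FALSE)
  nms <- character(0)
  for (j in seq_len(J)) {
    nms <- c(nms,
             sprintf("v%d_center_%d", j, seq_len(M[j])),
             sprintf("v%d_height_%d", j, seq_len(M[j])),
             sprintf("v%d_width_%d", j, seq_len(M[j])),
             sprintf("v%d_ninf", j))
  }
  if (config$fit_distortion)
    nms <- c(nms, "dist_scale", "dist_shift", "dist_tilt", "dist_curvature")
  if (config$fit_outer_radius) nms <- c(nms, "outer_radius")
  if (config$fit_core_radius)  nms <- c(nms, "core_radius")
  nms
}

unpack_params <- function(par, config, J, geometry) {
  par <- unname(par)       # positional from here on
  M <- config$bands_per_voxel
  models <- vector("list", J)
  i <- 0L
  for (j in seq_len(J)) {
    centers <- par[i + seq_len(M[j])]; i <- i + M[j]
    heights <- par[i + seq_len(M[j])]; i <- i + M[j]
    widths  <- par[i + seq_len(M[j])]; i <- i + M[j]
    ninf <- par[i + 1L]; i <- i + 1L
    bands <- Map(function(c0, h, w)
      structure(list(center = c0, height = h, width = w),
                class = "lorentzian_band"),
      centers, heights, widths)
    models[[j]] <- structure(list(bands = bands, n_infinity = ninf,
                                  basis = "lorentzian"),
                             class = "voxel_dispersion")
  }
  distortion <- NULL
  if (config$fit_distortion) {
    distortion <- structure(list(scale = par[i + 1L], shift = par[i + 2L],
                                 tilt = par[i + 3L], curvature = par[i + 4L]),
                            class = "distortion_params")
    i <- i + 4L
  }
  outer <- geometry$outer_radius
  core <- geometry$core_radius
  if (config$fit_outer_radius) { outer <- par[i + 1L]; i <- i + 1L }
  if (config$fit_core_radius)  { core  <- par[i + 1L]; i <- i + 1L }
  geom <- if (is.null(core)) sphere_geometry(outer)
          else sphere_geometry(outer, min(core, outer * (1 - 1e-9)))
  list(models = models, distortion = distortion, geometry = geom)
}

param_bounds <- function(config, nu, J, geometry) {
  M <- config$bands_per_voxel
  rng <- range(nu)
  lower <- numeric(0); upper <- numeric(0)
  h_lo <- if (config$allow_negative_heights) -config$height_bounds[2]
          else config$height_bounds[1]
  for (j in seq_len(J)) {
    bin <- diff(rng) / M[j]
    # the lower bound stays well above zero: a band whose centre approaches
    # 0 cancels against its mirror term and becomes an invisible "ghost"
    cb <- if (is.null(config$center_bounds))
      c(max(rng[1] / 2, rng[1] - bin), rng[2] + bin) else config$center_bounds
    lower <- c(lower, rep(cb[1], M[j]), rep(h_lo, M[j]),
               rep(config$width_bounds[1], M[j]), config$n_infinity_bounds[1])
    upper <- c(upper, rep(cb[2], M[j]), rep(config$height_bounds[2], M[j]),
               rep(config$width_bounds[2], M[j]), config$n_infinity_bounds[2])
  }
  if (config$fit_distortion) {
    lower <- c(lower, 0.1, -2, -2, -2)
    upper <- c(upper, 10, 2, 2, 2)
  }
  if (config$fit_outer_radius) {
    start <- config$outer_radius_start
    if (is.null(start)) start <- geometry$outer_radius
    b <- config$outer_radius_bounds
    if (is.null(b)) b <- c(0.5, 1.5) * start
    lower <- c(lower, b[1]); upper <- c(upper, b[2])
  }
  if (config$fit_core_radius) {
    start <- config$core_radius_start
    if (is.null(start)) start <- geometry$core_radius
    b <- config$core_radius_bounds
    if (is.null(b)) b <- c(0.5, 1.5) * start
    lower <- c(lower, b[1]); upper <- c(upper, b[2])
  }
  list(lower = lower, upper = upper)
}

#' Initial parameter state for the inverse fit
#'
#' Band centres start equi-spaced at the mid-bin positions
#' \eqn{\tilde\nu_{min} + (m - 1/2)\,\Delta\tilde\nu/M}: an unbiased layout
#' that always places some initial band close to every true band, which is
#' what keeps the optimization out of bad local minima.  Heights and widths
#' are drawn uniformly from the configured ranges under the configuration's
#' seed; `n_infinity` starts at 1.5, the distortion at identity, free radii
#' at their configured starting values.
#'
#' @param config A [fit_config()].
#' @param nu Wavenumber grid of the data.
#' @param J Voxel count (1 or 2).
#' @param geometry A [sphere_geometry()] supplying default radius starts.
#' @return Named list: `par` (named numeric vector), `lower`, `upper`.
#' @export
init_parameters <- function(config, nu, J, geometry = NULL) {
  stopifnot(inherits(config, "fit_config"))
  nu <- validate_grid(nu)
  if (diff(range(nu)) <= 0) stop("grid must span a positive interval", call. = FALSE)
  M <- config$bands_per_voxel
  if (length(M) != J)
    stop("`bands_per_voxel` length must equal J", call. = FALSE)
  if (any(M > length(nu) / 3))
    warning("more band parameters than a third of the grid points; ",
            "the fit may be over-parameterized", call. = FALSE)
  if (is.null(geometry))
    geometry <- if (J == 1L) sphere_geometry(10) else sphere_geometry(10, 8)
  rng <- local_rng(config$seed)
  par <- numeric(0)
  lo <- range(nu)[1]; hi <- range(nu)[2]
  for (j in seq_len(J)) {
    centers <- lo + (seq_len(M[j]) - 0.5) * (hi - lo) / M[j]
    heights <- rng$runif(M[j], config$init_height_range[1], config$init_height_range[2])
    widths  <- rng$runif(M[j], config$init_width_range[1], config$init_width_range[2])
    par <- c(par, centers, heights, widths, 1.5)
  }
  if (config$fit_distortion) par <- c(par, 1, 0, 0, 0)
  if (config$fit_outer_radius) {
    start <- config$outer_radius_start
    if (is.null(start)) start <- geometry$outer_radius
    par <- c(par, start)
  }
  if (config$fit_core_radius) {
    start <- config$core_radius_start
    if (is.null(start)) start <- geometry$core_radius
    if (is.null(start)) stop("core radius start required", call. = FALSE)
    par <- c(par, start)
  }
  names(par) <- param_layout(config, J)
  b <- param_bounds(config, nu, J, geometry)
  par <- pmin(pmax(par, b$lower), b$upper)
  list(par = par, lower = b$lower, upper = b$upper)
}

#' Sum-of-squares target from model and given values
#'
#' \eqn{S = \sum_l (Q^{model}_l - Q^{given}_l)^2}, the scalar the fit
#' minimizes.
#'
#' @param model_values,given_values Numeric vectors on a common grid.
#' @return Scalar \eqn{S \ge 0}.
#' @export
target_s <- function(model_values, given_values) {
  stopifnot(length(model_values) == length(given_values))
  sum((model_values - given_values)^2)
}

# peak contribution of each band of voxel j to the imaginary index inside
# the data window; a band whose centre has drifted toward zero (mirror-term
# cancellation) or far outside the window scores ~0 however large its area
band_utility <- function(par, config, J, nu, j) {
  M <- config$bands_per_voxel
  offs <- cumsum(c(0L, (3L * M + 1L)[-J]))
  sub <- nu[unique(round(seq(1, length(nu), length.out = 64)))]
  vapply(seq_len(M[j]), function(m) {
    ce <- par[offs[j] + m]
    h  <- par[offs[j] + M[j] + m]
    wd <- par[offs[j] + 2L * M[j] + m]
    max(abs(h * (1 / (1 + ((sub - ce) / wd)^2) - 1 / (1 + ((sub + ce) / wd)^2))))
  }, numeric(1))
}

# top-k well-separated local maxima of the smoothed |residual|: candidate
# locations for a missing absorption band
residual_peaks <- function(residuals, nu, k = 3L, min_sep = 150) {
  w <- max(5L, round(length(residuals) / 100))
  sm <- stats::filter(abs(residuals), rep(1 / w, w), sides = 2)
  sm <- ifelse(is.na(sm), 0, sm)
  peaks <- numeric(0)
  for (i in order(sm, decreasing = TRUE)) {
    if (all(abs(nu[i] - peaks) >= min_sep)) {
      peaks <- c(peaks, nu[i])
      if (length(peaks) == k) break
    }
  }
  peaks
}

# relocate the least useful band of voxel `j` to `target` (default: the
# largest smoothed-residual peak); fresh mid-range height/width give the
# solver gradient signal at the new location
reseed_band <- function(par, residuals, config, J, nu, j = 1L, target = NULL) {
  M <- config$bands_per_voxel
  offs <- cumsum(c(0L, (3L * M + 1L)[-J]))
  m <- which.min(band_utility(par, config, J, nu, j))
  if (is.null(target)) target <- residual_peaks(residuals, nu, k = 1L)
  par[offs[j] + m] <- target
  par[offs[j] + M[j] + m] <- mean(config$init_height_range)
  par[offs[j] + 2L * M[j] + m] <- mean(config$init_width_range)
  par
}

# split the strongest band of voxel `j` in two, recycling the voxel's
# weakest band as the second half; rescues two overlapping true bands
# covered by a single broad one
split_band <- function(par, config, J, nu, j = 1L) {
  M <- config$bands_per_voxel
  if (M[j] < 2L) return(NULL)
  offs <- cumsum(c(0L, (3L * M + 1L)[-J]))
  u <- band_utility(par, config, J, nu, j)
  msrc <- which.max(u); mdst <- which.min(u)
  if (msrc == mdst) return(NULL)
  ce <- par[offs[j] + msrc]
  h <- par[offs[j] + M[j] + msrc]
  wd <- par[offs[j] + 2L * M[j] + msrc]
  for (m in c(msrc, mdst)) {
    par[offs[j] + M[j] + m] <- 0.65 * h
    par[offs[j] + 2L * M[j] + m] <- 0.7 * wd
  }
  par[offs[j] + msrc] <- ce - 0.8 * wd
  par[offs[j] + mdst] <- ce + 0.8 * wd
  par
}

# candidate repair moves:# candidate repair moves: per-voxel relocations plus, for layered spheres,
# reassignments of each band to the other voxel (swapping with that voxel's
# least useful band) -- the layered fit's characteristic failure mode is a
# band attributed to the wrong layer
repair_moves <- function(par, residuals, config, J, nu) {
  targets <- residual_peaks(residuals, nu, k = 3L)
  moves <- list()
  for (j in seq_len(J)) {
    for (tg in targets)
      moves <- c(moves, list(reseed_band(par, residuals, config, J, nu, j, tg)))
    sp <- split_band(par, config, J, nu, j)
    if (!is.null(sp)) moves <- c(moves, list(sp))
  }
  if (J > 1L) {
    M <- config$bands_per_voxel
    offs <- cumsum(c(0L, (3L * M + 1L)[-J]))
    idx3 <- function(j, m) offs[j] + c(m, M[j] + m, 2L * M[j] + m)
    for (j in seq_len(J)) {
      jo <- if (j == 1L) 2L else 1L
      mo <- which.min(band_utility(par, config, J, nu, jo))
      for (m in seq_len(M[j])) {
        p <- par
        a <- idx3(j, m); b <- idx3(jo, mo)
        tmp <- p[a]; p[a] <- p[b]; p[b] <- tmp
        moves <- c(moves, list(p))
      }
    }
  }
  moves
}

# noise detector: spectral flatness of the double-differenced data over the
# upper frequency band (omega in [pi/4, pi]), whitened by the differencing
# response.  White noise is flat there (flatness ~ exp(-gamma) ~ 0.56);
# deterministic fine structure -- including the narrowband interference
# ripple of coated spheres, which defeats purely local statistics -- stays
# concentrated (flatness < 0.3 in practice).  Threshold 0.4.
looks_noisy <- function(values) {
  if (length(values) < 42L) return(FALSE)
  d2 <- diff(values, differences = 2L)
  if (stats::sd(d2) == 0) return(FALSE)
  n <- length(d2)
  P <- Mod(stats::fft(d2 - mean(d2)))^2
  k <- seq(floor(n / 8) + 1L, floor(n / 2))
  Pw <- P[k] / (2 * sin(pi * (k - 1) / n))^4
  if (any(Pw <= 0)) return(FALSE)
  exp(mean(log(Pw))) / mean(Pw) > 0.4
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# residual closure shared by objective_s and the solver
make_residual_fn <- function(given, geometry, config, J) {
  space <- config$comparison_space
  if (space == "auto") space <- given$kind
  g_ratio <- config$g_ratio
  if (space == "absorbance" && is.null(g_ratio)) {
    if (!config$fit_distortion)
      stop("absorbance-space fitting needs `g_ratio` (or `fit_distortion = TRUE`, ",
           "whose scale parameter absorbs an assumed G/g of 100)", call. = FALSE)
    g_ratio <- 100
  }
  given_vals <- if (identical(space, given$kind)) given$value
    else if (space == "qext") absorbance_to_qext(given, g_ratio)$value
    else qext_to_absorbance(given, g_ratio)$value
  nu <- given$nu
  function(par) {
    st <- unpack_params(par, config, J, geometry)
    q <- qext_from_dispersion(st$models, st$geometry, nu)
    if (space == "qext") return(q$value - given_vals)
    a <- qext_to_absorbance(q, g_ratio)
    if (!is.null(st$distortion)) a <- apply_distortion(a, st$distortion)
    a$value - given_vals
  }
}

#' Target function S and residuals for a parameter state
#'
#' Evaluates the forward model at packed parameters `par` and returns the
#' sum-of-squares mismatch with the given spectrum plus the residual vector
#' used by the least-squares solver.  Parameters outside the configured
#' bounds are clamped to the nearest bound with a warning.
#'
#' @param par Named parameter vector as produced by [init_parameters()].
#' @param given A [spectrum()] (kind `"qext"`, or `"absorbance"` when
#'   fitting in absorbance space).
#' @param geometry A [sphere_geometry()].
#' @param config A [fit_config()].
#' @return List with `s` (scalar) and `residuals`.
#' @export
objective_s <- function(par, given, geometry, config) {
  stopifnot(inherits(given, "spectrum"), inherits(geometry, "sphere_geometry"),
            inherits(config, "fit_config"))
  J <- geometry$J
  b <- param_bounds(config, given$nu, J, geometry)
  if (any(par < b$lower - 1e-12) || any(par > b$upper + 1e-12)) {
    warning("parameters outside bounds; clamping", call. = FALSE)
    par <- pmin(pmax(par, b$lower), b$upper)
  }
  r <- make_residual_fn(given, geometry, config, J)(par)
  list(s = sum(r^2), residuals = r)
}

fit_result <- function(best, config, geometry, J, history, reference, nu) {
  st <- unpack_params(best$par, config, J, geometry)
  # canonical band ordering for reporting
  models <- lapply(st$models, function(m)
    voxel_dispersion(m$bands, n_infinity = m$n_infinity))
  scores <- NULL
  if (!is.null(reference)) {
    if (inherits(reference, "voxel_dispersion") ||
        inherits(reference, "index_table")) reference <- list(reference)
    scores <- Map(function(ref, rec) score_dispersion(ref, rec, nu = nu),
                  reference, models)
  }
  structure(list(dispersions = models,
                 geometry = st$geometry,
                 distortion = st$distortion,
                 objective = best$objective,
                 converged = best$converged,
                 n_evaluations = best$n_evaluations,
                 start_objectives = history,
                 best_start = best$start,
                 scores = scores,
                 par = best$par),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> S = %.6g, converged = %s, best start %d of %d\n",
              x$objective, x$converged, x$best_start, length(x$start_objectives)))
  for (j in seq_along(x$dispersions)) {
    cat(sprintf("-- voxel %d --\n", j)); print(x$dispersions[[j]])
  }
  print(x$geometry)
  if (!is.null(x$distortion)) print(x$distortion)
  if (!is.null(x$scores))
    for (j in seq_along(x$scores))
      cat(sprintf("voxel %d: R2 real %.4f, R2 imag %.4f\n",
                  j, x$scores[[j]]$r2_real, x$scores[[j]]$r2_imag))
  invisible(x)
}

#' Reconstruct a dispersion model from an extinction or absorbance spectrum
#'
#' The inverse-scattering fit: bounded Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}) on the residuals between the Mie-model spectrum and
#' the given spectrum, repeated from `n_starts` random initializations
#' (equi-spaced centres, random heights and widths under per-start
#' sub-seeds); the start with the smallest final S wins, ties resolved to the
#' earliest start.  Everything the model needs beyond the band parameters --
#' `n_infinity` per voxel, optional distortion parameters of a raw absorbance
#' spectrum, optional outer/core radii -- is fitted jointly.  Deterministic
#' given (data, config, seed).
#'
#' @details Three continuation devices wrap the core solver, all
#' deterministic under the configuration seed.  (1) Each start first fits a
#' lightly smoothed copy of the data (noise-robust basin finding), then the
#' raw data, then runs greedy band-repair rounds (relocation, and for
#' layered spheres reassignment between voxels) ranked on subsampled data.
#' (2) A free radius is scanned over its bounds with full band fits at
#' frozen candidate radii -- the radius landscape carries interference
#' fringes that defeat a pure gradient method -- and released only once the
#' bands have locked on.  (3) A two-voxel fit is initialized from a
#' homogeneous pre-fit with the combined band count: every core/shell
#' assignment of the recovered bands is ranked by short fits and the best
#' assignments seed the starts, which resolves the layer-attribution
#' ambiguity that defeats random initialization.
#'
#' @param given A [spectrum()]; kind `"qext"` for extinction input or
#'   `"absorbance"` for raw absorbance input.
#' @param geometry A [sphere_geometry()]; supplies fixed radii and starting
#'   values for free ones.
#' @param config A [fit_config()] whose `bands_per_voxel` length matches
#'   `geometry$J`.
#' @param reference Optional reference index per voxel (a
#'   [voxel_dispersion()], an `index_table`, or a list of them) for R^2
#'   scoring of the result.
#' @return A `fit_result`: recovered `dispersions`, (possibly refined)
#'   `geometry`, `distortion`, final `objective`, convergence flag,
#'   per-start objective history and optional `scores`.
#' @export
fit_dispersion <- function(given, geometry, config, reference = NULL) {
  stopifnot(inherits(given, "spectrum"), inherits(geometry, "sphere_geometry"),
            inherits(config, "fit_config"))
  J <- geometry$J
  if (length(config$bands_per_voxel) != J)
    stop("`bands_per_voxel` must supply one band count per voxel", call. = FALSE)
  npar <- length(param_layout(config, J))
  if (length(given$nu) < 10 * npar) {
    msg <- sprintf("only %d data points for %d free parameters (< 10 per parameter)",
                   length(given$nu), npar)
    if (config$relax_identifiability) warning(msg, call. = FALSE)
    else stop(msg, "; set relax_identifiability = TRUE to proceed", call. = FALSE)
  }
  resfn_raw <- make_residual_fn(given, geometry, config, J)
  # Noisy data are fitted through a Savitzky-Golay filtered copy (order 3,
  # 21 points): exact least squares on the raw points chases the noise into
  # spurious narrow bands and band-weight shifts that barely change Q_ext
  # but corrupt the recovered index, while the filter suppresses the noise
  # variance and keeps band shapes.  Clean data (noise below 0.5% of the
  # typical value by the second-difference estimate) are fitted as-is, so
  # noiseless recovery stays exact.  The reported objective is always the
  # raw sum of squares.
  noisy_data <- switch(config$denoise,
    never = FALSE,
    always = TRUE,
    # auto: only on grids dense enough that the filter window spans several
    # band widths (an undersampled smooth ripple is locally
    # indistinguishable from noise), and only when the second differences
    # decorrelate like noise
    stats::median(diff(given$nu)) <= 5 && looks_noisy(given$value))
  given_fit <- if (noisy_data)
    spectrum(given$nu, signal::sgolayfilt(given$value, p = 3, n = 21),
             kind = given$kind)
  else given
  resfn <- make_residual_fn(given_fit, geometry, config, J)
  # stage-1 target: lightly smoothed data (noise-robust basin finding);
  # window 5 points is narrower than the narrowest resolvable band
  given_smooth <- spectrum(given_fit$nu, moving_average(given_fit$value, 5L),
                           kind = given_fit$kind)
  resfn_smooth <- make_residual_fn(given_smooth, geometry, config, J)
  seeds <- sub_seeds(config$seed, config$n_starts)
  floor_s <- config$perfect_floor * sum(given$value^2)   # vs the fit target
  # 3x-subsampled raw data: cheap but unbiased surrogate objective used to
  # rank repair moves and to scan candidate radii
  stride_idx <- seq(1L, length(given$nu), by = 3L)
  given_coarse <- spectrum(given_fit$nu[stride_idx],
                           given_fit$value[stride_idx], kind = given_fit$kind)
  resfn_coarse <- make_residual_fn(given_coarse, geometry, config, J)
  floor_coarse <- max(config$perfect_floor, 1e-8) * sum(given_coarse$value^2)
  run_lm <- function(par, lower, upper, fn = resfn,
                     maxiter = config$max_iterations) {
    minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper, fn = fn,
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter,
        ftol = config$residual_tolerance,
        ptol = config$step_tolerance,
        maxfev = 100000L))
  }
  # layered cascade: homogeneous pre-fit with the combined band count, then
  # enumerate core/shell assignments of the recovered bands and rank them by
  # short fits on the subsampled data; the best assignments seed the starts
  cascade_inits <- NULL
  if (J == 2L && choose(sum(config$bands_per_voxel),
                        config$bands_per_voxel[1]) <= 300) {
    M <- config$bands_per_voxel
    mtot <- sum(M)
    cfg_pre <- config
    cfg_pre$bands_per_voxel <- mtot
    cfg_pre$n_starts <- min(2L, config$n_starts)
    cfg_pre$fit_core_radius <- FALSE
    cfg_pre$core_radius_start <- NULL
    cfg_pre$core_radius_bounds <- NULL
    pre <- fit_dispersion(given, sphere_geometry(geometry$outer_radius), cfg_pre)
    bt <- band_table(pre$dispersions[[1L]])
    pre_ninf <- pre$dispersions[[1L]]$n_infinity
    cfg1 <- config; cfg1$seed <- seeds[1]
    tmpl <- init_parameters(cfg1, given$nu, J, geometry)
    offs <- c(0L, 3L * M[1] + 1L)
    mkpar <- function(sel) {
      oth <- setdiff(seq_len(mtot), sel)
      p <- tmpl$par
      rows <- list(sel, oth)
      for (j in 1:2) {
        p[offs[j] + seq_len(M[j])] <- bt$center[rows[[j]]]
        p[offs[j] + M[j] + seq_len(M[j])] <- bt$height[rows[[j]]]
        p[offs[j] + 2L * M[j] + seq_len(M[j])] <- bt$width[rows[[j]]]
        p[offs[j] + 3L * M[j] + 1L] <- pre_ninf
      }
      if (config$fit_distortion && !is.null(pre$distortion)) {
        p["dist_scale"] <- pre$distortion$scale
        p["dist_shift"] <- pre$distortion$shift
        p["dist_tilt"] <- pre$distortion$tilt
        p["dist_curvature"] <- pre$distortion$curvature
      }
      if (config$fit_outer_radius) p["outer_radius"] <- pre$geometry$outer_radius
      pmin(pmax(p, tmpl$lower), tmpl$upper)
    }
    combos <- utils::combn(mtot, M[1])
    rank_s <- apply(combos, 2, function(sel)
      sum(run_lm(mkpar(sel), tmpl$lower, tmpl$upper,
                 fn = resfn_coarse, maxiter = 45L)$fvec^2))
    keep <- order(rank_s)
    if (config$fit_core_radius) {
      # cross-scan candidate core radii for the leading assignments: the
      # provisional radius biases the first ranking, so re-rank the top few
      # at their per-assignment best radius
      idx <- match("core_radius", names(tmpl$par))
      cands <- seq(tmpl$lower[idx], tmpl$upper[idx], length.out = 21L)
      keep6 <- keep[seq_len(min(4L, length(keep)))]
      scan <- lapply(keep6, function(i) {
        p <- mkpar(combos[, i])
        ss <- vapply(cands, function(r) {
          q <- p; q[idx] <- r
          lo <- tmpl$lower; hi <- tmpl$upper; lo[idx] <- r; hi[idx] <- r
          sum(run_lm(q, lo, hi, fn = resfn_coarse, maxiter = 45L)$fvec^2)
        }, numeric(1))
        p[idx] <- cands[which.min(ss)]
        list(par = p, s = min(ss))
      })
      scan <- scan[order(vapply(scan, `[[`, numeric(1), "s"))]
      cascade_inits <- lapply(scan[seq_len(min(config$n_starts, length(scan)))],
                              `[[`, "par")
    } else {
      cascade_inits <- lapply(keep[seq_len(min(config$n_starts, length(keep)))],
                              function(i) mkpar(combos[, i]))
    }
  }
  # continuation over a free radius: the radius landscape is oscillatory
  # (interference fringes), so a gradient fit cannot traverse it.  Every
  # start scans its candidate radii with its own staged band fit at FROZEN
  # radius on the subsampled data (subsampling, unlike smoothing, keeps the
  # target representable by the model; the smoothed stage only seeds it),
  # and the radius is released once the bands have locked on.
  coarse_smooth <- spectrum(given_coarse$nu,
                            moving_average(given_coarse$value, 5L),
                            kind = given$kind)
  resfn_coarse_smooth <- make_residual_fn(coarse_smooth, geometry, config, J)
  scan_radii <- function(init) {
    free <- c("outer_radius", "core_radius")[c(config$fit_outer_radius,
                                               config$fit_core_radius)]
    for (pname in free) {
      idx <- match(pname, names(init$par))
      cands <- seq(init$lower[idx], init$upper[idx], length.out = 21L)
      best_s <- Inf; best_par <- init$par
      for (r in cands) {
        p <- init$par; p[idx] <- r
        lo <- init$lower; hi <- init$upper
        lo[idx] <- r; hi[idx] <- r
        sol <- run_lm(run_lm(p, lo, hi, fn = resfn_coarse_smooth)$par,
                      lo, hi, fn = resfn_coarse)
        s <- sum(sol$fvec^2)
        for (round in 1:2) {
          if (s <= floor_coarse) break
          improved <- FALSE
          for (jj in seq_len(J)) {
            p2 <- reseed_band(sol$par, sol$fvec, config, J, given_coarse$nu, jj)
            sol2 <- run_lm(p2, lo, hi, fn = resfn_coarse)
            s2 <- sum(sol2$fvec^2)
            if (s2 < s * (1 - 1e-9)) { sol <- sol2; s <- s2; improved <- TRUE }
          }
          if (!improved) break
        }
        if (s < best_s) { best_s <- s; best_par <- sol$par }
        if (best_s <= floor_coarse) break
      }
      init$par <- best_par
    }
    init
  }
  radius_names <- c("outer_radius", "core_radius")
  best <- NULL
  history <- rep(NA_real_, config$n_starts)
  for (k in seq_len(config$n_starts)) {
    cfg_k <- config; cfg_k$seed <- seeds[k]
    init <- init_parameters(cfg_k, given$nu, J, geometry)
    if (!is.null(cascade_inits) && k <= length(cascade_inits)) {
      init$par <- cascade_inits[[k]]
    } else if (config$fit_outer_radius || config$fit_core_radius) {
      init <- scan_radii(init)
    }
    frz <- intersect(radius_names, names(init$par))
    if (length(frz)) {
      # stage 1 with free radii frozen at their scanned/start values
      lo1 <- init$lower; hi1 <- init$upper
      lo1[match(frz, names(init$par))] <- init$par[frz]
      hi1[match(frz, names(init$par))] <- init$par[frz]
      sol1 <- run_lm(init$par, lo1, hi1, fn = resfn_smooth)
    } else {
      sol1 <- run_lm(init$par, init$lower, init$upper, fn = resfn_smooth)
    }
    sol <- run_lm(sol1$par, init$lower, init$upper)
    obj <- sum(sol$fvec^2)
    # greedy repair: candidate relocations/reassignments of weak bands are
    # ranked by short fits on the subsampled data, the best two are refit in
    # full, and a move is kept only when the objective improves
    for (round in seq_len(config$n_reseeds)) {
      if (obj <= floor_s) break
      moves <- repair_moves(sol$par, sol$fvec, config, J, given$nu)
      if (length(moves) > 2L) {
        rank_s <- vapply(moves, function(p)
          sum(run_lm(p, init$lower, init$upper,
                     fn = resfn_coarse, maxiter = 45L)$fvec^2), numeric(1))
        moves <- moves[order(rank_s)][1:2]
      }
      improved <- FALSE
      for (p in moves) {
        sol2 <- run_lm(p, init$lower, init$upper)
        obj2 <- sum(sol2$fvec^2)
        if (obj2 < obj * (1 - 1e-9)) {
          sol <- sol2; obj <- obj2; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    obj_raw <- if (noisy_data) sum(resfn_raw(sol$par)^2) else obj
    history[k] <- obj_raw
    cand <- list(par = sol$par, objective = obj_raw, objective_internal = obj,
                 converged = sol$info %in% 1:4,
                 n_evaluations = sol$niter, start = k)
    if (is.null(best) || obj < best$objective_internal) best <- cand
    if (obj <= floor_s) break   # perfect fit: further starts cannot improve
  }
  out <- fit_result(best, config, geometry, J, history, reference, given$nu)
  if (!out$converged)
    warning("no start converged within the iteration budget; ",
            "returning the best iterate", call. = FALSE)
  out
}

#' Joint reconstruction of a two-layer sphere
#'
#' Convenience wrapper around [fit_dispersion()] for core-shell geometries:
#' checks `J = 2` and that a band count is supplied for each voxel, then
#' jointly fits both voxels' bands (+ `n_infinity` each) through the
#' coated-sphere forward model, optionally with the core radius free.  Note
#' that when core and shell hold the same material the decomposition is not
#' identifiable -- any radius fits equally well -- although the objective
#' still reaches the noise floor.
#'
#' @inheritParams fit_dispersion
#' @return A `fit_result` with two dispersions (core, shell).
#' @export
fit_layered <- function(given, geometry, config, reference = NULL) {
  stopifnot(inherits(geometry, "sphere_geometry"))
  if (geometry$J != 2L)
    stop("`fit_layered` needs a core-shell geometry (J = 2)", call. = FALSE)
  fit_dispersion(given, geometry, config, reference)
}

#' Serialize a fit result to YAML
#'
#' @param result A `fit_result`.
#' @param path Optional output path; if `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
write_fit_result <- function(result, path = NULL) {
  stopifnot(inherits(result, "fit_result"))
  doc <- list(
    objective = result$objective,
    converged = result$converged,
    best_start = result$best_start,
    start_objectives = result$start_objectives,
    geometry = list(outer_radius_um = result$geometry$outer_radius,
                    core_radius_um = result$geometry$core_radius),
    distortion = if (!is.null(result$distortion)) unclass(result$distortion),
    dispersions = lapply(result$dispersions, function(d)
      yaml::yaml.load(write_dispersion(d))),
    scores = if (!is.null(result$scores))
      lapply(result$scores, function(s)
        list(r2_real = s$r2_real, r2_imag = s$r2_imag))
  )
  txt <- yaml::as.yaml(doc, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
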