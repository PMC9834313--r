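#' Random multi-band dispersion model
#'
#' Draws a seeded ground-truth dispersion with resolvable bands: centres are
#' rejection-sampled until every pair is separated by at least 1.5 times the
#' mean of the width range, heights and widths are uniform in their ranges.
#' Stands in for tabulated optical constants of real polymers (multi-band
#' mid-IR spectra of PMMA/PS character) in fully self-contained experiments.
#'
#' @param n_bands Number of bands (\eqn{\ge 1}).
#' @param center_range Centre range in cm\eqn{^{-1}} (default 600-3600, inside
#'   the usual 500-4000 mid-IR window so band wings stay on-grid).
#' @param height_range Peak-height range (imaginary-index units).
#' @param width_range Half-width range in cm\eqn{^{-1}}.
#' @param n_infinity Baseline real index.
#' @param seed Integer seed; same seed, same model.
#' @return A [voxel_dispersion()].
#' @export
random_dispersion <- function(n_bands,
                              center_range = c(600, 3600),
                              height_range = c(0.02, 0.3),
                              width_range = c(10, 60),
                              n_infinity = 1.5,
                              seed = 1L) {
  stopifnot(n_bands >= 1L,
            length(center_range) == 2L, center_range[1] < center_range[2],
            center_range[1] > 0,
            length(height_range) == 2L, height_range[1] <= height_range[2],
            height_range[1] >= 0,
            length(width_range) == 2L, width_range[1] <= width_range[2],
            width_range[1] > 0)
  rng <- local_rng(seed)
  min_gap <- 1.5 * mean(width_range)
  centers <- NULL
  for (attempt in seq_len(10000L)) {
    cand <- sort(rng$runif(n_bands, center_range[1], center_range[2]))
    if (n_bands == 1L || min(diff(cand)) >= min_gap) { centers <- cand; break }
  }
  if (is.null(centers))
    stop("could not place ", n_bands, " bands with the required spacing; ",
         "use fewer bands or a wider centre range", call. = FALSE)
  heights <- rng$runif(n_bands, height_range[1], height_range[2])
  widths  <- rng$runif(n_bands, width_range[1], width_range[2])
  voxel_dispersion(
    bands = Map(lorentzian_band, centers, heights, widths),
    n_infinity = n_infinity
  )
}

# private, restorable RNG scope: draws are reproducible per seed and do not
# disturb the caller's RNG state
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  draw <- function(fn, ...) {
    prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", globalenv())
    if (is.null(prev)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", prev, envir = globalenv())
    out
  }
  list(runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
       sample_int = function(n, size) draw(sample.int, n, size))
}

#' Multiplicative bounded noise
#'
#' Multiplies every point by \eqn{(1+\epsilon)} with \eqn{\epsilon} uniform
#' on \eqn{[-f, +f]}; bounded support makes a stated noise level of, say,
#' 10% literally "up to 10%".
#'
#' @param spec A [spectrum()].
#' @param fraction Noise fraction \eqn{f \in [0, 0.5]}.
#' @param seed Integer seed.
#' @return The noisy [spectrum()] (same kind, same grid).
#' @export
add_noise <- function(spec, fraction, seed = 1L) {
  stopifnot(inherits(spec, "spectrum"),
            is.numeric(fraction), length(fraction) == 1L)
  if (fraction < 0 || fraction > 0.5)
    stop("`fraction` must lie in [0, 0.5]", call. = FALSE)
  if (fraction == 0) return(spec)
  rng <- local_rng(seed)
  eps <- rng$runif(length(spec$nu), -fraction, fraction)
  spectrum(spec$nu, spec$value * (1 + eps), kind = spec$kind)
}

#' Generate a complete synthetic observation
#'
#' Composes the full forward pipeline: dispersion model(s) -> Mie extinction
#' spectrum -> optional conversion to absorbance with distortion -> optional
#' multiplicative noise.  When `distortion` is supplied the observed spectrum
#' is an absorbance spectrum (experimental artefacts live in that
#' representation) and `g_ratio` is required for the conversion; otherwise
#' the observation stays in extinction-efficiency units.
#'
#' @param dispersions A [voxel_dispersion()] or list of 1-2 (core, shell).
#' @param geometry A [sphere_geometry()] with `J` matching the model count.
#' @param nu Wavenumber grid (default 500-4000 cm\eqn{^{-1}} at 2
#'   cm\eqn{^{-1}}).
#' @param noise_fraction Bounded multiplicative noise level, `[0, 0.5]`.
#' @param distortion Optional [distortion_params()].
#' @param g_ratio \eqn{G/g}; required when `distortion` is given.
#' @param seed Integer seed driving the noise draw.
#' @return An object of class `truth_bundle`: list with `dispersions`,
#'   `geometry`, `clean_qext`, `observed`, `noise_fraction`, `distortion`,
#'   `g_ratio`, `seed`.
#' @export
make_observation <- function(dispersions, geometry,
                             nu = seq(500, 4000, by = 2),
                             noise_fraction = 0,
                             distortion = NULL,
                             g_ratio = NULL,
                             seed = 1L) {
  if (inherits(dispersions, "voxel_dispersion")) dispersions <- list(dispersions)
  stopifnot(inherits(geometry, "sphere_geometry"))
  if (length(dispersions) != geometry$J)
    stop("dispersion count must match geometry voxel count", call. = FALSE)
  if (!is.null(distortion) && is.null(g_ratio))
    stop("`g_ratio` is required when a distortion is applied (the conversion ",
         "to absorbance needs it)", call. = FALSE)
  clean <- qext_from_dispersion(dispersions, geometry, nu)
  observed <- clean
  if (!is.null(distortion)) {
    stopifnot(inherits(distortion, "distortion_params"))
    observed <- apply_distortion(qext_to_absorbance(clean, g_ratio), distortion)
  }
  if (noise_fraction > 0)
    observed <- add_noise(observed, noise_fraction, seed = seed)
  structure(list(dispersions = dispersions, geometry = geometry,
                 clean_qext = clean, observed = observed,
                 noise_fraction = noise_fraction,
                 distortion = distortion, g_ratio = g_ratio,
                 seed = as.integer(seed)),
            class = "truth_bundle")
}

#' Write a truth bundle to a directory
#'
#' Emits `truth.yaml` (dispersions, geometry, distortion, noise, seed),
#' `clean_qext.csv` and `observed.csv`.
#'
#' @param bundle A `truth_bundle` from [make_observation()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  doc <- list(
    geometry = list(outer_radius_um = bundle$geometry$outer_radius,
                    core_radius_um = bundle$geometry$core_radius,
                    J = bundle$geometry$J),
    dispersions = lapply(bundle$dispersions, function(d)
      yaml::yaml.load(write_dispersion(d))),
    noise_fraction = bundle$noise_fraction,
    g_ratio = bundle$g_ratio,
    distortion = if (!is.null(bundle$distortion)) unclass(bundle$distortion),
    seed = bundle$seed,
    observed_kind = bundle$observed$kind
  )
  writeLines(yaml::as.yaml(doc, precision = 15), file.path(dir, "truth.yaml"))
  write_spectrum(bundle$clean_qext, file.path(dir, "clean_qext.csv"))
  write_spectrum(bundle$observed, file.path(dir, "observed.csv"))
  invisible(dir)
}

#' Read a truth bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A `truth_bundle`.
#' @export
read_bundle <- function(dir) {
  doc <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  geometry <- sphere_geometry(doc$geometry$outer_radius_um,
                              doc$geometry$core_radius_um)
  dispersions <- lapply(doc$dispersions, function(d)
    read_dispersion(yaml::as.yaml(d, precision = 15)))
  clean <- read_spectrum(file.path(dir, "clean_qext.csv"), kind = "qext")
  observed <- read_spectrum(file.path(dir, "observed.csv"),
                            kind = doc$observed_kind)
  distortion <- if (!is.null(doc$distortion))
    do.call(distortion_params, doc$distortion)
  structure(list(dispersions = dispersions, geometry = geometry,
                 clean_qext = clean, observed = observed,
                 noise_fraction = doc$noise_fraction,
                 distortion = distortion, g_ratio = doc$g_ratio,
                 seed = doc$seed),
            class = "truth_bundle")
}
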