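#' Coefficient of determination of a reconstruction
#'
#' Scores a reconstructed complex refractive index against a reference,
#' separately for real and imaginary parts.  With residuals
#' \eqn{e_k = \eta_k - \tilde\eta_k} (reference minus reconstruction),
#' \deqn{R^2 = 1 - \frac{\sum_k e_k^2}{\sum_k (\eta_k - \bar\eta)^2}}
#' where \eqn{\bar\eta} is the scalar mean of the reference part over the
#' grid.  \eqn{R^2 = 1} is a perfect reconstruction, 0 is no better than the
#' reference's mean, and negative values (worse than the mean) are reported
#' unclamped.
#'
#' @param reference Complex vector: the reference index on the scoring grid.
#' @param reconstruction Complex vector on the same grid.
#' @return An object of class `reconstruction_score`: list with `r2_real`,
#'   `r2_imag`, and the underlying sums `s_res_real`, `s_res_imag`,
#'   `s_tot_real`, `s_tot_imag`.
#' @export
#' @examples
#' r_squared(complex(real = 1:3, imaginary = c(0, .1, .2)),
#'           complex(real = c(1, 2, 4), imaginary = c(0, .1, .25)))
r_squared <- function(reference, reconstruction) {
  reference <- as.complex(reference)
  reconstruction <- as.complex(reconstruction)
  if (length(reference) != length(reconstruction))
    stop("reference and reconstruction must share a grid", call. = FALSE)
  if (length(reference) < 3L)
    stop("need at least 3 points to score", call. = FALSE)
  part_score <- function(ref, rec, what) {
    s_tot <- sum((ref - mean(ref))^2)
    if (s_tot <= 0)
      stop(sprintf("reference %s part is constant; R^2 undefined", what),
           call. = FALSE)
    s_res <- sum((ref - rec)^2)
    list(r2 = 1 - s_res / s_tot, s_res = s_res, s_tot = s_tot)
  }
  re <- part_score(Re(reference), Re(reconstruction), "real")
  im <- part_score(Im(reference), Im(reconstruction), "imaginary")
  structure(list(r2_real = re$r2, r2_imag = im$r2,
                 s_res_real = re$s_res, s_tot_real = re$s_tot,
                 s_res_imag = im$s_res, s_tot_imag = im$s_tot),
            class = "reconstruction_score")
}

#' @export
print.reconstruction_score <- function(x, ...) {
  cat(sprintf("<reconstruction_score> R2 real = %.4f, R2 imag = %.4f\n",
              x$r2_real, x$r2_imag))
  invisible(x)
}

#' Score a fitted dispersion against a reference dispersion or table
#'
#' Evaluates the reconstruction analytically at the scoring wavenumbers (the
#' dispersion model is continuous, so no interpolation of the reconstruction
#' is ever needed) and calls [r_squared()].
#'
#' @param reference A [voxel_dispersion()] or an `index_table`.
#' @param reconstruction A [voxel_dispersion()].
#' @param nu Scoring grid; for an `index_table` reference defaults to the
#'   table's own grid.
#' @return A `reconstruction_score`.
#' @export
score_dispersion <- function(reference, reconstruction, nu = NULL) {
  stopifnot(inherits(reconstruction, "voxel_dispersion"))
  if (inherits(reference, "index_table")) {
    if (is.null(nu)) nu <- reference$nu
    ref <- interpolate_index(reference, nu)
  } else if (inherits(reference, "voxel_dispersion")) {
    if (is.null(nu)) stop("`nu` required when the reference is a dispersion model",
                          call. = FALSE)
    ref <- complex_index(reference, nu)
  } else stop("unsupported reference type", call. = FALSE)
  r_squared(ref, complex_index(reconstruction, nu))
}
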