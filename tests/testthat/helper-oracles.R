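# Independent oracles for the Mie forward models.  These deliberately use a
# different algorithm from the package: Riccati-Bessel FUNCTION VALUES by
# downward recurrence on values (normalized at psi_0 = sin z) and the
# textbook determinant/linear-system forms of the scattering coefficients,
# whereas the package works with logarithmic derivatives and a
# ratio-stabilized elimination.

# psi_0..psi_N at complex z, downward recurrence normalized at psi_0
oracle_psi <- function(z, N) {
  nb <- N + 20L + ceiling(Mod(z))
  p <- complex(length.out = nb + 3)
  p[nb + 3] <- 0i
  p[nb + 2] <- 1e-280 + 0i
  for (n in seq(nb, 0L)) p[n + 1] <- (2 * n + 3) / z * p[n + 2] - p[n + 3]
  p <- p * (sin(z) / p[1])
  p[seq_len(N + 1)]
}

# chi_0..chi_N at complex z, upward recurrence
oracle_chi <- function(z, N) {
  ch <- complex(length.out = N + 1)
  cm1 <- -sin(z)
  ch[1] <- cos(z)
  for (n in 1:N)
    ch[n + 1] <- (2 * n - 1) / z * ch[n] - (if (n == 1) cm1 else ch[n - 1])
  ch
}

# derivatives from the recurrence f'_n = f_{n-1} - (n/z) f_n, n >= 1;
# index 1 holds f'_0
oracle_deriv <- function(vals, z, d0) {
  N <- length(vals) - 1
  d <- complex(length.out = N + 1)
  d[1] <- d0
  for (n in 1:N) d[n + 1] <- vals[n] - n / z * vals[n + 1]
  d
}

# homogeneous sphere efficiencies from the textbook coefficient formulas
oracle_mie_homog <- function(m, x) {
  N <- truncation_order(x)
  pm <- oracle_psi(m * x, N); dpm <- oracle_deriv(pm, m * x, cos(m * x))
  px <- oracle_psi(x + 0i, N); dpx <- oracle_deriv(px, x + 0i, cos(x))
  cx <- oracle_chi(x + 0i, N); dcx <- oracle_deriv(cx, x + 0i, -sin(x))
  xiv <- px - 1i * cx; dxi <- dpx - 1i * dcx
  n <- 1:N; i <- n + 1
  a <- (m * pm[i] * dpx[i] - px[i] * dpm[i]) /
       (m * pm[i] * dxi[i] - xiv[i] * dpm[i])
  b <- (pm[i] * dpx[i] - m * px[i] * dpm[i]) /
       (pm[i] * dxi[i] - m * xiv[i] * dpm[i])
  list(q_ext = 2 / x^2 * sum((2 * n + 1) * Re(a + b)),
       q_sca = 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2)))
}

# coated sphere by direct solution of the 4x4 boundary-condition system per
# order and polarization (column-scaled for conditioning)
oracle_mie_coated <- function(m1, m2, x1, x2) {
  N <- truncation_order(x2)
  z11 <- m1 * x1; z21 <- m2 * x1; z22 <- m2 * x2
  p11 <- oracle_psi(z11, N); d11 <- oracle_deriv(p11, z11, cos(z11))
  p21 <- oracle_psi(z21, N); d21 <- oracle_deriv(p21, z21, cos(z21))
  c21 <- oracle_chi(z21, N); e21 <- oracle_deriv(c21, z21, -sin(z21))
  p22 <- oracle_psi(z22, N); d22 <- oracle_deriv(p22, z22, cos(z22))
  c22 <- oracle_chi(z22, N); e22 <- oracle_deriv(c22, z22, -sin(z22))
  px <- oracle_psi(x2 + 0i, N); dpx <- oracle_deriv(px, x2 + 0i, cos(x2))
  cx <- oracle_chi(x2 + 0i, N); dcx <- oracle_deriv(cx, x2 + 0i, -sin(x2))
  xiv <- px - 1i * cx; dxi <- dpx - 1i * dcx
  solve_last <- function(A, rhs) {
    sc <- apply(abs(A), 2, max); sc[sc == 0] <- 1
    tryCatch(solve(sweep(A, 2, sc, "/"), rhs)[4] / sc[4],
             error = function(e) NA_complex_)
  }
  qe <- 0; qs <- 0
  for (n in 1:N) {
    i <- n + 1
    rhs <- c(0, 0, px[i], dpx[i])
    A <- matrix(c(
      m1 * p11[i], -m2 * p21[i], -m2 * c21[i], 0,
      d11[i],      -d21[i],      -e21[i],      0,
      0,            m2 * p22[i],  m2 * c22[i], xiv[i],
      0,            d22[i],       e22[i],      dxi[i]), 4, 4, byrow = TRUE)
    a <- solve_last(A, rhs)
    B <- matrix(c(
      p11[i],      -p21[i],      -c21[i],      0,
      m1 * d11[i], -m2 * d21[i], -m2 * e21[i], 0,
      0,            p22[i],       c22[i],      xiv[i],
      0,            m2 * d22[i],  m2 * e22[i], dxi[i]), 4, 4, byrow = TRUE)
    b <- solve_last(B, rhs)
    if (is.na(a) || is.na(b)) break
    qe <- qe + (2 * n + 1) * Re(a + b)
    qs <- qs + (2 * n + 1) * (Mod(a)^2 + Mod(b)^2)
  }
  list(q_ext = 2 / x2^2 * qe, q_sca = 2 / x2^2 * qs)
}

# radius (um) giving size parameter x at wavenumber nu (cm^-1)
radius_for_x <- function(x, nu) x / (2 * pi * 1e-4 * nu)
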