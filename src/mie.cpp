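// Lorenz-Mie partial-wave series, homogeneous and two-layer spheres.
// Mirrors the algorithm documented in R/mie.R: logarithmic derivative of the
// internal Riccati-Bessel function by downward recurrence (seeded above
// max(N, |mz|)), external functions by two-term upward recurrence, coated
// coefficients by ratio-stabilized elimination of the interior fields.
#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

// fast complex division (no over/underflow guards; out-of-range orders are
// masked by the isfinite check in the accumulation)
static inline cplx cdiv(const cplx a, const cplx b) {
  double d = b.real() * b.real() + b.imag() * b.imag();
  return cplx((a.real() * b.real() + a.imag() * b.imag()) / d,
              (a.imag() * b.real() - a.real() * b.imag()) / d);
}

// D1_{1..ntop}(z) by downward recurrence
static void log_derivative(const cplx z, int ntop, std::vector<cplx>& D) {
  int nstart = std::max(ntop, (int)std::ceil(std::abs(z))) + 15;
  cplx Dn(0.0, 0.0);
  for (int n = nstart; n >= 2; --n) {
    cplx noz = (double)n / z;
    Dn = noz - cdiv(cplx(1.0, 0.0), Dn + noz);
    if (n - 1 <= ntop) D[n - 1] = Dn;
  }
}

// [[Rcpp::export(name = ".mie_homog_cpp")]]
List mie_homog_cpp(ComplexVector m, NumericVector x, IntegerVector ncut) {
  int L = x.size();
  int ntop = 0;
  for (int i = 0; i < L; ++i) ntop = std::max(ntop, ncut[i]);
  NumericVector qe(L), qs(L);
  std::vector<cplx> D(ntop + 1);
  for (int i = 0; i < L; ++i) {
    double xi = x[i];
    cplx mi(m[i].r, m[i].i);
    log_derivative(mi * xi, ncut[i], D);
    double psi_nm2 = std::cos(xi), psi_nm1 = std::sin(xi);
    double chi_nm2 = -std::sin(xi), chi_nm1 = std::cos(xi);
    double se = 0.0, ss = 0.0;
    for (int n = 1; n <= ncut[i]; ++n) {
      double psi_n = (2.0 * n - 1.0) / xi * psi_nm1 - psi_nm2;
      double chi_n = (2.0 * n - 1.0) / xi * chi_nm1 - chi_nm2;
      cplx xi_n(psi_n, -chi_n), xi_nm1(psi_nm1, -chi_nm1);
      cplx fa = cdiv(D[n], mi) + (double)n / xi;
      cplx fb = D[n] * mi + (double)n / xi;
      cplx a = cdiv(fa * psi_n - psi_nm1, fa * xi_n - xi_nm1);
      cplx b = cdiv(fb * psi_n - psi_nm1, fb * xi_n - xi_nm1);
      double w = 2.0 * n + 1.0;
      double ce = w * (a.real() + b.real());
      double cs = w * (std::norm(a) + std::norm(b));
      if (std::isfinite(ce) && std::isfinite(cs)) { se += ce; ss += cs; }
      psi_nm2 = psi_nm1; psi_nm1 = psi_n;
      chi_nm2 = chi_nm1; chi_nm1 = chi_n;
    }
    qe[i] = 2.0 / (xi * xi) * se;
    qs[i] = 2.0 / (xi * xi) * ss;
  }
  return List::create(Named("q_ext") = qe, Named("q_sca") = qs);
}

// [[Rcpp::export(name = ".mie_coated_cpp")]]
List mie_coated_cpp(ComplexVector m1v, ComplexVector m2v,
                    NumericVector x1, NumericVector x2, IntegerVector ncut) {
  int L = x2.size();
  int ntop = 0;
  for (int i = 0; i < L; ++i) ntop = std::max(ntop, ncut[i]);
  NumericVector qe(L), qs(L);
  std::vector<cplx> Dc(ntop + 1);
  for (int i = 0; i < L; ++i) {
    double y = x2[i];
    cplx m1(m1v[i].r, m1v[i].i), m2(m2v[i].r, m2v[i].i);
    cplx z21 = m2 * x1[i], z22 = m2 * y;
    cplx iz21 = cdiv(cplx(1.0,0.0), z21), iz22 = cdiv(cplx(1.0,0.0), z22);
    log_derivative(m1 * x1[i], ncut[i], Dc);
    // shell Riccati-Bessel at inner and outer walls, upward
    cplx p1_nm2 = std::cos(z21), p1_nm1 = std::sin(z21);
    cplx c1_nm2 = -std::sin(z21), c1_nm1 = std::cos(z21);
    cplx p2_nm2 = std::cos(z22), p2_nm1 = std::sin(z22);
    cplx c2_nm2 = -std::sin(z22), c2_nm1 = std::cos(z22);
    double py_nm2 = std::cos(y), py_nm1 = std::sin(y);
    double cy_nm2 = -std::sin(y), cy_nm1 = std::cos(y);
    double se = 0.0, ss = 0.0;
    for (int n = 1; n <= ncut[i]; ++n) {
      double tn = 2.0 * n - 1.0;
      cplx P1 = tn * iz21 * p1_nm1 - p1_nm2;
      cplx X1 = tn * iz21 * c1_nm1 - c1_nm2;
      cplx dP1 = p1_nm1 - (double)n * iz21 * P1;
      cplx dX1 = c1_nm1 - (double)n * iz21 * X1;
      cplx P2 = tn * iz22 * p2_nm1 - p2_nm2;
      cplx X2 = tn * iz22 * c2_nm1 - c2_nm2;
      cplx dP2 = p2_nm1 - (double)n * iz22 * P2;
      cplx dX2 = c2_nm1 - (double)n * iz22 * X2;
      double psi_n = tn / y * py_nm1 - py_nm2;
      double chi_n = tn / y * cy_nm1 - cy_nm2;
      double dpsi_n = py_nm1 - (double)n / y * psi_n;
      double dchi_n = cy_nm1 - (double)n / y * chi_n;
      cplx xi_n(psi_n, -chi_n), dxi_n(dpsi_n, -dchi_n);
      cplx rho_a = cdiv(m1 * dP1 - m2 * Dc[n] * P1, m2 * Dc[n] * X1 - m1 * dX1);
      cplx rho_b = cdiv(m1 * Dc[n] * P1 - m2 * dP1, m2 * dX1 - m1 * Dc[n] * X1);
      cplx Fa = P2 + rho_a * X2, dFa = dP2 + rho_a * dX2;
      cplx Fb = P2 + rho_b * X2, dFb = dP2 + rho_b * dX2;
      cplx a = cdiv(m2 * Fa * dpsi_n - dFa * psi_n, m2 * Fa * dxi_n - dFa * xi_n);
      cplx b = cdiv(Fb * dpsi_n - m2 * dFb * psi_n, Fb * dxi_n - m2 * dFb * xi_n);
      double w = 2.0 * n + 1.0;
      double ce = w * (a.real() + b.real());
      double cs = w * (std::norm(a) + std::norm(b));
      if (std::isfinite(ce) && std::isfinite(cs)) { se += ce; ss += cs; }
      p1_nm2 = p1_nm1; p1_nm1 = P1; c1_nm2 = c1_nm1; c1_nm1 = X1;
      p2_nm2 = p2_nm1; p2_nm1 = P2; c2_nm2 = c2_nm1; c2_nm1 = X2;
      py_nm2 = py_nm1; py_nm1 = psi_n; cy_nm2 = cy_nm1; cy_nm1 = chi_n;
    }
    qe[i] = 2.0 / (y * y) * se;
    qs[i] = 2.0 / (y * y) * ss;
  }
  return List::create(Named("q_ext") = qe, Named("q_sca") = qs);
}
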