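#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Implicit-Euler / fixed-point / FFT stepper for the two-species
// Gierer-Meinhardt system on an n x n torus.  The backward-Euler update
//   (v - h f(v) - h d_i L v) = v_old   (per species)
// is solved by the fixed-point iteration
//   v <- (I - h d_i L)^{-1} (v_old + h f(v)),
// where each linear solve is a pointwise division in Fourier space by the
// symbol 1 + h d (4 - 2 cos(2 pi k / n) - 2 cos(2 pi l / n)).
//
// Both species share one complex FFT per direction: the two real fields are
// packed as z = rhs1 + i rhs2, the spectra separated by Hermitian symmetry,
// divided by their symbols and repacked before the single inverse FFT.

static mat lap_symbol(int n, double hd) {
  mat s(n, n);
  for (int k = 0; k < n; ++k) {
    double ck = std::cos(2.0 * M_PI * k / n);
    for (int l = 0; l < n; ++l)
      s(k, l) = 1.0 + hd * (4.0 - 2.0 * ck - 2.0 * std::cos(2.0 * M_PI * l / n));
  }
  return s;
}

// z -> per-species symbol division using the packed-spectrum trick.
// With z = F(rhs1 + i rhs2) and zr = z at the reversed frequency, the two
// real spectra separate by Hermitian symmetry; both divisions are by real
// symbols, so everything reduces to real multiplications by 1/symbol.
static void packed_solve(const mat& rhs1, const mat& rhs2,
                         const mat& isym1, const mat& isym2,
                         const uvec& revlin, mat& out1, mat& out2) {
  const unsigned int n = rhs1.n_rows, m = n * n;
  cx_mat z = fft2(cx_mat(rhs1, rhs2));
  cx_mat w(n, n);
  const std::complex<double>* zp = z.memptr();
  std::complex<double>* wp = w.memptr();
  const double* s1 = isym1.memptr();
  const double* s2 = isym2.memptr();
  for (unsigned int p = 0; p < m; ++p) {
    const unsigned int q = revlin(p);
    const double x = zp[p].real(), y = zp[p].imag();
    const double xr = zp[q].real(), yr = zp[q].imag();
    wp[p] = std::complex<double>(
      0.5 * ((x + xr) * s1[p] + (x - xr) * s2[p]),
      0.5 * ((y - yr) * s1[p] + (y + yr) * s2[p]));
  }
  cx_mat back = ifft2(w);
  out1 = real(back);
  out2 = imag(back);
}

static inline void gm_rates(const mat& v1, const mat& v2,
                            double a, double b, double c, mat& f1, mat& f2) {
  f1 = a - b * v1 + square(v1) / (v2 % (1.0 + c * square(v1)));
  f2 = square(v1) - v2;
}

// 5-point torus Laplacian applied to a field (negative-definite convention:
// neighbour sum minus 4x, matching dv/dt = f(v) + d L v).
static mat torus_lap(const mat& x) {
  const int n = x.n_rows;
  uvec up(n), dn(n);
  for (int i = 0; i < n; ++i) { up(i) = (i + 1) % n; dn(i) = (i + n - 1) % n; }
  return x.rows(up) + x.rows(dn) + x.cols(up) + x.cols(dn) - 4.0 * x;
}

// [[Rcpp::export(name = ".gm_simulate_cpp")]]
Rcpp::List gm_simulate_cpp(arma::mat u1, arma::mat u2,
                           double a, double b, double c,
                           double d1, double d2,
                           double h, double eps_inner, double eps_outer,
                           double check_interval, double t_final,
                           int max_inner, double h_min) {
  const int n = u1.n_rows;
  uvec revlin(n * n);
  for (int l = 0; l < n; ++l) {
    const int lr = (n - l) % n;
    for (int k = 0; k < n; ++k)
      revlin(k + n * l) = ((n - k) % n) + n * lr;
  }

  mat isym1 = 1.0 / lap_symbol(n, h * d1), isym2 = 1.0 / lap_symbol(n, h * d2);
  double t = 0.0, next_check = check_interval;
  bool converged = false;
  int halvings = 0;

  mat v1, v2, f1, f2, n1, n2;
  while (t < t_final - 1e-12 && !converged) {
    // one implicit-Euler step, fixed point in (v1, v2)
    v1 = u1; v2 = u2;
    bool ok = false;
    for (int l = 0; l < max_inner; ++l) {
      gm_rates(v1, v2, a, b, c, f1, f2);
      packed_solve(u1 + h * f1, u2 + h * f2, isym1, isym2, revlin, n1, n2);
      if (!n1.is_finite() || !n2.is_finite()) break;
      const double num = std::sqrt(accu(square(n1 - v1)) + accu(square(n2 - v2)));
      const double den = std::sqrt(accu(square(v1)) + accu(square(v2)));
      v1 = n1; v2 = n2;
      if (num <= eps_inner * den) { ok = true; break; }
    }
    if (!ok) {
      // divergence signal: halve the step and retry from the same state
      h *= 0.5;
      ++halvings;
      if (h < h_min)
        Rcpp::stop("step size underflow after repeated halving (h = %g)", h);
      isym1 = 1.0 / lap_symbol(n, h * d1);
      isym2 = 1.0 / lap_symbol(n, h * d2);
      continue;
    }
    u1 = v1; u2 = v2; t += h;

    if (t >= next_check - 1e-12) {
      next_check += check_interval;
      gm_rates(u1, u2, a, b, c, f1, f2);
      const double res = std::max(abs(f1 + d1 * torus_lap(u1)).max(),
                                  abs(f2 + d2 * torus_lap(u2)).max());
      if (res <= eps_outer) converged = true;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("u1") = u1, Rcpp::Named("u2") = u2,
    Rcpp::Named("t_end") = t, Rcpp::Named("converged") = converged,
    Rcpp::Named("h_final") = h, Rcpp::Named("halvings") = halvings);
}
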