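// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Batched kinetic-scaling (method B) drift kernel used by the fitting
// objective, where one full symmetric eigendecomposition is needed per
// (participant, coherence) cell. K0 is the unit-spacing Matrix Numerov
// kinetic operator; the physical kinetic matrix is K0 / dx^2.
//
// For each coherence c and participant p:
//   H = (alpha_p / dx^2) K0 + diag(V_c)
//   psi(t) = exp(-i H t) psi0,  psi0 uniform (1/sqrt(n))
//   A[p, c] = lam * mean_t( sum_{right} |psi|^2 - sum_{left} |psi|^2 )
// with the sign flipped when the correct well is the left one.
// [[Rcpp::export]]
arma::mat drift_kernel_cpp(const arma::mat& K0,
                           double dx,
                           const arma::mat& V,
                           const arma::uvec& left_idx,
                           const arma::uvec& right_idx,
                           const arma::vec& alpha,
                           const arma::vec& times,
                           double lam,
                           bool correct_right) {
  const uword n = K0.n_rows;
  const uword C = V.n_cols;
  const uword P = alpha.n_elem;
  const uword T = times.n_elem;
  const double dx2 = dx * dx;

  vec psi0(n, fill::value(1.0 / std::sqrt((double) n)));
  mat out(P, C);

  for (uword c = 0; c < C; ++c) {
    for (uword p = 0; p < P; ++p) {
      mat H = (alpha(p) / dx2) * K0;
      H.diag() += V.col(c);
      vec ev;
      mat U;
      if (!eig_sym(ev, U, H, "dc"))
        Rcpp::stop("eigendecomposition failed in drift kernel");
      vec c0 = U.t() * psi0;
      double acc = 0.0;
      for (uword it = 0; it < T; ++it) {
        cx_vec phases = exp(cx_vec(zeros(n), -ev * times(it)));
        cx_vec psi = U * (phases % (cx_vec(c0, zeros(n))));
        vec prob = square(abs(psi));
        double pr = accu(prob.elem(right_idx));
        double pl = accu(prob.elem(left_idx));
        acc += correct_right ? (pr - pl) : (pl - pr);
      }
      out(p, c) = lam * acc / (double) T;
    }
  }
  return out;
}

// Euler-Maruyama first-passage simulation of the drift-diffusion process
//   dx = A dt + sqrt(d2) dW
// with absorbing boundaries at +z / -z, start x0. Uses R's RNG so results
// are reproducible under set.seed(). Returns per-path boundary (+1 upper,
// -1 lower, 0 unabsorbed within max_steps) and decision time.
//
// Plain Euler stepping has an O(sqrt(dt)) first-passage bias: a path can
// cross a boundary and return within one step. The standard diffusion-
// bridge correction removes it: given endpoints x_a, x_b inside the
// boundaries, the probability that the bridge touched +z in between is
// exp(-2 (z - x_a)(z - x_b) / (d2 dt)), and analogously for -z.
// [[Rcpp::export]]
Rcpp::List ddm_simulate_cpp(double A, double d2, double z, double x0,
                            int n_paths, double dt, int max_steps) {
  Rcpp::IntegerVector choice(n_paths);
  Rcpp::NumericVector dtime(n_paths);
  const double s = std::sqrt(d2 * dt);
  const double inv = 2.0 / (d2 * dt);
  for (int i = 0; i < n_paths; ++i) {
    double x = x0;
    int k = 0;
    int hit = 0;
    while (k < max_steps) {
      const double xa = x;
      x += A * dt + s * norm_rand();
      ++k;
      if (x >= z)  { hit = 1;  break; }
      if (x <= -z) { hit = -1; break; }
      const double p_up = std::exp(-inv * (z - xa) * (z - x));
      if (unif_rand() < p_up) { hit = 1; break; }
      const double p_dn = std::exp(-inv * (z + xa) * (z + x));
      if (unif_rand() < p_dn) { hit = -1; break; }
    }
    choice[i] = hit;
    dtime[i] = hit == 0 ? NA_REAL : k * dt;
  }
  return Rcpp::List::create(Rcpp::Named("choice") = choice,
                            Rcpp::Named("dt") = dtime);
}
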