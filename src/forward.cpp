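#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Neural state propagation for dx/dt = A x + C u with u piecewise constant
// on bins of width dt. Exact per bin: x_{k+1} = e^{A dt} x_k + A^{-1}(e^{A dt} - I) C u_k.
// Returns states on the grid t = 0, dt, ..., n*dt ((n+1) x R).
// [[Rcpp::export]]
Rcpp::List neural_states_cpp(const arma::mat& A, const arma::vec& C,
                             const arma::vec& u, double dt) {
  const int n = u.n_elem;
  const int R = A.n_rows;
  mat X(n + 1, R, fill::zeros);

  mat Ed = expmat(A * dt);
  mat M;
  if (!solve(M, A, Ed - eye(R, R))) {
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "singular A matrix",
                              Rcpp::Named("states") = X);
  }
  vec drive = M * C;
  vec x(R, fill::zeros);
  for (int k = 0; k < n; ++k) {
    x = Ed * x + drive * u[k];
    if (!x.is_finite() || arma::abs(x).max() > 1e6) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("reason") = "divergent neural trajectory",
                                Rcpp::Named("states") = X);
    }
    X.row(k + 1) = x.t();
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("reason") = "",
                            Rcpp::Named("states") = X);
}

struct HemoState { double s, f, v, q; };

static inline HemoState hemo_deriv(const HemoState& h, double x,
                                   double kappa, double tau, double gamma,
                                   double ialpha, double E0) {
  HemoState d;
  const double fv = std::pow(h.v, ialpha);   // outflow v^{1/alpha}
  d.s = x - kappa * h.s - gamma * (h.f - 1.0);
  d.f = h.s;
  d.v = (h.f - fv) / tau;
  d.q = (h.f * (1.0 - std::pow(1.0 - E0, 1.0 / h.f)) / E0 - fv * h.q / h.v) / tau;
  return d;
}

// Balloon-Windkessel hemodynamics driven by neural states X ((n+1) x R, grid
// t = 0..n*dt). RK4 per bin; neural drive at RK4 midpoints is the linear
// interpolant of the grid values. Returns BOLD on the same grid.
// [[Rcpp::export]]
Rcpp::List hemodynamics_cpp(const arma::mat& X, const arma::vec& kappa,
                            const arma::vec& tau, double gamma, double alpha,
                            double E0, double V0, double k1, double k2,
                            double k3, double dt) {
  const int n = X.n_rows - 1;
  const int R = X.n_cols;
  const double ialpha = 1.0 / alpha;
  mat Y(n + 1, R, fill::zeros);

  for (int r = 0; r < R; ++r) {
    HemoState h = {0.0, 1.0, 1.0, 1.0};
    for (int k = 0; k < n; ++k) {
      const double x0 = X(k, r), x1 = X(k + 1, r), xm = 0.5 * (x0 + x1);
      HemoState k1s = hemo_deriv(h, x0, kappa[r], tau[r], gamma, ialpha, E0);
      HemoState h2 = {h.s + 0.5 * dt * k1s.s, h.f + 0.5 * dt * k1s.f,
                      h.v + 0.5 * dt * k1s.v, h.q + 0.5 * dt * k1s.q};
      HemoState k2s = hemo_deriv(h2, xm, kappa[r], tau[r], gamma, ialpha, E0);
      HemoState h3 = {h.s + 0.5 * dt * k2s.s, h.f + 0.5 * dt * k2s.f,
                      h.v + 0.5 * dt * k2s.v, h.q + 0.5 * dt * k2s.q};
      HemoState k3s = hemo_deriv(h3, xm, kappa[r], tau[r], gamma, ialpha, E0);
      HemoState h4 = {h.s + dt * k3s.s, h.f + dt * k3s.f,
                      h.v + dt * k3s.v, h.q + dt * k3s.q};
      HemoState k4s = hemo_deriv(h4, x1, kappa[r], tau[r], gamma, ialpha, E0);
      h.s += dt / 6.0 * (k1s.s + 2 * k2s.s + 2 * k3s.s + k4s.s);
      h.f += dt / 6.0 * (k1s.f + 2 * k2s.f + 2 * k3s.f + k4s.f);
      h.v += dt / 6.0 * (k1s.v + 2 * k2s.v + 2 * k3s.v + k4s.v);
      h.q += dt / 6.0 * (k1s.q + 2 * k2s.q + 2 * k3s.q + k4s.q);
      if (!(h.f > 0.0) || !(h.v > 0.0) || !(h.q > 0.0) ||
          !std::isfinite(h.s + h.f + h.v + h.q)) {
        return Rcpp::List::create(
            Rcpp::Named("ok") = false,
            Rcpp::Named("reason") = "hemodynamic state left the positive domain",
            Rcpp::Named("bold") = Y);
      }
      Y(k + 1, r) = V0 * (k1 * (1.0 - h.q) + k2 * (1.0 - h.q / h.v) +
                          k3 * (1.0 - h.v));
    }
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("reason") = "",
                            Rcpp::Named("bold") = Y);
}
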