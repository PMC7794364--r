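// Artificial-centering hit-and-run walk over the flux polytope
// {v : S v = 0, lb <= v <= ub}. Directions are differences between a
// randomly chosen warmup point and the running center, projected onto an
// orthonormal basis N of null(S), so the equality constraints hold by
// construction; the step length is drawn uniformly on the feasible chord.
// Uses R's RNG so a set.seed() call on the R side makes runs bit-identical.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

//' @noRd
// [[Rcpp::export(name = ".achr_walk_cpp")]]
Rcpp::List achr_walk_cpp(const arma::mat &warmup,   // n x n_warmup columns
                         const arma::mat &Nbasis,   // n x k orthonormal null(S)
                         const arma::vec &lb, const arma::vec &ub,
                         arma::vec x, arma::vec center, double center_count,
                         int n_samples, int thinning, double tol) {
  const int n = x.n_elem;
  const int nw = warmup.n_cols;
  // coordinates pinned by their bounds can never move; rounding noise from
  // the running-center mean must not steer the chord there
  std::vector<bool> pinned(n);
  for (int i = 0; i < n; ++i) pinned[i] = (ub[i] - lb[i] <= 1e-9);
  mat out(n, n_samples);
  long degenerate = 0, clamped = 0;
  long step_no = 0;

  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thinning; ++t) {
      ++step_no;
      // direction: random warmup point minus running center, in null(S)
      vec d;
      double tmin = 0, tmax = 0;
      bool ok = false;
      for (int attempt = 0; attempt < 16 && !ok; ++attempt) {
        int idx = (int)std::floor(unif_rand() * nw);
        if (idx >= nw) idx = nw - 1;
        d = warmup.col(idx) - center;
        d = Nbasis * (Nbasis.t() * d);
        double nd = norm(d);
        // genuine directions join distinct feasible points; anything this
        // small is rounding noise and would normalize into garbage
        if (nd < 1e-8) continue;
        d /= nd;
        // feasible chord along d. Bound-pinned coordinates are excluded:
        // their direction components are rounding noise (directions are
        // differences of feasible points), and a 0/tiny ratio would
        // collapse the chord; the per-step drift they cause is ~1e-11 and
        // is removed by the clamp below.
        tmin = -datum::inf; tmax = datum::inf;
        for (int i = 0; i < n; ++i) {
          if (!pinned[i] && std::fabs(d[i]) > 1e-12) {
            double t1 = (lb[i] - x[i]) / d[i];
            double t2 = (ub[i] - x[i]) / d[i];
            if (d[i] > 0) { tmin = std::max(tmin, t1); tmax = std::min(tmax, t2); }
            else          { tmin = std::max(tmin, t2); tmax = std::min(tmax, t1); }
          }
        }
        if (std::isfinite(tmin) && std::isfinite(tmax) && tmax - tmin > 1e-12) ok = true;
      }
      if (ok) {
        double step = tmin + unif_rand() * (tmax - tmin);
        x += step * d;
      } else {
        ++degenerate;  // stay put; the chain still advances
      }
      // numerical housekeeping: clamp bound overshoot and re-project onto
      // null(S) every step. Clamping a coordinate moves x off the
      // steady-state plane; left uncorrected the error feeds back through
      // the running center and grows multiplicatively, so the projection
      // runs every step (one extra matvec pair) and keeps the residual at
      // machine precision.
      for (int i = 0; i < n; ++i) {
        if (x[i] < lb[i]) { if (lb[i] - x[i] > tol) ++clamped; x[i] = lb[i]; }
        if (x[i] > ub[i]) { if (x[i] - ub[i] > tol) ++clamped; x[i] = ub[i]; }
      }
      x = Nbasis * (Nbasis.t() * x);
      for (int i = 0; i < n; ++i) x[i] = std::min(std::max(x[i], lb[i]), ub[i]);
      center = (center * center_count + x) / (center_count + 1.0);
      center_count += 1.0;
    }
    out.col(s) = x;
  }
  return Rcpp::List::create(
    Rcpp::Named("samples") = out.t(),
    Rcpp::Named("degenerate_steps") = (double)degenerate,
    Rcpp::Named("clamped_steps") = (double)clamped);
}
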