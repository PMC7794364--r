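// Bounded-variable primal simplex for the small dense LPs that arise in
// flux balance / flux variability analysis:
//
//   max (or min)  c'x   s.t.  A x = b,  lb <= x <= ub
//
// Two-phase method with artificial variables; Dantzig pricing with a
// Bland's-rule fallback for anti-cycling. Upper bounds may be +Inf;
// every lower bound must be finite (the R wrapper guarantees this).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int AT_LB = 0, AT_UB = 1, BASIC = 2;

struct SimplexState {
  mat A;            // m x n (structural + slack + artificial columns)
  vec c, lb, ub, x;
  uvec basis;       // size m, column indices
  std::vector<int> stat;  // per-column status
  int m, n;
};

// one simplex phase; returns 0 optimal, 2 unbounded, 3 iteration limit
static int run_phase(SimplexState &S, int maxiter, double tol) {
  const int m = S.m, n = S.n;
  int bland_after = std::max(200, 20 * (m + n));
  for (int iter = 0; iter < maxiter; ++iter) {
    bool bland = iter > bland_after;
    mat B = S.A.cols(S.basis);
    vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = S.c[S.basis[i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 3;

    // pricing
    int q = -1; double best = tol; int sigma = 0;
    for (int j = 0; j < n; ++j) {
      if (S.stat[j] == BASIC) continue;
      double d = S.c[j] - dot(S.A.col(j), y);
      double viol = 0; int sg = 0;
      if (S.stat[j] == AT_LB && d > tol)  { viol = d;  sg = +1; }
      if (S.stat[j] == AT_UB && d < -tol) { viol = -d; sg = -1; }
      if (sg != 0) {
        if (bland) { q = j; sigma = sg; break; }
        if (viol > best) { best = viol; q = j; sigma = sg; }
      }
    }
    if (q < 0) return 0;  // optimal

    vec w;
    if (!solve(w, B, S.A.col(q), solve_opts::no_approx)) return 3;

    // ratio test: entering moves by t*sigma >= 0; basic values change by -sigma*t*w
    double tmax = datum::inf;
    int leave = -1, leave_to = AT_LB;
    double own_range = S.ub[q] - S.lb[q];  // may be inf
    if (own_range < tmax) { tmax = own_range; leave = -2; }
    for (int i = 0; i < m; ++i) {
      double wi = sigma * w[i];
      uword bi = S.basis[i];
      if (wi > tol) {               // basic var decreases toward its lb
        double t = (S.x[bi] - S.lb[bi]) / wi;
        if (t < tmax - 1e-12 || (bland && t <= tmax && leave < 0)) {
          tmax = std::max(t, 0.0); leave = i; leave_to = AT_LB;
        }
      } else if (wi < -tol) {       // basic var increases toward its ub
        if (!std::isfinite(S.ub[bi])) continue;
        double t = (S.x[bi] - S.ub[bi]) / wi;
        if (t < tmax - 1e-12 || (bland && t <= tmax && leave < 0)) {
          tmax = std::max(t, 0.0); leave = i; leave_to = AT_UB;
        }
      }
    }
    if (!std::isfinite(tmax)) return 2;  // unbounded

    // apply step
    for (int i = 0; i < m; ++i) S.x[S.basis[i]] -= sigma * tmax * w[i];
    S.x[q] += sigma * tmax;
    if (leave == -2) {
      S.stat[q] = (sigma > 0) ? AT_UB : AT_LB;      // bound flip, basis unchanged
      S.x[q] = (sigma > 0) ? S.ub[q] : S.lb[q];
    } else if (leave >= 0) {
      uword out = S.basis[leave];
      S.stat[out] = leave_to;
      S.x[out] = (leave_to == AT_LB) ? S.lb[out] : S.ub[out];
      S.basis[leave] = q;
      S.stat[q] = BASIC;
    } else {
      return 3;  // no blocking row found but tmax finite: numerical trouble
    }
  }
  return 3;
}

//' @noRd
// [[Rcpp::export(name = ".lp_simplex_cpp")]]
Rcpp::List lp_simplex_cpp(const arma::mat &A, const arma::vec &b,
                          const arma::vec &cc, const arma::vec &lb,
                          const arma::vec &ub, bool maximize,
                          int maxiter, double tol) {
  int m = A.n_rows, n0 = A.n_cols;
  SimplexState S;
  S.m = m; S.n = n0 + m;
  S.A = join_rows(A, eye(m, m));
  S.lb = join_cols(lb, zeros<vec>(m));
  S.ub = join_cols(ub, vec(m, fill::value(datum::inf)));
  S.x = zeros<vec>(S.n);
  S.stat.assign(S.n, AT_LB);
  S.basis.set_size(m);

  // start structural vars at a finite bound
  for (int j = 0; j < n0; ++j) {
    if (std::isfinite(S.lb[j])) { S.x[j] = S.lb[j]; S.stat[j] = AT_LB; }
    else if (std::isfinite(S.ub[j])) { S.x[j] = S.ub[j]; S.stat[j] = AT_UB; }
    else Rcpp::stop("free variables (both bounds infinite) are not supported");
  }
  vec r = b - A * S.x.head(n0);
  for (int i = 0; i < m; ++i) {
    int aj = n0 + i;
    if (r[i] < 0) S.A(i, aj) = -1.0;
    S.x[aj] = std::fabs(r[i]);
    S.basis[i] = aj;
    S.stat[aj] = BASIC;
  }

  // Phase 1: minimize sum of artificials
  S.c = join_cols(zeros<vec>(n0), -ones<vec>(m));
  int st = run_phase(S, maxiter, tol);
  double art = 0;
  for (int i = 0; i < m; ++i) art += S.x[n0 + i] > 0 ? S.x[n0 + i] : 0;
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  if (art > std::sqrt(tol))
    return Rcpp::List::create(Rcpp::Named("status") = 1);  // infeasible

  // pin artificials at zero so they never re-enter or move
  for (int i = 0; i < m; ++i) {
    S.ub[n0 + i] = 0.0;
    S.x[n0 + i] = std::max(0.0, std::min(S.x[n0 + i], 0.0));
    if (S.stat[n0 + i] != BASIC) { S.stat[n0 + i] = AT_LB; S.x[n0 + i] = 0; }
  }

  // Phase 2
  S.c = join_cols(maximize ? cc : vec(-cc), zeros<vec>(m));
  st = run_phase(S, maxiter, tol);
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  if (st == 2) return Rcpp::List::create(Rcpp::Named("status") = 2);

  vec x = S.x.head(n0);
  double obj = dot(cc, x);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj);
}
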