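// Bounded-variable two-phase primal simplex for the LP contract:
//
//   min c'x   s.t.   A x = b,   lb <= x <= ub
//
// Full-tableau implementation, dense arithmetic. Sized for the model scales
// this package targets (toy and mid-size stoichiometric systems, up to a few
// hundred variables); not intended for genome-scale matrices, where a sparse
// revised simplex or an external solver would be the right tool.
//
// Pivoting: Dantzig rule with a switch to Bland's rule after an iteration
// threshold so degenerate metabolic LPs cannot cycle. Ratio test allows
// nonbasic bound flips. Phase 1 starts from an all-artificial basis; the
// artificial columns are never allowed to re-enter.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BINF = std::numeric_limits<double>::infinity();

struct Tableau {
  mat T;       // m x N working tableau, N = n structural + m artificial
  vec xval;    // current value of every column variable
  uvec basis;  // basic column per row
  ivec state;  // 0 nonbasic at lb, 1 nonbasic at ub, 2 basic, 3 free at zero
  vec L, U;    // working bounds per column
  uword m, n, N;
};

// Run one simplex phase with costs cc; only columns < enter_limit may enter.
// Returns 0 at phase optimum, 2 if unbounded, 3 if iteration limit hit.
static int run_phase(Tableau& tb, const vec& cc, uword enter_limit,
                     double tol, int maxit, int& iter) {
  const uword m = tb.m;
  const int bland_after = 500 + 10 * static_cast<int>(tb.N);
  int local_iter = 0;

  while (iter < maxit) {
    ++iter; ++local_iter;
    // reduced costs d_j = c_j - y'A_j with y' = cB' T
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB[i] = cc[tb.basis[i]];
    rowvec y = cB.t() * tb.T;

    const bool bland = local_iter > bland_after;
    uword q = tb.N;
    int dirq = 0;
    double best = tol;
    for (uword j = 0; j < enter_limit; ++j) {
      if (tb.state[j] == 2) continue;
      if (tb.U[j] - tb.L[j] <= 0) continue;  // fixed variable
      const double d = cc[j] - y[j];
      int dir = 0; double viol = 0.0;
      if (tb.state[j] == 0 && d < -tol) { dir = 1; viol = -d; }
      else if (tb.state[j] == 1 && d > tol) { dir = -1; viol = d; }
      else if (tb.state[j] == 3 && std::fabs(d) > tol) {
        dir = (d < 0.0) ? 1 : -1; viol = std::fabs(d);
      }
      if (dir != 0) {
        if (bland) { q = j; dirq = dir; break; }
        if (viol > best) { best = viol; q = j; dirq = dir; }
      }
    }
    if (q == tb.N) return 0;  // phase optimal

    // ratio test; entering moves by t >= 0 in direction dirq
    vec col = tb.T.col(q);
    double tlim = tb.U[q] - tb.L[q];  // bound-flip limit (can be inf)
    sword leave = -1;
    double leave_to = 0.0, piv_sz = 0.0;
    for (uword i = 0; i < m; ++i) {
      const double delta = -static_cast<double>(dirq) * col[i];
      const uword bi = tb.basis[i];
      double lim = BINF, bnd = 0.0;
      if (delta < -tol) {
        if (tb.L[bi] > -BINF) { lim = (tb.xval[bi] - tb.L[bi]) / (-delta); bnd = tb.L[bi]; }
      } else if (delta > tol) {
        if (tb.U[bi] < BINF) { lim = (tb.U[bi] - tb.xval[bi]) / delta; bnd = tb.U[bi]; }
      }
      if (lim == BINF) continue;
      const double slack_tol =
        1e-9 * (1.0 + (std::isfinite(tlim) ? std::fabs(tlim) : 0.0));
      if (lim < tlim - slack_tol) {
        tlim = lim; leave = static_cast<sword>(i);
        leave_to = bnd; piv_sz = std::fabs(col[i]);
      } else if (leave >= 0 && lim <= tlim + slack_tol &&
                 std::fabs(col[i]) > piv_sz) {
        // tie: prefer the numerically larger pivot
        if (lim < tlim) tlim = lim;
        leave = static_cast<sword>(i);
        leave_to = bnd; piv_sz = std::fabs(col[i]);
      }
    }
    if (tlim == BINF) return 2;  // unbounded ray
    double t = tlim > 0.0 ? tlim : 0.0;

    // apply the step
    tb.xval[q] += dirq * t;
    for (uword i = 0; i < m; ++i)
      tb.xval[tb.basis[i]] += -static_cast<double>(dirq) * col[i] * t;

    if (leave < 0) {
      // pure bound flip
      tb.state[q] = (tb.state[q] == 0) ? 1 : 0;
      continue;
    }
    const uword p = static_cast<uword>(leave);
    const uword out = tb.basis[p];
    tb.xval[out] = leave_to;  // snap the leaving variable onto its bound
    if (tb.L[out] > -BINF && std::fabs(leave_to - tb.L[out]) <=
        std::fabs(leave_to - tb.U[out]))
      tb.state[out] = 0;
    else
      tb.state[out] = 1;

    const double piv = tb.T(p, q);
    tb.T.row(p) /= piv;
    vec cq = tb.T.col(q);
    cq[p] = 0.0;
    tb.T -= cq * tb.T.row(p);
    tb.basis[p] = q;
    tb.state[q] = 2;
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_bounded")]]
Rcpp::List simplex_bounded(const arma::mat& A, const arma::vec& b,
                           const arma::vec& c, const arma::vec& lb,
                           const arma::vec& ub,
                           double tol = 1e-9, int maxit = 50000) {
  const uword m = A.n_rows, n = A.n_cols;
  const uword N = n + m;

  Tableau tb;
  tb.m = m; tb.n = n; tb.N = N;
  tb.L.set_size(N); tb.U.set_size(N);
  tb.L.head(n) = lb; tb.U.head(n) = ub;
  tb.L.tail(m).zeros();
  tb.U.tail(m).fill(BINF);
  tb.state.set_size(N);
  tb.xval.zeros(N);

  // nonbasic start: each structural variable at its finite bound nearest zero
  for (uword j = 0; j < n; ++j) {
    const bool lf = std::isfinite(lb[j]), uf = std::isfinite(ub[j]);
    if (lf && uf) {
      if (std::fabs(lb[j]) <= std::fabs(ub[j])) { tb.xval[j] = lb[j]; tb.state[j] = 0; }
      else { tb.xval[j] = ub[j]; tb.state[j] = 1; }
    } else if (lf) { tb.xval[j] = lb[j]; tb.state[j] = 0; }
    else if (uf)   { tb.xval[j] = ub[j]; tb.state[j] = 1; }
    else           { tb.xval[j] = 0.0;   tb.state[j] = 3; }
  }

  vec r = b - A * tb.xval.head(n);
  tb.T.set_size(m, N);
  tb.T.cols(0, n - 1) = A;
  tb.T.cols(n, N - 1).zeros();
  tb.basis.set_size(m);
  for (uword i = 0; i < m; ++i) {
    if (r[i] < 0.0) tb.T.row(i) *= -1.0;
    tb.T(i, n + i) = 1.0;
    tb.basis[i] = n + i;
    tb.state[n + i] = 2;
    tb.xval[n + i] = std::fabs(r[i]);
  }

  int iter = 0;

  // phase 1: drive the artificials to zero
  vec c1 = join_cols(zeros<vec>(n), ones<vec>(m));
  int st = run_phase(tb, c1, n, tol, maxit, iter);
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("iterations") = iter);
  double infeas = 0.0;
  for (uword i = 0; i < m; ++i) infeas += tb.xval[n + i];
  if (infeas > 1e-7 * (1.0 + norm(b, "inf")))
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("iterations") = iter);
  // pin artificials so they cannot move again
  for (uword j = n; j < N; ++j) { tb.L[j] = 0.0; tb.U[j] = 0.0; }

  // phase 2
  vec c2 = join_cols(c, zeros<vec>(m));
  st = run_phase(tb, c2, n, tol, maxit, iter);
  if (st == 2)
    return Rcpp::List::create(Rcpp::Named("status") = 2,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("iterations") = iter);
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3,
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("iterations") = iter);

  vec x = tb.xval.head(n);
  // snap tiny bound violations left by finite-precision pivoting
  for (uword j = 0; j < n; ++j) {
    if (std::isfinite(lb[j]) && x[j] < lb[j]) x[j] = lb[j];
    if (std::isfinite(ub[j]) && x[j] > ub[j]) x[j] = ub[j];
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("objective") = dot(c, x),
                            Rcpp::Named("x") = x,
                            Rcpp::Named("iterations") = iter);
}
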