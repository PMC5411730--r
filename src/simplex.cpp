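// Bounded-variable two-phase primal simplex for dense LPs:
//   min c'x  s.t.  A x = b,  l <= x <= u  (l, u finite).
// Problem sizes here are small (tens of rows), so the basis system is
// re-factorised every iteration; Bland's rule kicks in after a run of
// degenerate pivots to rule out cycling.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double RC_TOL = 1e-9;     // reduced-cost optimality tolerance
const double PIV_TOL = 1e-10;   // pivot / ratio-test tolerance
const int DEGEN_LIMIT = 60;     // degenerate pivots before switching to Bland

struct SimplexResult {
  int status;   // 0 optimal, 1 infeasible, 2 iteration limit, 3 singular basis
  vec x;
  double obj;
};

// One simplex phase over the working problem (structurals + artificials).
// basis, stat are modified in place. stat: 0 basic, 1 at lower, 2 at upper.
int simplex_iterate(const mat& A, const vec& b, const vec& c,
                    const vec& l, const vec& u,
                    uvec& basis, ivec& stat, vec& x, int maxiter) {
  const uword m = A.n_rows, n = A.n_cols;
  int degen_run = 0;
  for (int iter = 0; iter < maxiter; ++iter) {
    mat AB = A.cols(basis);
    // basic values from nonbasic bounds
    vec rhs = b;
    for (uword j = 0; j < n; ++j) {
      if (stat(j) == 1) { x(j) = l(j); rhs -= A.col(j) * l(j); }
      else if (stat(j) == 2) { x(j) = u(j); rhs -= A.col(j) * u(j); }
    }
    vec xB;
    bool ok = solve(xB, AB, rhs, solve_opts::no_approx);
    if (!ok) return 3;
    for (uword k = 0; k < m; ++k) x(basis(k)) = xB(k);

    vec cB(m);
    for (uword k = 0; k < m; ++k) cB(k) = c(basis(k));
    vec y;
    ok = solve(y, AB.t(), cB, solve_opts::no_approx);
    if (!ok) return 3;

    // pricing
    bool bland = degen_run >= DEGEN_LIMIT;
    sword enter = -1;
    int dir = 0;
    double best = RC_TOL;
    for (uword j = 0; j < n; ++j) {
      if (stat(j) == 0) continue;
      double dj = c(j) - dot(y, A.col(j));
      if (stat(j) == 1 && dj < -RC_TOL) {
        if (bland) { enter = j; dir = 1; break; }
        if (-dj > best) { best = -dj; enter = j; dir = 1; }
      } else if (stat(j) == 2 && dj > RC_TOL) {
        if (bland) { enter = j; dir = -1; break; }
        if (dj > best) { best = dj; enter = j; dir = -1; }
      }
    }
    if (enter < 0) return 0;  // optimal

    vec w;
    ok = solve(w, AB, A.col((uword)enter), solve_opts::no_approx);
    if (!ok) return 3;

    // ratio test: entering moves by t in direction dir
    double tmax = u(enter) - l(enter);  // bound flip distance
    sword leave_pos = -1;               // position in basis, -1 => bound flip
    int leave_to = 0;                   // 1 -> lower, 2 -> upper
    double t = tmax;
    for (uword k = 0; k < m; ++k) {
      double delta = dir * w(k);
      uword i = basis(k);
      if (delta > PIV_TOL) {
        double tk = (x(i) - l(i)) / delta;
        if (tk < t - PIV_TOL || (tk < t + PIV_TOL && (leave_pos < 0 || i < basis(leave_pos)))) {
          if (tk < t) t = tk;
          if (t < 0) t = 0;
          leave_pos = k; leave_to = 1;
        }
      } else if (delta < -PIV_TOL) {
        double tk = (u(i) - x(i)) / (-delta);
        if (tk < t - PIV_TOL || (tk < t + PIV_TOL && (leave_pos < 0 || i < basis(leave_pos)))) {
          if (tk < t) t = tk;
          if (t < 0) t = 0;
          leave_pos = k; leave_to = 2;
        }
      }
    }
    if (leave_pos < 0 && !std::isfinite(tmax)) return 0; // cannot happen with finite bounds

    degen_run = (t <= PIV_TOL) ? degen_run + 1 : 0;

    if (leave_pos < 0) {
      // bound flip
      stat(enter) = (dir == 1) ? 2 : 1;
    } else {
      uword out = basis(leave_pos);
      basis(leave_pos) = (uword)enter;
      stat(out) = leave_to;
      stat(enter) = 0;
    }
  }
  return 2;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List simplex_lp(const arma::mat& A, const arma::vec& b,
                      const arma::vec& c, const arma::vec& l,
                      const arma::vec& u, int maxiter = 20000) {
  const uword m = A.n_rows, n = A.n_cols;

  // working problem: structurals 0..n-1, artificials n..n+m-1
  const uword N = n + m;
  mat W(m, N, fill::zeros);
  W.cols(0, n - 1) = A;
  vec r = b - A * l;
  for (uword i = 0; i < m; ++i) W(i, n + i) = (r(i) >= 0) ? 1.0 : -1.0;

  vec L(N), U(N);
  L.subvec(0, n - 1) = l; U.subvec(0, n - 1) = u;
  double art_cap = accu(abs(b)) + accu(abs(A) * abs(l)) + 1.0;
  for (uword i = 0; i < m; ++i) { L(n + i) = 0.0; U(n + i) = art_cap; }

  uvec basis(m);
  for (uword i = 0; i < m; ++i) basis(i) = n + i;
  ivec stat(N, fill::ones);  // everything at lower
  for (uword i = 0; i < m; ++i) stat(n + i) = 0;
  vec x(N, fill::zeros);

  // phase 1: minimise artificial mass
  vec c1(N, fill::zeros);
  for (uword i = 0; i < m; ++i) c1(n + i) = 1.0;
  int st = simplex_iterate(W, b, c1, L, U, basis, stat, x, maxiter);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = st,
                                         Rcpp::Named("x") = R_NilValue,
                                         Rcpp::Named("obj") = NA_REAL);
  double art_mass = 0;
  for (uword i = 0; i < m; ++i) art_mass += x(n + i);
  if (art_mass > 1e-9)
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("x") = R_NilValue,
                              Rcpp::Named("obj") = NA_REAL);

  // phase 2: pin artificials at zero, optimise the real objective
  for (uword i = 0; i < m; ++i) { L(n + i) = 0.0; U(n + i) = 0.0; }
  vec c2(N, fill::zeros);
  c2.subvec(0, n - 1) = c;
  st = simplex_iterate(W, b, c2, L, U, basis, stat, x, maxiter);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = st,
                                         Rcpp::Named("x") = R_NilValue,
                                         Rcpp::Named("obj") = NA_REAL);

  vec xs = x.subvec(0, n - 1);
  // clamp roundoff outside bounds
  for (uword j = 0; j < n; ++j) {
    if (xs(j) < l(j)) xs(j) = l(j);
    if (xs(j) > u(j)) xs(j) = u(j);
  }
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = xs,
                            Rcpp::Named("obj") = dot(c, xs));
}
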