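// Bounded-variable two-phase primal (revised) simplex.
//
// Solves   min c'x   s.t.  A x = b,  lb <= x <= ub
// with possibly infinite bounds.  Dense linear algebra via Armadillo; the
// basis system is re-factorised at every pivot, which is robust and cheap at
// the problem sizes constraint-based toy models produce (tens to a few
// hundred variables).  Dantzig pricing with a permanent switch to Bland's
// rule after a run of degenerate pivots guarantees termination.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const int NB_LOWER = 0;
static const int NB_UPPER = 1;
static const int NB_FREE = 2;
static const int IN_BASIS = 3;

// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
// [[Rcpp::export(name = ".simplex_core")]]
Rcpp::List simplex_core(const arma::mat& A0,
                        const arma::vec& b,
                        const arma::vec& c0,
                        const arma::vec& lb0,
                        const arma::vec& ub0,
                        int max_iter = 20000,
                        double tol = 1e-9) {
  const uword m = A0.n_rows;
  const uword n = A0.n_cols;
  const uword ntot = n + m;  // structural + artificial

  vec lb(ntot), ub(ntot), x(ntot, fill::zeros);
  ivec status(ntot);
  lb.subvec(0, n - 1) = lb0;
  ub.subvec(0, n - 1) = ub0;

  // structural variables start nonbasic at the finite bound nearer zero
  for (uword j = 0; j < n; ++j) {
    const bool lf = std::isfinite(lb(j)), uf = std::isfinite(ub(j));
    if (lf && uf) {
      if (std::abs(lb(j)) <= std::abs(ub(j))) { x(j) = lb(j); status(j) = NB_LOWER; }
      else { x(j) = ub(j); status(j) = NB_UPPER; }
    } else if (lf) { x(j) = lb(j); status(j) = NB_LOWER; }
    else if (uf) { x(j) = ub(j); status(j) = NB_UPPER; }
    else { x(j) = 0.0; status(j) = NB_FREE; }
  }

  // residual fixes artificial column signs so artificials start feasible >= 0
  vec r = b - A0 * x.subvec(0, n - 1);
  mat A(m, ntot, fill::zeros);
  A.cols(0, n - 1) = A0;
  for (uword i = 0; i < m; ++i) {
    const double s = (r(i) >= 0.0) ? 1.0 : -1.0;
    A(i, n + i) = s;
    x(n + i) = std::abs(r(i));
    lb(n + i) = 0.0;
    ub(n + i) = datum::inf;
    status(n + i) = IN_BASIS;
  }

  uvec basis(m);
  for (uword i = 0; i < m; ++i) basis(i) = n + i;

  vec cost(ntot, fill::zeros);  // phase 1: artificials cost 1
  cost.subvec(n, ntot - 1).fill(1.0);

  int phase = 1;
  int iter = 0;
  int degen_run = 0;
  bool bland = false;
  int lp_status = 0;

  auto refresh_basics = [&]() {
    // recompute basic values from nonbasic assignment to control drift
    vec rhs = b;
    for (uword j = 0; j < ntot; ++j)
      if (status(j) != IN_BASIS && x(j) != 0.0) rhs -= A.col(j) * x(j);
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
    vec xb = solve(B, rhs, solve_opts::fast);
    for (uword i = 0; i < m; ++i) x(basis(i)) = xb(i);
  };

  while (true) {
    if (iter >= max_iter) { lp_status = 3; break; }
    ++iter;
    if (iter % 64 == 0) refresh_basics();

    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB(i) = cost(basis(i));
    vec y;
    bool ok = solve(y, B.t(), cB, solve_opts::fast + solve_opts::no_approx);
    if (!ok) { refresh_basics(); y = solve(B.t(), cB); }

    // pricing
    sword q = -1;
    int dir = 0;
    double best = tol;
    for (uword j = 0; j < ntot; ++j) {
      if (status(j) == IN_BASIS) continue;
      if (phase == 2 && j >= n) continue;  // fixed artificials never re-enter
      const double dj = cost(j) - dot(y, A.col(j));
      int dj_dir = 0;
      double viol = 0.0;
      if (status(j) == NB_LOWER && dj < -tol) { dj_dir = 1; viol = -dj; }
      else if (status(j) == NB_UPPER && dj > tol) { dj_dir = -1; viol = dj; }
      else if (status(j) == NB_FREE && std::abs(dj) > tol) {
        dj_dir = dj < 0 ? 1 : -1; viol = std::abs(dj);
      }
      if (dj_dir == 0) continue;
      if (bland) { q = j; dir = dj_dir; break; }
      if (viol > best) { best = viol; q = j; dir = dj_dir; }
    }

    if (q < 0) {  // optimal for current phase
      if (phase == 1) {
        double art = 0.0;
        for (uword i = 0; i < m; ++i) art += x(n + i) > 0 ? x(n + i) : 0.0;
        double p1obj = 0.0;
        for (uword j = n; j < ntot; ++j) p1obj += x(j);
        if (p1obj > 1e-7) { lp_status = 1; break; }
        // pin artificials at zero and switch to the real objective
        for (uword j = n; j < ntot; ++j) { lb(j) = 0.0; ub(j) = 0.0; if (status(j) != IN_BASIS) x(j) = 0.0; }
        cost.zeros();
        cost.subvec(0, n - 1) = c0;
        phase = 2;
        bland = false;
        degen_run = 0;
        continue;
      }
      lp_status = 0;
      break;
    }

    vec w = solve(B, A.col(q), solve_opts::fast);

    // ratio test; entering variable moves by dir * t, basics by -dir * w * t
    double t_limit = datum::inf;
    sword leave = -1;       // basis position of leaving variable
    int leave_to = NB_LOWER;
    bool bound_flip = false;
    {
      const double span = ub(q) - lb(q);
      if (std::isfinite(span)) { t_limit = span; bound_flip = true; }
    }
    // pass 1: exact minimum blocking step
    vec ratio(m); ratio.fill(datum::inf);
    ivec ratio_to(m, fill::zeros);
    for (uword i = 0; i < m; ++i) {
      const double rho = -dir * w(i);  // change rate of basic i
      const uword bi = basis(i);
      if (rho < -tol) {
        if (std::isfinite(lb(bi))) {
          ratio(i) = std::max(0.0, (x(bi) - lb(bi)) / (-rho));
          ratio_to(i) = NB_LOWER;
        }
      } else if (rho > tol) {
        if (std::isfinite(ub(bi))) {
          ratio(i) = std::max(0.0, (ub(bi) - x(bi)) / rho);
          ratio_to(i) = NB_UPPER;
        }
      }
      if (ratio(i) < t_limit) { t_limit = ratio(i); bound_flip = false; }
    }
    // pass 2: among near-minimal blockers choose the largest pivot for
    // stability; the step taken stays the exact minimum
    if (!bound_flip && std::isfinite(t_limit)) {
      double best_pivot = -1.0;
      for (uword i = 0; i < m; ++i) {
        if (ratio(i) <= t_limit + 1e-9 && std::abs(w(i)) > best_pivot) {
          best_pivot = std::abs(w(i));
          leave = i;
          leave_to = ratio_to(i);
        }
      }
    }

    if (!std::isfinite(t_limit)) {
      if (phase == 1) { lp_status = 1; break; }  // cannot happen; guard
      lp_status = 2;
      break;
    }

    if (t_limit <= 1e-12) ++degen_run; else degen_run = 0;
    if (degen_run > 200) bland = true;

    // apply step
    x(q) += dir * t_limit;
    for (uword i = 0; i < m; ++i) x(basis(i)) += -dir * w(i) * t_limit;

    if (bound_flip || leave < 0) {
      status(q) = (dir > 0) ? NB_UPPER : NB_LOWER;
      x(q) = (dir > 0) ? ub(q) : lb(q);
    } else {
      const uword out = basis(leave);
      status(out) = leave_to;
      x(out) = (leave_to == NB_LOWER) ? lb(out) : ub(out);
      basis(leave) = (uword)q;
      status(q) = IN_BASIS;
    }
  }

  refresh_basics();
  vec xs = x.subvec(0, n - 1);
  const double obj = dot(c0, xs);
  return Rcpp::List::create(Rcpp::Named("status") = lp_status,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = xs,
                            Rcpp::Named("iterations") = iter);
}
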