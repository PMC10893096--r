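// Dense bounded-variable two-phase primal simplex.
//
// Solves   max c'x   s.t.  A x = b,  l <= x <= u   (all bounds finite).
// Sized for flux balance analysis on desk-scale metabolic models
// (tens of reactions); every iteration refactorizes, Bland's rule is
// used throughout so the highly degenerate b = 0 case terminates.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

namespace {

const int MAXIT = 50000;

struct SimplexProblem {
  arma::mat A;          // m x (n + m), artificials appended
  arma::vec b, cost, l, u;
  int m, n, ntot;
  std::vector<int> basis;   // length m, variable index of each basic slot
  std::vector<int> vstat;   // 0 at lower, 1 at upper, 2 basic
  double tol;
};

// One simplex phase on the current cost vector.
// status: 0 optimal, 2 iteration limit, 3 numerical failure.
int run_phase(SimplexProblem &P) {
  const int m = P.m, ntot = P.ntot;
  arma::vec x(ntot, arma::fill::zeros);
  for (int iter = 0; iter < MAXIT; ++iter) {
    // nonbasic values
    for (int j = 0; j < ntot; ++j) {
      if (P.vstat[j] == 0) x(j) = P.l(j);
      else if (P.vstat[j] == 1) x(j) = P.u(j);
    }
    // basic values: A_B x_B = b - A_N x_N
    arma::vec rhs = P.b;
    for (int j = 0; j < ntot; ++j)
      if (P.vstat[j] != 2 && x(j) != 0.0) rhs -= P.A.col(j) * x(j);
    arma::mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = P.A.col(P.basis[i]);
    arma::vec xB;
    if (!arma::solve(xB, B, rhs, arma::solve_opts::no_approx)) return 3;
    for (int i = 0; i < m; ++i) x(P.basis[i]) = xB(i);

    // duals and reduced costs; Bland entering rule
    arma::vec cB(m);
    for (int i = 0; i < m; ++i) cB(i) = P.cost(P.basis[i]);
    arma::vec y;
    if (!arma::solve(y, B.t(), cB, arma::solve_opts::no_approx)) return 3;
    int enter = -1;
    for (int j = 0; j < ntot; ++j) {
      if (P.vstat[j] == 2) continue;
      if (P.u(j) - P.l(j) < P.tol) continue;  // fixed variable
      double d = P.cost(j) - arma::dot(y, P.A.col(j));
      if ((P.vstat[j] == 0 && d > P.tol) || (P.vstat[j] == 1 && d < -P.tol)) {
        enter = j;
        break;
      }
    }
    if (enter < 0) return 0;  // optimal

    double dir = (P.vstat[enter] == 0) ? 1.0 : -1.0;
    arma::vec w;
    if (!arma::solve(w, B, arma::vec(P.A.col(enter)),
                     arma::solve_opts::no_approx)) return 3;

    // ratio test; t = movement of entering variable toward its other bound
    double tmax = P.u(enter) - P.l(enter);
    int leave = -1;  // -1 means bound flip
    for (int i = 0; i < m; ++i) {
      double coef = -dir * w(i);  // dx_basic_i = coef * t
      double t;
      int bi = P.basis[i];
      if (coef > P.tol) t = (P.u(bi) - x(bi)) / coef;
      else if (coef < -P.tol) t = (P.l(bi) - x(bi)) / coef;
      else continue;
      if (t < 0) t = 0;  // degeneracy / roundoff
      if (t < tmax - 1e-12) {
        tmax = t;
        leave = i;
      } else if (std::abs(t - tmax) <= 1e-12 && leave >= 0 &&
                 bi < P.basis[leave]) {
        leave = i;  // Bland tie-break on variable index
      }
    }
    if (leave < 0) {
      P.vstat[enter] = 1 - P.vstat[enter];  // bound flip
    } else {
      double coef = -dir * w(leave);
      int lv = P.basis[leave];
      P.vstat[lv] = (coef > 0) ? 1 : 0;  // hits the bound it moved toward
      P.basis[leave] = enter;
      P.vstat[enter] = 2;
    }
  }
  return 2;
}

}  // namespace

// status: 0 optimal, 1 infeasible, 2 iteration limit, 3 numerical failure
int lp_solve_core(const arma::mat &S, const arma::vec &b, const arma::vec &c,
                  const arma::vec &lb, const arma::vec &ub, double tol,
                  double &obj, arma::vec &xout) {
  const int m = S.n_rows, n = S.n_cols;
  SimplexProblem P;
  P.m = m;
  P.n = n;
  P.ntot = n + m;
  P.tol = tol;
  P.A = arma::join_rows(S, arma::eye(m, m));
  P.b = b;
  P.l.set_size(P.ntot);
  P.u.set_size(P.ntot);
  P.l.head(n) = lb;
  P.u.head(n) = ub;
  P.cost = arma::vec(P.ntot, arma::fill::zeros);
  P.vstat.assign(P.ntot, 0);
  for (int j = 0; j < n; ++j)
    P.vstat[j] = (std::abs(lb(j)) <= std::abs(ub(j))) ? 0 : 1;

  // artificial starting basis holding the residual of the nonbasic point
  arma::vec xN(n);
  for (int j = 0; j < n; ++j) xN(j) = (P.vstat[j] == 0) ? lb(j) : ub(j);
  arma::vec r = b - S * xN;
  P.basis.resize(m);
  for (int i = 0; i < m; ++i) {
    int j = n + i;
    P.basis[i] = j;
    P.vstat[j] = 2;
    P.l(j) = std::min(0.0, r(i));
    P.u(j) = std::max(0.0, r(i));
    P.cost(j) = (r(i) >= 0) ? -1.0 : 1.0;  // maximize -|artificial|
  }

  // phase 1: drive artificials to zero
  int st = run_phase(P);
  if (st != 0) return st;
  // evaluate artificial mass at the phase-1 optimum
  {
    arma::vec x(P.ntot, arma::fill::zeros);
    for (int j = 0; j < P.ntot; ++j) {
      if (P.vstat[j] == 0) x(j) = P.l(j);
      else if (P.vstat[j] == 1) x(j) = P.u(j);
    }
    arma::vec rhs = P.b;
    for (int j = 0; j < P.ntot; ++j)
      if (P.vstat[j] != 2 && x(j) != 0.0) rhs -= P.A.col(j) * x(j);
    arma::mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = P.A.col(P.basis[i]);
    arma::vec xB;
    if (!arma::solve(xB, B, rhs, arma::solve_opts::no_approx)) return 3;
    double art = 0;
    for (int i = 0; i < m; ++i)
      if (P.basis[i] >= n) art += std::abs(xB(i));
    for (int j = n; j < P.ntot; ++j) {
      if (P.vstat[j] == 0) art += std::abs(P.l(j));
      else if (P.vstat[j] == 1) art += std::abs(P.u(j));
    }
    if (art > 1e-7) return 1;  // infeasible
  }

  // phase 2: real objective, artificials pinned at zero
  for (int j = n; j < P.ntot; ++j) {
    P.l(j) = 0;
    P.u(j) = 0;
    P.cost(j) = 0;
    if (P.vstat[j] != 2) P.vstat[j] = 0;
  }
  P.cost.head(n) = c;
  st = run_phase(P);
  if (st != 0) return st;

  // recover solution
  arma::vec x(P.ntot, arma::fill::zeros);
  for (int j = 0; j < P.ntot; ++j) {
    if (P.vstat[j] == 0) x(j) = P.l(j);
    else if (P.vstat[j] == 1) x(j) = P.u(j);
  }
  arma::vec rhs = P.b;
  for (int j = 0; j < P.ntot; ++j)
    if (P.vstat[j] != 2 && x(j) != 0.0) rhs -= P.A.col(j) * x(j);
  arma::mat B(m, m);
  for (int i = 0; i < m; ++i) B.col(i) = P.A.col(P.basis[i]);
  arma::vec xB;
  if (!arma::solve(xB, B, rhs, arma::solve_opts::no_approx)) return 3;
  for (int i = 0; i < m; ++i) x(P.basis[i]) = xB(i);
  xout = x.head(n);
  obj = arma::dot(c, xout);
  return 0;
}

//' @noRd
// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::mat &S, const arma::vec &b,
                        const arma::vec &c, const arma::vec &lb,
                        const arma::vec &ub, double tol = 1e-9) {
  double obj = 0;
  arma::vec x;
  int st = lp_solve_core(S, b, c, lb, ub, tol, obj, x);
  if (st == 2) Rcpp::stop("simplex iteration limit reached");
  if (st == 3) Rcpp::stop("simplex numerical failure (singular basis)");
  if (st == 1)
    return Rcpp::List::create(Rcpp::Named("status") = "infeasible",
                              Rcpp::Named("objective") = NA_REAL,
                              Rcpp::Named("fluxes") = R_NilValue);
  return Rcpp::List::create(Rcpp::Named("status") = "optimal",
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("fluxes") = x);
}
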