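// Individual-based spatial community FBA stepping loop.
//
// One agent per grid cell; per step each agent (in seeded shuffled order)
// caps its exchange uptake by the local substrate amount, solves FBA,
// grows, exchanges metabolites with its cell, divides into a free
// 8-neighbor cell at 2*b0, moves with probability p_move; then every
// substrate field takes one explicit zero-flux Laplacian sweep.
// Uses R's RNG so set.seed() governs every stochastic choice.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]

int lp_solve_core(const arma::mat &S, const arma::vec &b, const arma::vec &c,
                  const arma::vec &lb, const arma::vec &ub, double tol,
                  double &obj, arma::vec &xout);

namespace {

struct SpeciesModel {
  arma::mat S;
  arma::vec lb, ub, obj;
  std::vector<int> ex_rxn;  // 0-based reaction index of each exchange
  std::vector<int> ex_met;  // 0-based global metabolite index
  struct CachedSol {
    double mu;
    std::vector<double> flux;
    bool feasible;
  };
  // LP cache keyed on the effective exchange lower bounds
  std::map<std::vector<double>, CachedSol> cache;
};

inline int runif_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)std::floor(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

void shuffle_idx(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".arena_run_cpp")]]
Rcpp::List arena_run_cpp(Rcpp::List models, Rcpp::IntegerVector agent_species,
                         Rcpp::NumericVector agent_biomass,
                         Rcpp::IntegerVector agent_cell, arma::mat substrate,
                         int rows, int cols, int steps, double dt, double b0,
                         double p_move, arma::vec alpha, double lptol) {
  Rcpp::RNGScope rng;
  const int ncell = rows * cols;
  const int nmet = substrate.n_cols;
  const int nspecies = models.size();

  std::vector<SpeciesModel> mod(nspecies);
  for (int s = 0; s < nspecies; ++s) {
    Rcpp::List m = models[s];
    mod[s].S = Rcpp::as<arma::mat>(m["S"]);
    mod[s].lb = Rcpp::as<arma::vec>(m["lb"]);
    mod[s].ub = Rcpp::as<arma::vec>(m["ub"]);
    mod[s].obj = Rcpp::as<arma::vec>(m["obj"]);
    Rcpp::IntegerVector er = m["ex_rxn"], em = m["ex_met"];
    for (int k = 0; k < er.size(); ++k) {
      mod[s].ex_rxn.push_back(er[k] - 1);
      mod[s].ex_met.push_back(em[k] - 1);
    }
  }

  std::vector<int> species(agent_species.begin(), agent_species.end());
  for (size_t i = 0; i < species.size(); ++i) species[i] -= 1;
  std::vector<double> biomass(agent_biomass.begin(), agent_biomass.end());
  std::vector<int> cell(agent_cell.begin(), agent_cell.end());
  for (size_t i = 0; i < cell.size(); ++i) cell[i] -= 1;

  std::vector<int> occ(ncell, -1);
  for (size_t i = 0; i < cell.size(); ++i) occ[cell[i]] = (int)i;

  arma::mat counts(steps + 1, nspecies, arma::fill::zeros);
  for (size_t i = 0; i < species.size(); ++i) counts(0, species[i]) += 1;
  arma::mat secretion(nspecies, nmet, arma::fill::zeros);
  arma::mat uptake(nspecies, nmet, arma::fill::zeros);
  arma::mat flux_delta(steps, nmet, arma::fill::zeros);   // sum flux*biomass*dt
  arma::mat env_pre_diff(steps, nmet, arma::fill::zeros); // totals before diffusion
  arma::mat env_post(steps, nmet, arma::fill::zeros);     // totals after diffusion
  arma::rowvec env0 = arma::sum(substrate, 0);
  double clamp_total = 0;
  int n_infeasible = 0;

  std::vector<int> nb;
  nb.reserve(8);
  // cell index is column-major (r + c*rows), matching R matrix layout
  auto free_neighbors = [&](int c0, std::vector<int> &out) {
    out.clear();
    int r = c0 % rows, cc = c0 / rows;
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int r2 = r + dr, c2 = cc + dc;
        if (r2 < 0 || r2 >= rows || c2 < 0 || c2 >= cols) continue;
        int idx = r2 + c2 * rows;
        if (occ[idx] < 0) out.push_back(idx);
      }
  };

  arma::mat lap(rows, cols);

  for (int t = 0; t < steps; ++t) {
    int n0 = (int)species.size();
    std::vector<int> order(n0);
    for (int i = 0; i < n0; ++i) order[i] = i;
    shuffle_idx(order);

    // growth and exchange
    for (int oi = 0; oi < n0; ++oi) {
      int a = order[oi];
      SpeciesModel &M = mod[species[a]];
      int c0 = cell[a];
      double bm = biomass[a];
      size_t nex = M.ex_rxn.size();
      std::vector<double> elb(nex);
      for (size_t k = 0; k < nex; ++k) {
        double avail = substrate(c0, M.ex_met[k]);
        double cap = avail / (bm * dt);
        double lo = M.lb(M.ex_rxn[k]);
        if (-cap > lo) lo = -cap;
        double hi = M.ub(M.ex_rxn[k]);
        if (lo > hi) lo = hi;
        elb[k] = lo;
      }
      double mu = 0;
      const std::vector<double> *exflux = NULL;
      auto hit = M.cache.find(elb);
      if (hit == M.cache.end()) {
        arma::vec lb2 = M.lb;
        for (size_t k = 0; k < nex; ++k) lb2(M.ex_rxn[k]) = elb[k];
        double obj = 0;
        arma::vec x;
        arma::vec zero(M.S.n_rows, arma::fill::zeros);
        int st = lp_solve_core(M.S, zero, M.obj, lb2, M.ub, lptol, obj, x);
        SpeciesModel::CachedSol sol;
        sol.flux.assign(nex, 0.0);
        sol.feasible = (st == 0);
        sol.mu = 0;
        if (st == 0) {
          sol.mu = obj > 0 ? obj : 0;
          for (size_t k = 0; k < nex; ++k) sol.flux[k] = x(M.ex_rxn[k]);
        }
        hit = M.cache.insert(std::make_pair(elb, sol)).first;
      }
      mu = hit->second.mu;
      exflux = &hit->second.flux;
      if (!hit->second.feasible) ++n_infeasible;  // per agent occurrence
      if (exflux) {
        for (size_t k = 0; k < nex; ++k) {
          double amt = (*exflux)[k] * bm * dt;
          if (amt == 0) continue;
          int g = M.ex_met[k];
          double v = substrate(c0, g) + amt;
          if (v < 0) {  // solver-tolerance overshoot only
            clamp_total += -v;
            v = 0;
          }
          substrate(c0, g) = v;
          flux_delta(t, g) += amt;
          if (amt > 0) secretion(species[a], g) += amt;
          else uptake(species[a], g) -= amt;
        }
      }
      biomass[a] = bm * (1.0 + mu * dt);
    }

    // division
    for (int oi = 0; oi < n0; ++oi) {
      int a = order[oi];
      if (biomass[a] >= 2.0 * b0) {
        free_neighbors(cell[a], nb);
        if (!nb.empty()) {
          int dest = nb[runif_int((int)nb.size())];
          double half = biomass[a] / 2.0;
          biomass[a] = half;
          species.push_back(species[a]);
          biomass.push_back(half);
          cell.push_back(dest);
          occ[dest] = (int)species.size() - 1;
        }
      }
    }

    // movement (agents present at step start)
    for (int oi = 0; oi < n0; ++oi) {
      int a = order[oi];
      if (p_move <= 0) break;
      if (unif_rand() < p_move) {
        free_neighbors(cell[a], nb);
        if (!nb.empty()) {
          int dest = nb[runif_int((int)nb.size())];
          occ[cell[a]] = -1;
          occ[dest] = a;
          cell[a] = dest;
        }
      }
    }

    env_pre_diff.row(t) = arma::sum(substrate, 0);

    // diffusion: one explicit 4-neighbor Laplacian sweep, zero-flux borders
    for (int g = 0; g < nmet; ++g) {
      if (alpha(g) <= 0) continue;
      arma::mat u(substrate.colptr(g), rows, cols, false, true);
      // u is column-major rows x cols view of the field
      lap.zeros();
      for (int cc = 0; cc < cols; ++cc)
        for (int r = 0; r < rows; ++r) {
          double ui = u(r, cc);
          if (r > 0) lap(r, cc) += u(r - 1, cc) - ui;
          if (r < rows - 1) lap(r, cc) += u(r + 1, cc) - ui;
          if (cc > 0) lap(r, cc) += u(r, cc - 1) - ui;
          if (cc < cols - 1) lap(r, cc) += u(r, cc + 1) - ui;
        }
      u += alpha(g) * lap;
    }
    env_post.row(t) = arma::sum(substrate, 0);

    for (size_t i = 0; i < species.size(); ++i) counts(t + 1, species[i]) += 1;
  }

  Rcpp::IntegerVector out_species(species.size()), out_cell(cell.size());
  for (size_t i = 0; i < species.size(); ++i) {
    out_species[i] = species[i] + 1;
    out_cell[i] = cell[i] + 1;
  }
  return Rcpp::List::create(
      Rcpp::Named("substrate") = substrate,
      Rcpp::Named("species") = out_species,
      Rcpp::Named("biomass") = Rcpp::NumericVector(biomass.begin(), biomass.end()),
      Rcpp::Named("cell") = out_cell,
      Rcpp::Named("counts") = counts,
      Rcpp::Named("secretion") = secretion,
      Rcpp::Named("uptake") = uptake,
      Rcpp::Named("flux_delta") = flux_delta,
      Rcpp::Named("env_pre_diff") = env_pre_diff,
      Rcpp::Named("env_post") = env_post,
      Rcpp::Named("env0") = env0,
      Rcpp::Named("clamp_total") = clamp_total,
      Rcpp::Named("n_infeasible") = n_infeasible);
}
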