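// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Relaxation onto { S v >= 0 (internal species rows), S v = 0 (intake rows),
// lb <= v <= ub, pinned components fixed }.
//
// Base scheme is Agmon-Motzkin-Schoenberg: select the most violated species
// row, move v along the row normal restricted to free (non-pinned)
// components by step * violation / ||row||^2, re-clip moved components to
// their bounds. Nearly parallel constraint rows (conserved-moiety pairs,
// long transport chains) make the pure scheme zigzag, so the kernel
// periodically applies a joint minimum-norm correction: all currently
// violated rows are driven to zero residual while currently tight rows are
// held tight (the move stays within the active face), with an inner
// active-set loop holding components that hit their bounds. The final
// residual is always recomputed exactly before reporting feasibility.

// [[Rcpp::export]]
List relax_kernel(const arma::mat& S, IntegerVector row_type,
                  NumericVector lb, NumericVector ub,
                  IntegerVector pinned, const arma::mat& nu0,
                  double step, double eps, int max_iter) {
  const int M = S.n_rows, N = S.n_cols, K = nu0.n_rows;
  const int block = 50;

  std::vector<bool> is_pinned(N, false);
  for (int i = 0; i < pinned.size(); ++i) is_pinned[pinned[i]] = true;

  // S with pinned columns zeroed: normals restricted to free components
  arma::mat Sf = S;
  for (int j = 0; j < N; ++j) if (is_pinned[j]) Sf.col(j).zeros();

  std::vector<std::vector<int>> rows(M), cols(N);
  arma::vec norm2(M, arma::fill::zeros);
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < N; ++j)
      if (Sf(m, j) != 0.0) {
        rows[m].push_back(j);
        cols[j].push_back(m);
        norm2[m] += Sf(m, j) * Sf(m, j);
      }
  const arma::mat Gfull = Sf * Sf.t();   // row Gram matrix, computed once

  arma::mat out(K, N);
  IntegerVector iters(K);
  NumericVector maxviol(K);
  LogicalVector converged(K);

  arma::vec v(N), p(M);

  for (int k = 0; k < K; ++k) {
    v = nu0.row(k).t();
    p = S * v;

    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      int r = -1;
      double worst = 0.0;
      for (int m = 0; m < M; ++m) {
        double viol = (row_type[m] == 1) ? std::fabs(p[m]) : -p[m];
        if (viol > worst) { worst = viol; r = m; }
      }
      if (worst <= eps) break;
      if (r < 0 || norm2[r] <= 0.0) break;   // unfixable given the pins

      if (worst < 1e-3 || (it + 1) % block == 0) {
        // violated rows first, then tight rows to be held tight
        std::vector<int> vid;
        for (int m = 0; m < M; ++m) {
          if (norm2[m] <= 0.0) continue;
          bool bad = (row_type[m] == 1) ? (std::fabs(p[m]) > eps * 0.5)
                                        : (p[m] < -eps * 0.5);
          if (bad) vid.push_back(m);
        }
        const size_t n_bad = vid.size();
        for (int m = 0; m < M; ++m) {
          if (norm2[m] <= 0.0 || std::fabs(p[m]) > 1e3 * eps) continue;
          bool dup = false;
          for (size_t a = 0; a < n_bad; ++a)
            if (vid[a] == m) { dup = true; break; }
          if (!dup) vid.push_back(m);
        }
        if (n_bad > 0) {
          const size_t nv = vid.size();
          arma::uvec uvid(nv);
          for (size_t a = 0; a < nv; ++a) uvid[a] = vid[a];
          arma::vec rhs0(nv, arma::fill::zeros);
          for (size_t a = 0; a < n_bad; ++a) rhs0[a] = -p[vid[a]];

          arma::mat G = Gfull.submat(uvid, uvid);
          std::vector<bool> at_bound(N, false);
          arma::vec dv(N, arma::fill::zeros);
          for (int pass = 0; pass < 8; ++pass) {
            // rhs accounting for moves already fixed at bounds
            arma::vec rhs = rhs0;
            for (int j = 0; j < N; ++j)
              if (dv[j] != 0.0 && at_bound[j])
                for (size_t a = 0; a < nv; ++a)
                  rhs[a] -= Sf(vid[a], j) * dv[j];
            arma::mat Greg = G;
            Greg.diag() += 1e-12 * (1.0 + Greg.diag().max());
            arma::vec y;
            if (!arma::solve(y, Greg, rhs, arma::solve_opts::likely_sympd))
              break;
            // d = Sf[vid,:]' y over free, unfixed components
            arma::vec d(N, arma::fill::zeros);
            for (size_t a = 0; a < nv; ++a) {
              const std::vector<int>& sup = rows[vid[a]];
              for (size_t b = 0; b < sup.size(); ++b)
                d[sup[b]] += Sf(vid[a], sup[b]) * y[a];
            }
            std::vector<int> newly_fixed;
            for (int j = 0; j < N; ++j) {
              if (is_pinned[j] || at_bound[j] || d[j] == 0.0) continue;
              double nv_ = v[j] + dv[j] + d[j];
              if (nv_ < lb[j]) {
                dv[j] = lb[j] - v[j]; at_bound[j] = true; newly_fixed.push_back(j);
              } else if (nv_ > ub[j]) {
                dv[j] = ub[j] - v[j]; at_bound[j] = true; newly_fixed.push_back(j);
              } else dv[j] = d[j];   // full correction, replaced each pass
            }
            if (newly_fixed.empty()) break;
            // remove newly fixed columns from the Gram submatrix (once each)
            for (size_t c = 0; c < newly_fixed.size(); ++c) {
              int j = newly_fixed[c];
              for (size_t a = 0; a < nv; ++a) {
                double sa = Sf(vid[a], j);
                if (sa == 0.0) continue;
                for (size_t b = 0; b < nv; ++b) {
                  double sb = Sf(vid[b], j);
                  if (sb != 0.0) G(a, b) -= sa * sb;
                }
              }
            }
            // bound-fixed moves keep their assigned values; free moves are
            // recomputed from scratch on the next pass
            for (int j = 0; j < N; ++j)
              if (!at_bound[j]) dv[j] = 0.0;
          }
          for (int j = 0; j < N; ++j) {
            if (is_pinned[j] || dv[j] == 0.0) continue;
            double nv_ = v[j] + dv[j];
            if (nv_ < lb[j]) nv_ = lb[j];
            if (nv_ > ub[j]) nv_ = ub[j];
            v[j] = nv_;
          }
          p = S * v;
          continue;
        }
      }

      double delta = step * (-p[r]) / norm2[r];
      const std::vector<int>& sup = rows[r];
      for (size_t a = 0; a < sup.size(); ++a) {
        int j = sup[a];
        double nv_ = v[j] + delta * Sf(r, j);
        if (nv_ < lb[j]) nv_ = lb[j];
        if (nv_ > ub[j]) nv_ = ub[j];
        double d = nv_ - v[j];
        if (d != 0.0) {
          p += d * S.col(j);
          v[j] = nv_;
        }
      }

      if ((it & 0x03FF) == 0x03FF) p = S * v;   // periodic exact refresh
    }

    p = S * v;                                   // exact final residual
    double worst = 0.0;
    for (int m = 0; m < M; ++m) {
      double viol = (row_type[m] == 1) ? std::fabs(p[m]) : -p[m];
      if (viol > worst) worst = viol;
    }

    out.row(k) = v.t();
    iters[k] = it;
    maxviol[k] = worst;
    converged[k] = (worst <= eps);
    if ((k & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["nu"] = wrap(out), _["iterations"] = iters,
                      _["max_violation"] = maxviol,
                      _["converged"] = converged);
}
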