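// Numerical core for simplex-constrained least squares and the alternating
// archetype fit.
//
// All solvers work on Gram matrices, so the per-field cost is independent of
// the grid size once the cross-products are formed (by BLAS). The simplex
// projection min ||B'w - t||^2 s.t. w >= 0, sum(w) = 1 is solved by
// Lawson-Hanson NNLS on the system augmented with a constant row of
// magnitude M (the classical sum-to-one device) to discover the active set,
// followed by an exact equality-constrained refit on the support, so the
// returned weights solve the constrained problem to solver precision and
// sum to one exactly. The augmented quantities are never materialised:
// with G = B B', h = B t, the augmented Gram/rhs are G + M^2 and h + M^2,
// so gradients only need the running sum of w.
//
// Hot loops use raw buffers and a hand-rolled small Cholesky; the
// alternating fit warm-starts each projection from the previous iteration's
// support and accepts it only when the full KKT conditions verify.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Workspace {
  std::vector<double> A;    // packed SPD system, s x s col-major
  std::vector<double> b1;   // rhs / solution buffers
  std::vector<double> b2;
  std::vector<double> w;    // candidate weights on the support
  std::vector<double> gw;   // G w (full length m)
  std::vector<int> sup;     // scratch support
};

// In-place Cholesky factorisation + solve for one or two right-hand sides.
// a holds the SPD matrix (col-major, s x s); b1 (and b2 when s2 is true)
// are overwritten with the solutions. Returns false when not PD.
bool chol_solve(std::vector<double>& a, int s, std::vector<double>& b1,
                std::vector<double>* b2) {
  for (int j = 0; j < s; ++j) {
    double d = a[j + j * s];
    for (int k = 0; k < j; ++k) d -= a[j + k * s] * a[j + k * s];
    if (d <= 1e-300) return false;
    d = std::sqrt(d);
    a[j + j * s] = d;
    for (int i = j + 1; i < s; ++i) {
      double v = a[i + j * s];
      for (int k = 0; k < j; ++k) v -= a[i + k * s] * a[j + k * s];
      a[i + j * s] = v / d;
    }
  }
  auto tri_solve = [&](std::vector<double>& b) {
    for (int i = 0; i < s; ++i) {
      double v = b[i];
      for (int k = 0; k < i; ++k) v -= a[i + k * s] * b[k];
      b[i] = v / a[i + i * s];
    }
    for (int i = s - 1; i >= 0; --i) {
      double v = b[i];
      for (int k = i + 1; k < s; ++k) v -= a[k + i * s] * b[k];
      b[i] = v / a[i + i * s];
    }
  };
  tri_solve(b1);
  if (b2) tri_solve(*b2);
  return true;
}

// Equality-constrained refit on a support S (indices into 0..m-1):
//   min ||B_S' w - t||^2  s.t. sum(w) = 1
// solved through the Schur complement of the KKT system:
//   w = G_SS^{-1}(h_S - l * 1),  l = (1' G^{-1} h - 1) / (1' G^{-1} 1).
// Fills ws.w (length |S|) and returns the multiplier via *lambda2.
// Returns false when G_SS is numerically singular.
bool refit_support(const double* G, const double* h, int m,
                   const std::vector<int>& S, Workspace& ws,
                   double* lambda2) {
  const int s = static_cast<int>(S.size());
  ws.A.resize(static_cast<size_t>(s) * s);
  ws.b1.resize(s);
  ws.b2.resize(s);
  for (int a = 0; a < s; ++a) {
    const double* col = G + static_cast<size_t>(S[a]) * m;
    for (int b = 0; b < s; ++b) ws.A[b + a * s] = col[S[b]];
    ws.b1[a] = h[S[a]];
    ws.b2[a] = 1.0;
  }
  if (!chol_solve(ws.A, s, ws.b1, &ws.b2)) return false;
  double sa = 0, sb = 0;
  for (int a = 0; a < s; ++a) { sa += ws.b1[a]; sb += ws.b2[a]; }
  if (sb <= 0) return false;
  const double l2 = (sa - 1.0) / sb;
  ws.w.resize(s);
  for (int a = 0; a < s; ++a) ws.w[a] = ws.b1[a] - l2 * ws.b2[a];
  *lambda2 = l2;
  return true;
}

// Lawson-Hanson NNLS on the M-augmented system, Gram form, augmented
// quantities computed on the fly. On exit `support` holds the passive set
// and ws.gw the weights as a full-length vector.
void nnls_augmented(const double* G, const double* h, int m, double M2,
                    Workspace& ws, std::vector<int>& support,
                    std::vector<double>& wfull) {
  wfull.assign(m, 0.0);
  support.clear();
  std::vector<char> passive(m, 0);
  double scale = 1.0;
  for (int j = 0; j < m; ++j) scale = std::max(scale, std::fabs(h[j]) + M2);
  const double tol = 1e-11 * scale;
  const int outer_max = 3 * m + 60;
  ws.gw.assign(m, 0.0); // G w, maintained sparsely
  double wsum = 0.0;

  for (int it = 0; it < outer_max; ++it) {
    // augmented gradient: (h - Gw) + M^2 (1 - sum w)
    const double aug = M2 * (1.0 - wsum);
    int bi = -1;
    double best = tol;
    for (int j = 0; j < m; ++j) {
      if (passive[j]) continue;
      const double g = h[j] - ws.gw[j] + aug;
      if (g > best) { best = g; bi = j; }
    }
    if (bi < 0) break;
    passive[bi] = 1;
    support.push_back(bi);

    for (;;) {
      const int s = static_cast<int>(support.size());
      ws.A.resize(static_cast<size_t>(s) * s);
      ws.b1.resize(s);
      for (int a = 0; a < s; ++a) {
        const double* col = G + static_cast<size_t>(support[a]) * m;
        for (int b = 0; b < s; ++b)
          ws.A[b + a * s] = col[support[b]] + M2;
        ws.b1[a] = h[support[a]] + M2;
      }
      bool ok = chol_solve(ws.A, s, ws.b1, nullptr);
      if (!ok) {
        // degenerate (duplicate rows): nudge the diagonal
        for (int a = 0; a < s; ++a) {
          const double* col = G + static_cast<size_t>(support[a]) * m;
          for (int b = 0; b < s; ++b)
            ws.A[b + a * s] = col[support[b]] + M2;
          ws.A[a + a * s] *= 1.0 + 1e-10;
          ws.b1[a] = h[support[a]] + M2;
        }
        if (!chol_solve(ws.A, s, ws.b1, nullptr)) { ws.b1.assign(s, 0.0); }
      }
      bool feas = true;
      for (int a = 0; a < s; ++a) if (ws.b1[a] <= 0) { feas = false; break; }
      if (feas) {
        for (int a = 0; a < s; ++a) wfull[support[a]] = ws.b1[a];
        break;
      }
      double alpha = std::numeric_limits<double>::infinity();
      for (int a = 0; a < s; ++a) {
        if (ws.b1[a] <= 0) {
          const double cur = wfull[support[a]];
          const double den = cur - ws.b1[a];
          const double st = den > 0 ? cur / den : 0.0;
          if (st < alpha) alpha = st;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      std::vector<int> kept;
      kept.reserve(s);
      for (int a = 0; a < s; ++a) {
        const int j = support[a];
        double v = wfull[j] + alpha * (ws.b1[a] - wfull[j]);
        if (v <= 1e-12) { passive[j] = 0; wfull[j] = 0.0; }
        else { wfull[j] = v; kept.push_back(j); }
      }
      support.swap(kept);
      if (support.empty()) return;
    }
    // refresh G w and sum w from the sparse support
    std::fill(ws.gw.begin(), ws.gw.end(), 0.0);
    wsum = 0.0;
    for (int j : support) {
      const double wj = wfull[j];
      wsum += wj;
      const double* col = G + static_cast<size_t>(j) * m;
      for (int i = 0; i < m; ++i) ws.gw[i] += col[i] * wj;
    }
  }
}

// Exact simplex-constrained LS of one target, Gram form. `support` is used
// as a warm start: if the KKT conditions verify on it, the active-set
// search is skipped; either way it holds the final support on exit.
// Writes the full weight vector into `w` (length m) and returns the
// squared residual given ||t||^2 = tnorm2.
double simplex_gram(const double* G, const double* h, int m, double M2,
                    double tnorm2, std::vector<int>& support,
                    std::vector<double>& w, Workspace& ws) {
  w.assign(m, 0.0);
  if (m == 1) {
    support.assign(1, 0);
    w[0] = 1.0;
    double rss = tnorm2 - 2.0 * h[0] + G[0];
    return rss > 0 ? rss : 0.0;
  }
  double scale = 1.0;
  for (int j = 0; j < m; ++j) scale = std::max(scale, std::fabs(h[j]));

  auto accept = [&](const std::vector<int>& S, double l2) -> bool {
    // primal: refit weights already >= -1e-12 guaranteed by caller check;
    // dual: 2(Gw - h)_j + 2*l2 >= -tol off the support
    const int s = static_cast<int>(S.size());
    ws.gw.assign(m, 0.0);
    for (int a = 0; a < s; ++a) {
      const double* col = G + static_cast<size_t>(S[a]) * m;
      const double wa = ws.w[a];
      for (int i = 0; i < m; ++i) ws.gw[i] += col[i] * wa;
    }
    const double tol = 1e-8 * scale;
    std::vector<char> in(m, 0);
    for (int j : S) in[j] = 1;
    for (int j = 0; j < m; ++j) {
      if (in[j]) continue;
      if ((ws.gw[j] - h[j]) + l2 < -tol) return false;
    }
    return true;
  };

  // ---- warm start
  if (!support.empty() && static_cast<int>(support.size()) <= m) {
    double l2;
    if (refit_support(G, h, m, support, ws, &l2)) {
      bool feas = true;
      for (double v : ws.w) if (v < -1e-12) { feas = false; break; }
      if (feas && accept(support, l2)) {
        double tot = 0.0;
        for (size_t a = 0; a < support.size(); ++a) {
          double v = ws.w[a] > 0 ? ws.w[a] : 0.0;
          w[support[a]] = v;
          tot += v;
        }
        if (tot > 0) {
          double rss = tnorm2;
          for (int j : support) {
            w[j] /= tot;
            rss -= 2.0 * w[j] * h[j];
          }
          for (int ja : support)
            for (int jb : support)
              rss += w[ja] * w[jb] * G[ja + static_cast<size_t>(jb) * m];
          return rss > 0 ? rss : 0.0;
        }
      }
    }
  }

  // ---- cold path: augmented NNLS, then exact refit with negative drops
  std::vector<double> wnn;
  nnls_augmented(G, h, m, M2, ws, support, wnn);
  if (support.empty()) {
    // fall back to the single closest basis row
    int bi = 0;
    double best = -std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double v = h[j] - 0.5 * G[j + static_cast<size_t>(j) * m];
      if (v > best) { best = v; bi = j; }
    }
    support.assign(1, bi);
  }
  std::vector<int> S = support;
  for (;;) {
    double l2;
    if (!refit_support(G, h, m, S, ws, &l2)) {
      // singular support: fall back to renormalised NNLS weights
      double tot = 0.0;
      for (int j : S) tot += wnn[j];
      if (tot <= 0) { S.resize(1); ws.w.assign(1, 1.0); }
      else {
        ws.w.resize(S.size());
        for (size_t a = 0; a < S.size(); ++a) ws.w[a] = wnn[S[a]] / tot;
      }
      break;
    }
    int worst = -1;
    double wmin = -1e-12;
    for (size_t a = 0; a < S.size(); ++a)
      if (ws.w[a] < wmin) { wmin = ws.w[a]; worst = static_cast<int>(a); }
    if (worst < 0) break;
    S.erase(S.begin() + worst);
    if (S.empty()) { S.assign(1, support[0]); ws.w.assign(1, 1.0); break; }
  }
  support = S;
  double tot = 0.0;
  for (size_t a = 0; a < S.size(); ++a) {
    double v = ws.w[a] > 0 ? ws.w[a] : 0.0;
    w[S[a]] = v;
    tot += v;
  }
  double rss = tnorm2;
  for (int j : S) {
    w[j] /= tot;
    rss -= 2.0 * w[j] * h[j];
  }
  for (int ja : S)
    for (int jb : S)
      rss += w[ja] * w[jb] * G[ja + static_cast<size_t>(jb) * m];
  return rss > 0 ? rss : 0.0;
}

} // namespace

// Batch simplex projection: every row of `targets` against the rows of
// `basis`. Returns the n x m weight matrix and per-row squared residuals.
// [[Rcpp::export]]
Rcpp::List cpp_simplex_ls(const arma::mat& targets, const arma::mat& basis,
                          double penalty) {
  const uword n = targets.n_rows, m = basis.n_rows;
  const double M2 = penalty * penalty;
  mat Gu = basis * basis.t();
  mat Hu = basis * targets.t(); // m x n
  mat W(n, m);
  vec rss(n);
  Workspace ws;
  std::vector<int> support;
  std::vector<double> w;
  for (uword i = 0; i < n; ++i) {
    support.clear(); // no warm start across unrelated targets
    const double tn2 = dot(targets.row(i), targets.row(i));
    rss(i) = simplex_gram(Gu.memptr(), Hu.colptr(i), static_cast<int>(m), M2,
                          tn2, support, w, ws);
    for (uword j = 0; j < m; ++j) W(i, j) = w[j];
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("rss") = rss);
}

// One restart of the alternating archetype fit.
//   X: n x d data, init_idx: 1-based indices of the K seeding data points.
// Iteration: W-step (simplex projection of data on archetypes),
// unconstrained Z-hat solve, C-step (simplex projection of each Z-hat row
// on the data), RSS = ||X - W C X||_F^2. The RSS sequence is kept
// monotone: an iteration that would increase it is rolled back and the fit
// stops there. An archetype that loses all weight is re-seeded on the
// worst-reconstructed data point.
// [[Rcpp::export]]
Rcpp::List cpp_aa_fit(const arma::mat& X, const arma::uvec& init_idx,
                      int max_iter, double tol, double penalty) {
  const uword n = X.n_rows, d = X.n_cols;
  const uword K = init_idx.n_elem;
  const int mn = static_cast<int>(n), mK = static_cast<int>(K);
  const double M2 = penalty * penalty;

  mat Gd = X * X.t(); // data Gram for the C-step, formed once
  vec xn2 = Gd.diag();

  mat Z(K, d);
  for (uword k = 0; k < K; ++k) Z.row(k) = X.row(init_idx(k) - 1);

  mat W(n, K, fill::zeros), C(K, n, fill::zeros);
  std::vector<std::vector<int>> wsup(n), csup(K);
  Workspace ws;
  std::vector<double> wbuf;
  double rss_prev = datum::inf;
  std::vector<double> rss_hist;
  int iters = 0, reinits = 0;

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    // ---- W-step
    {
      mat Gu = Z * Z.t();
      mat Hu = Z * X.t(); // K x n
      for (uword i = 0; i < n; ++i) {
        simplex_gram(Gu.memptr(), Hu.colptr(i), mK, M2, xn2(i), wsup[i],
                     wbuf, ws);
        for (uword k = 0; k < K; ++k) W(i, k) = wbuf[k];
      }
    }
    // dead archetype: re-seed on the worst-reconstructed data point
    {
      rowvec totw = sum(W, 0);
      if (totw.min() < 1e-8) {
        vec pr = sum(square(X - W * Z), 1);
        for (uword k = 0; k < K; ++k) {
          if (totw(k) < 1e-8) {
            const uword worst = index_max(pr);
            Z.row(k) = X.row(worst);
            pr(worst) = 0;
            ++reinits;
          }
        }
        continue; // redo the W-step against the repaired basis
      }
    }
    // ---- Z-hat: unconstrained LS solve of X ~ W Zhat
    mat WtW = W.t() * W;
    WtW.diag() += 1e-10 * (arma::trace(WtW) / K + 1.0);
    mat Zhat = solve(WtW, W.t() * X, solve_opts::likely_sympd);

    // ---- C-step
    mat Hz = X * Zhat.t(); // n x K
    mat Znew(K, d);
    for (uword k = 0; k < K; ++k) {
      simplex_gram(Gd.memptr(), Hz.colptr(k), mn, M2,
                   dot(Zhat.row(k), Zhat.row(k)), csup[k], wbuf, ws);
      rowvec zr(d, fill::zeros);
      for (int j : csup[k]) zr += wbuf[j] * X.row(j);
      Znew.row(k) = zr;
      for (uword j = 0; j < n; ++j) C(k, j) = wbuf[j];
    }

    const double rss = accu(square(X - W * Znew));
    if (rss > rss_prev) break; // roll back: keep previous Z (monotone)
    Z = Znew;
    rss_hist.push_back(rss);
    const double rel = (rss_prev - rss) / std::max(rss_prev, 1e-300);
    rss_prev = rss;
    if (rel < tol) break;
  }

  // final W consistent with the returned Z
  {
    mat Gu = Z * Z.t();
    mat Hu = Z * X.t();
    for (uword i = 0; i < n; ++i) {
      simplex_gram(Gu.memptr(), Hu.colptr(i), mK, M2, xn2(i), wsup[i],
                   wbuf, ws);
      for (uword k = 0; k < K; ++k) W(i, k) = wbuf[k];
    }
  }
  double rss_final = accu(square(X - W * Z));
  rss_hist.push_back(rss_final);
  // guard the reported trace against recomputation float dust
  for (size_t t = 1; t < rss_hist.size(); ++t)
    if (rss_hist[t] > rss_hist[t - 1]) rss_hist[t] = rss_hist[t - 1];

  return Rcpp::List::create(
    Rcpp::Named("Z") = Z,
    Rcpp::Named("W") = W,
    Rcpp::Named("C") = C,
    Rcpp::Named("rss") = rss_hist.back(),
    Rcpp::Named("rss_trace") = rss_hist,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("reinits") = reinits);
}
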