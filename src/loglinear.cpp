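#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstdint>

using namespace Rcpp;

// Hierarchical log-linear model machinery on 2^k contingency tables of
// binary variables. Cells are indexed by bitmask: bit (v-1) set means
// variable v is in state 1; cell index = bitmask + 1 in R.
//
// Two generating classes over an edge set are supported:
//  - cliques:  maximal cliques of the graph (graphical model); the complete
//              graph is then the saturated model.
//  - pairwise: the edges themselves plus isolated singletons (all-two-factor
//              hierarchy); the complete graph is the all-pairwise model.

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// Bron-Kerbosch with pivoting over bitmask vertex sets (k <= 16).
static void bron_kerbosch(uint32_t R, uint32_t P, uint32_t X,
                          const std::vector<uint32_t>& adj,
                          std::vector<uint32_t>& out) {
  if (P == 0u && X == 0u) { out.push_back(R); return; }
  uint32_t PX = P | X;
  int pivot = -1, best = -1;
  for (uint32_t s = PX; s; s &= s - 1) {
    int u = __builtin_ctz(s);
    int c = popcount32(P & adj[u]);
    if (c > best) { best = c; pivot = u; }
  }
  uint32_t cand = P & ~adj[pivot];
  for (uint32_t s = cand; s; s &= s - 1) {
    int v = __builtin_ctz(s);
    uint32_t vb = 1u << v;
    bron_kerbosch(R | vb, P & adj[v], X & adj[v], adj, out);
    P &= ~vb;
    X |= vb;
  }
}

// Generator masks for the model over `adj`; pairwise = edges + isolated
// singletons, cliques = maximal cliques (which includes isolated vertices).
static std::vector<uint32_t> generator_masks(int k,
                                             const std::vector<uint32_t>& adj,
                                             bool pairwise) {
  std::vector<uint32_t> gens;
  if (!pairwise) {
    bron_kerbosch(0u, (1u << k) - 1u, 0u, adj, gens);
    return gens;
  }
  for (int a = 0; a < k; ++a) {
    if (adj[a] == 0u) gens.push_back(1u << a);
    for (uint32_t s = adj[a] & ~((1u << (a + 1)) - 1u); s; s &= s - 1) {
      int b = __builtin_ctz(s);
      gens.push_back((1u << a) | (1u << b));
    }
  }
  return gens;
}

// Free parameters of the hierarchical model: one u-term per subset (incl.
// empty) of some generator, variables being binary.
static int count_params(int k, const std::vector<uint32_t>& gens) {
  size_t ncell = size_t(1) << k;
  std::vector<char> seen(ncell, 0);
  for (size_t g = 0; g < gens.size(); ++g) {
    uint32_t M = gens[g], sub = M;
    while (true) {
      seen[sub] = 1;
      if (sub == 0u) break;
      sub = (sub - 1u) & M;
    }
  }
  int p = 0;
  for (size_t i = 0; i < ncell; ++i) p += seen[i];
  return p;
}

struct FitResult {
  double G2, max_gap;
  int df, n_params, iterations;
  bool converged;
};

// IPF to convergence on max |observed - fitted| generator-margin gap.
// `init` may carry a warm start (any table whose log-linear expansion has no
// u-terms outside the generator hierarchy); empty means flat start.
// Observed margins are cached by mask across calls on the same table.
static FitResult ipf_core(const std::vector<double>& counts, double n_total,
                          int k, const std::vector<uint32_t>& gens,
                          double tol, int maxit,
                          std::map<uint32_t, std::vector<double> >& cache,
                          std::vector<double>& fitted,
                          const std::vector<double>* init) {
  size_t ncell = counts.size();
  size_t nmar = gens.size();
  std::vector<const std::vector<double>*> obs(nmar);
  for (size_t m = 0; m < nmar; ++m) {
    uint32_t M = gens[m];
    std::map<uint32_t, std::vector<double> >::iterator it = cache.find(M);
    if (it == cache.end()) {
      it = cache.insert(std::make_pair(M, std::vector<double>())).first;
      std::vector<double>& omr = it->second;
      omr.assign(ncell, 0.0);
      for (size_t c = 0; c < ncell; ++c) omr[c & M] += counts[c];
    }
    obs[m] = &it->second;
  }

  if (init && init->size() == ncell) fitted = *init;
  else fitted.assign(ncell, n_total / double(ncell));

  std::vector<double> fit_mar(ncell);
  double max_gap = R_PosInf;
  int it2 = 0;
  for (it2 = 1; it2 <= maxit; ++it2) {
    max_gap = 0.0;
    for (size_t m = 0; m < nmar; ++m) {
      uint32_t M = gens[m];
      uint32_t sub = M;
      // zero only the margin slots (submasks of M)
      while (true) { fit_mar[sub] = 0.0; if (sub == 0u) break; sub = (sub - 1u) & M; }
      for (size_t c = 0; c < ncell; ++c) fit_mar[c & M] += fitted[c];
      const std::vector<double>& om = *obs[m];
      sub = M;
      while (true) {
        double d = om[sub] - fit_mar[sub];
        if (d < 0) d = -d;
        if (d > max_gap) max_gap = d;
        if (sub == 0u) break;
        sub = (sub - 1u) & M;
      }
      for (size_t c = 0; c < ncell; ++c) {
        uint32_t mc = c & M;
        double fm = fit_mar[mc];
        fitted[c] = (fm > 0.0) ? fitted[c] * om[mc] / fm : 0.0;
      }
    }
    if (max_gap < tol) break;
  }

  FitResult res;
  res.converged = (max_gap < tol);
  res.max_gap = max_gap;
  res.iterations = it2 > maxit ? maxit : it2;
  double G2 = 0.0;
  for (size_t c = 0; c < ncell; ++c) {
    double n = counts[c];
    if (n > 0.0) {
      double mhat = fitted[c];
      if (mhat <= 0.0) mhat = 1e-300;  // structural mismatch guard
      G2 += n * std::log(n / mhat);
    }
  }
  G2 *= 2.0;
  if (G2 < 0.0 && G2 > -1e-8) G2 = 0.0;
  res.G2 = G2;
  res.n_params = count_params(k, gens);
  res.df = int(ncell) - res.n_params;
  return res;
}

static std::vector<uint32_t> adj_from_edges(int k, const IntegerMatrix& edges) {
  std::vector<uint32_t> adj(k, 0u);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || b < 0 || a >= k || b >= k || a == b)
      stop("invalid edge (%d, %d) for k = %d", edges(e, 0), edges(e, 1), k);
    adj[a] |= (1u << b);
    adj[b] |= (1u << a);
  }
  return adj;
}

// Independence-model start table (valid warm start for any hierarchy that
// contains all singletons).
static void independence_start(const std::vector<double>& counts,
                               double n_total, int k,
                               std::vector<double>& out) {
  size_t ncell = counts.size();
  std::vector<double> p1(k, 0.0);
  for (size_t c = 0; c < ncell; ++c)
    for (int v = 0; v < k; ++v)
      if (c & (1u << v)) p1[v] += counts[c];
  for (int v = 0; v < k; ++v) p1[v] /= n_total;
  out.assign(ncell, n_total);
  for (size_t c = 0; c < ncell; ++c)
    for (int v = 0; v < k; ++v)
      out[c] *= (c & (1u << v)) ? p1[v] : 1.0 - p1[v];
}

// [[Rcpp::export(name = ".cpp_max_cliques")]]
List cpp_max_cliques(int k, IntegerMatrix edges) {
  std::vector<uint32_t> adj = adj_from_edges(k, edges);
  std::vector<uint32_t> cl;
  bron_kerbosch(0u, (1u << k) - 1u, 0u, adj, cl);
  List out(cl.size());
  for (size_t i = 0; i < cl.size(); ++i) {
    std::vector<int> verts;
    for (int v = 0; v < k; ++v) if (cl[i] & (1u << v)) verts.push_back(v + 1);
    out[i] = wrap(verts);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_ipf_fit")]]
List cpp_ipf_fit(NumericVector counts_in, int k, IntegerMatrix edges,
                 double tol, int maxit, bool pairwise) {
  if (k < 1 || k > 16) stop("k must be in 1..16");
  size_t ncell = size_t(1) << k;
  if ((size_t)counts_in.size() != ncell) stop("counts must have length 2^k");
  std::vector<double> counts(counts_in.begin(), counts_in.end());
  double n_total = 0.0;
  for (size_t c = 0; c < ncell; ++c) {
    if (counts[c] < 0) stop("negative cell count");
    n_total += counts[c];
  }
  std::vector<uint32_t> adj = adj_from_edges(k, edges);
  std::vector<uint32_t> gens = generator_masks(k, adj, pairwise);
  std::map<uint32_t, std::vector<double> > cache;
  std::vector<double> fitted;
  std::vector<double> start;
  independence_start(counts, n_total, k, start);
  FitResult res = ipf_core(counts, n_total, k, gens, tol, maxit, cache,
                           fitted, &start);
  return List::create(
    _["fitted"] = NumericVector(fitted.begin(), fitted.end()),
    _["G2"] = res.G2,
    _["df"] = res.df,
    _["n_params"] = res.n_params,
    _["converged"] = res.converged,
    _["iterations"] = res.iterations,
    _["max_gap"] = res.max_gap);
}

// ---- backward elimination driver --------------------------------------
// Full edge-elimination loop over all-two-factor hierarchies, specialised
// for speed: observed singleton/pair margins are computed once, model
// parameter counts are closed-form (1 + k + |E|), and candidate fits
// warm-start from the current fit with the removed edge's two-factor
// u-term flattened out (the adjusted table lies inside the candidate
// hierarchy, so IPF converges to the candidate MLE in a few sweeps).

struct PairwiseWork {
  int k;
  size_t ncell;
  double n_total;
  std::vector<double> counts;
  // margin arrays indexed by generator mask through mar_of
  std::vector< std::vector<double> > margins;
  std::vector<int> mar_of;
  std::vector<double> fit_mar;

  PairwiseWork(const std::vector<double>& cnts, int kk)
      : k(kk), ncell(cnts.size()), n_total(0.0), counts(cnts),
        mar_of(cnts.size(), -1), fit_mar(cnts.size(), 0.0) {
    for (size_t c = 0; c < ncell; ++c) n_total += counts[c];
    for (int a = 0; a < k; ++a) {
      add_margin(1u << a);
      for (int b = a + 1; b < k; ++b) add_margin((1u << a) | (1u << b));
    }
  }

  void add_margin(uint32_t M) {
    std::vector<double> om(ncell, 0.0);
    for (size_t c = 0; c < ncell; ++c) om[c & M] += counts[c];
    mar_of[M] = (int)margins.size();
    margins.push_back(om);
  }

  // IPF over the given generator masks; returns G2, sets `fitted`.
  bool ipf(const std::vector<uint32_t>& gens, const std::vector<double>* init,
           double tol, int maxit, std::vector<double>& fitted, double& G2) {
    if (init) fitted = *init;
    else fitted.assign(ncell, n_total / double(ncell));
    double max_gap = R_PosInf;
    for (int it = 1; it <= maxit; ++it) {
      max_gap = 0.0;
      for (size_t m = 0; m < gens.size(); ++m) {
        uint32_t M = gens[m];
        const std::vector<double>& om = margins[mar_of[M]];
        uint32_t sub = M;
        while (true) { fit_mar[sub] = 0.0; if (sub == 0u) break; sub = (sub - 1u) & M; }
        for (size_t c = 0; c < ncell; ++c) fit_mar[c & M] += fitted[c];
        sub = M;
        while (true) {
          double d = om[sub] - fit_mar[sub];
          if (d < 0) d = -d;
          if (d > max_gap) max_gap = d;
          if (sub == 0u) break;
          sub = (sub - 1u) & M;
        }
        for (size_t c = 0; c < ncell; ++c) {
          uint32_t mc = c & M;
          double fm = fit_mar[mc];
          fitted[c] = (fm > 0.0) ? fitted[c] * om[mc] / fm : 0.0;
        }
      }
      if (max_gap < tol) break;
    }
    G2 = 0.0;
    for (size_t c = 0; c < ncell; ++c) {
      double n = counts[c];
      if (n > 0.0) {
        double mhat = fitted[c];
        if (mhat <= 0.0) mhat = 1e-300;
        G2 += n * std::log(n / mhat);
      }
    }
    G2 *= 2.0;
    if (G2 < 0.0 && G2 > -1e-8) G2 = 0.0;
    return max_gap < tol;
  }
};

// Generators of the pairwise hierarchy for an edge list: the edges plus a
// singleton for every isolated vertex.
static void pairwise_gens(int k, const std::vector< std::pair<int,int> >& edges,
                          int skip, std::vector<uint32_t>& out) {
  out.clear();
  uint32_t covered = 0u;
  for (size_t e = 0; e < edges.size(); ++e) {
    if ((int)e == skip) continue;
    uint32_t M = (1u << edges[e].first) | (1u << edges[e].second);
    out.push_back(M);
    covered |= M;
  }
  for (int v = 0; v < k; ++v)
    if (!(covered & (1u << v))) out.push_back(1u << v);
}

// [[Rcpp::export(name = ".cpp_backward_select")]]
List cpp_backward_select(NumericVector counts_in, int k, double alpha,
                         double tol, int maxit) {
  if (k < 1 || k > 16) stop("k must be in 1..16");
  size_t ncell = size_t(1) << k;
  if ((size_t)counts_in.size() != ncell) stop("counts must have length 2^k");
  std::vector<double> counts(counts_in.begin(), counts_in.end());
  PairwiseWork w(counts, k);

  std::vector< std::pair<int,int> > edges;
  for (int a = 0; a < k - 1; ++a)
    for (int b = a + 1; b < k; ++b)
      edges.push_back(std::make_pair(a, b));

  std::vector<double> start;
  independence_start(counts, w.n_total, k, start);

  std::vector<uint32_t> gens;
  pairwise_gens(k, edges, -1, gens);
  std::vector<double> cur_fitted;
  double cur_G2;
  if (!w.ipf(gens, &start, tol, maxit, cur_fitted, cur_G2))
    stop("IPF did not converge in %d sweeps", maxit);
  int cur_df = int(ncell) - (1 + k + (int)edges.size());
  double fm_G2 = cur_G2;
  int fm_df = cur_df;

  std::vector<int> tr_a, tr_b;
  std::vector<double> tr_prm, tr_pfm;
  std::vector<double> cand_fitted, warm, best_fitted;

  while (!edges.empty()) {
    size_t ne = edges.size();
    double best_prm = -1.0, best_pfm = 0.0, best_G2 = 0.0;
    size_t best_e = 0;
    int rm_df = cur_df + 1;                      // one u-term fewer
    double p_fm_ddf = (double)(rm_df - fm_df);   // same for all candidates
    for (size_t e = 0; e < ne; ++e) {
      int a = edges[e].first, b = edges[e].second;
      uint32_t ba = 1u << a, bb = 1u << b;
      // warm start: flatten u_ab out of the current fitted table
      const std::vector<double>* init = &start;
      double m11 = cur_fitted[ba | bb], m10 = cur_fitted[ba],
             m01 = cur_fitted[bb], m00 = cur_fitted[0];
      if (m11 > 0 && m10 > 0 && m01 > 0 && m00 > 0) {
        double psi = (m11 * m00) / (m10 * m01);
        warm = cur_fitted;
        for (size_t c = 0; c < ncell; ++c)
          if ((c & ba) && (c & bb)) warm[c] /= psi;
        init = &warm;
      }
      pairwise_gens(k, edges, (int)e, gens);
      double rm_G2;
      if (!w.ipf(gens, init, tol, maxit, cand_fitted, rm_G2))
        stop("IPF did not converge in %d sweeps", maxit);
      double dG2 = rm_G2 - cur_G2;
      if (dG2 < 0) dG2 = 0;
      double p_rm = R::pchisq(dG2, 1.0, 0, 0);
      double dG2_fm = rm_G2 - fm_G2;
      if (dG2_fm < 0) dG2_fm = 0;
      double p_fm = p_fm_ddf > 0 ? R::pchisq(dG2_fm, p_fm_ddf, 0, 0) : 1.0;
      if (p_rm > alpha && p_fm > alpha && p_rm > best_prm) {
        best_prm = p_rm;
        best_pfm = p_fm;
        best_e = e;
        best_G2 = rm_G2;
        best_fitted = cand_fitted;
      }
    }
    if (best_prm < 0) break;
    tr_a.push_back(edges[best_e].first + 1);
    tr_b.push_back(edges[best_e].second + 1);
    tr_prm.push_back(best_prm);
    tr_pfm.push_back(best_pfm);
    edges.erase(edges.begin() + best_e);
    cur_G2 = best_G2;
    cur_df = rm_df;
    cur_fitted.swap(best_fitted);
  }

  IntegerMatrix em(edges.size(), 2);
  for (size_t e = 0; e < edges.size(); ++e) {
    em(e, 0) = edges[e].first + 1;
    em(e, 1) = edges[e].second + 1;
  }
  return List::create(
    _["edges"] = em,
    _["G2"] = cur_G2,
    _["df"] = cur_df,
    _["n_params"] = int(ncell) - cur_df,
    _["fitted"] = NumericVector(cur_fitted.begin(), cur_fitted.end()),
    _["fm_G2"] = fm_G2,
    _["fm_df"] = fm_df,
    _["trace_a"] = wrap(tr_a),
    _["trace_b"] = wrap(tr_b),
    _["trace_p_rm"] = wrap(tr_prm),
    _["trace_p_fm"] = wrap(tr_pfm));
}
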