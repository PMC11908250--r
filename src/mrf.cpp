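// Multivariate regression forest core.
//
// Trees are grown on a bootstrap multiset with the summed split criterion
// over per-node standardized responses; every internal node records the
// response variable with the largest per-response split statistic (MSRV).
// All randomness comes from a self-contained 64-bit generator so a forest
// is a pure function of (data, params, seed), independent of R's RNG and
// of execution schedule.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

// splitmix64: tiny, well-mixed, platform-stable.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) { next(); }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // integer in [0, n) by 32x32 multiply-shift (n << 2^32 always here)
  int below(int n) {
    uint32_t hi = static_cast<uint32_t>(next() >> 32);
    return static_cast<int>((static_cast<uint64_t>(hi) * n) >> 32);
  }
};

static uint64_t mix_seed(int seed, int tree_index) {
  uint64_t s = static_cast<uint64_t>(static_cast<uint32_t>(seed));
  s = s * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL *
      static_cast<uint64_t>(static_cast<uint32_t>(tree_index));
  return s;
}

// sample m of 0..N-1 without replacement, ascending
static void sample_wor(int N, int m, Rng& rng, std::vector<int>& scratch,
                       std::vector<int>& out) {
  scratch.resize(N);
  for (int i = 0; i < N; ++i) scratch[i] = i;
  out.resize(m);
  for (int i = 0; i < m; ++i) {
    int j = i + rng.below(N - i);
    std::swap(scratch[i], scratch[j]);
    out[i] = scratch[i];
  }
  std::sort(out.begin(), out.end());
}

// ------------------------------------------------------- split search ----

struct BestSplit {
  bool found = false;
  int var = -1;        // column of X (0-based)
  double value = 0.0;  // cut point (midpoint)
  int left_k = 0;      // left daughter size
  double gq = -1.0;    // summed criterion at the best split
};

// Search the best (variable, cut) over `cands` (ascending 0-based X columns)
// for node members `samp` (indices into X rows, with multiplicity), given
// standardized responses Z (nt x qs, row-major) and their column sums T.
// Ties keep the first candidate/cut encountered (smallest var, smallest cut).
// running dot-product step: acc = sum_j s[j] * z[j], then s += z.
// four independent lanes so the reduction pipelines/vectorizes.
static inline double dot_update(double* __restrict s,
                                const double* __restrict z, int qs) {
  double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
  int j = 0;
  for (; j + 4 <= qs; j += 4) {
    a0 += s[j] * z[j];
    a1 += s[j + 1] * z[j + 1];
    a2 += s[j + 2] * z[j + 2];
    a3 += s[j + 3] * z[j + 3];
    s[j] += z[j];
    s[j + 1] += z[j + 1];
    s[j + 2] += z[j + 2];
    s[j + 3] += z[j + 3];
  }
  for (; j < qs; ++j) {
    a0 += s[j] * z[j];
    s[j] += z[j];
  }
  return (a0 + a1) + (a2 + a3);
}

// cap on node size for materializing the nt x nt Gram matrix (~32 MB)
static const int GRAM_MAX_NT = 2048;

static BestSplit search_split(const NumericMatrix& X,
                              const std::vector<int>& samp,
                              const std::vector<int>& cands,
                              const std::vector<double>& Z,
                              const std::vector<double>& T,
                              const std::vector<double>& row2,
                              int qs, int nodesize, int nsplit, Rng& rng) {
  const int nt = static_cast<int>(samp.size());
  const int n = X.nrow();
  const double* Xp = &X[0];
  BestSplit best;
  std::vector<double> xv(nt);
  std::vector<int> ord(nt);
  std::vector<double> s(qs);
  std::vector<int> valid, chosen, scratch;

  // within-node standardized responses have column sum exactly 0; then
  // Gj = s^2/nL + (T - s)^2/nR collapses to s^2 (1/nL + 1/nR), so the
  // summed criterion is tracked by one incrementally updated sum of
  // squares. Fall back to the general form for arbitrary T.
  bool centered = true;
  for (int j = 0; j < qs; ++j) {
    if (T[j] != 0.0) {
      centered = false;
      break;
    }
  }

  // centered fast path: sum_j s_j(k)^2 = a_k' (Z Z') a_k over the left
  // membership a_k, so with the Gram matrix K built once per node every
  // candidate sweep is O(nt^2) in cache instead of O(nt * q) streaming
  const bool useGram = centered && nt <= GRAM_MAX_NT && qs >= 2;
  std::vector<double> K, r;
  if (useGram) {
    K.assign(static_cast<size_t>(nt) * nt, 0.0);
    const double one = 1.0, zero = 0.0;
    // Z is nt x qs row-major == qs x nt column-major; K = Z Z^T = A^T A
    F77_CALL(dsyrk)("U", "T", &nt, &qs, &one, Z.data(), &qs, &zero,
                    K.data(), &nt FCONE FCONE);
    for (int i = 0; i < nt; ++i) {  // mirror upper to full
      for (int j = i + 1; j < nt; ++j) {
        K[static_cast<size_t>(i) * nt + j] =
            K[static_cast<size_t>(j) * nt + i];
      }
    }
    r.assign(nt, 0.0);
  }

  for (size_t ci = 0; ci < cands.size(); ++ci) {
    const int v = cands[ci];
    const double* xcol = Xp + static_cast<size_t>(v) * n;
    for (int i = 0; i < nt; ++i) xv[i] = xcol[samp[i]];
    for (int i = 0; i < nt; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    if (xv[ord[0]] == xv[ord[nt - 1]]) continue;  // constant in node

    // admissible left sizes k: daughters >= nodesize, cut between
    // distinct adjacent values
    valid.clear();
    for (int k = nodesize; k <= nt - nodesize; ++k) {
      if (xv[ord[k - 1]] < xv[ord[k]]) valid.push_back(k);
    }
    if (valid.empty()) continue;

    const std::vector<int>* eval = &valid;
    if (nsplit > 0 && static_cast<int>(valid.size()) > nsplit) {
      sample_wor(static_cast<int>(valid.size()), nsplit, rng, scratch, chosen);
      for (size_t i = 0; i < chosen.size(); ++i) chosen[i] = valid[chosen[i]];
      eval = &chosen;
    }
    const int kLast = eval->back();

    double ssq = 0.0;  // running sum_j s_j^2 (centered fast path)
    size_t ei = 0;
    if (useGram) {
      std::fill(r.begin(), r.end(), 0.0);
      for (int k = 1; k <= kLast; ++k) {
        const int t = ord[k - 1];
        const double* Krow = &K[static_cast<size_t>(t) * nt];
        ssq += 2.0 * r[t] + Krow[t];
        // r is only ever read for samples still to be added
        for (int m = k; m < nt; ++m) {
          const int i = ord[m];
          r[i] += Krow[i];
        }
        if ((*eval)[ei] != k) continue;
        ++ei;
        const double g = ssq * (1.0 / k + 1.0 / (nt - k));
        if (g > best.gq) {
          best.found = true;
          best.var = v;
          best.left_k = k;
          best.value = 0.5 * (xv[ord[k - 1]] + xv[ord[k]]);
          best.gq = g;
        }
      }
      continue;
    }
    std::fill(s.begin(), s.end(), 0.0);
    for (int k = 1; k <= kLast; ++k) {
      const int row = ord[k - 1];
      const double* zrow = &Z[static_cast<size_t>(row) * qs];
      if (centered) {
        // ssq(k) = ssq(k-1) + 2 s.z + |z|^2 with |z|^2 precomputed per row
        ssq += 2.0 * dot_update(s.data(), zrow, qs) + row2[row];
      } else {
        for (int j = 0; j < qs; ++j) s[j] += zrow[j];
      }
      if ((*eval)[ei] != k) continue;
      ++ei;
      double g;
      const double invL = 1.0 / k, invR = 1.0 / (nt - k);
      if (centered) {
        g = ssq * (invL + invR);
      } else {
        g = 0.0;
        for (int j = 0; j < qs; ++j) {
          const double r = T[j] - s[j];
          g += s[j] * s[j] * invL + r * r * invR;
        }
      }
      if (g > best.gq) {
        best.found = true;
        best.var = v;
        best.left_k = k;
        best.value = 0.5 * (xv[ord[k - 1]] + xv[ord[k]]);
        best.gq = g;
      }
    }
  }
  return best;
}

// per-response split statistic vector at a fixed (var, left_k)
static void split_g_vector(const NumericMatrix& X,
                           const std::vector<int>& samp, int var, int left_k,
                           const std::vector<double>& Z,
                           const std::vector<double>& T, int qs,
                           std::vector<double>& G) {
  const int nt = static_cast<int>(samp.size());
  std::vector<double> xv(nt);
  std::vector<int> ord(nt);
  for (int i = 0; i < nt; ++i) xv[i] = X(samp[i], var);
  for (int i = 0; i < nt; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });
  std::vector<double> s(qs, 0.0);
  for (int k = 0; k < left_k; ++k) {
    const double* zrow = &Z[static_cast<size_t>(ord[k]) * qs];
    for (int j = 0; j < qs; ++j) s[j] += zrow[j];
  }
  G.resize(qs);
  for (int j = 0; j < qs; ++j) {
    const double r = T[j] - s[j];
    G[j] = s[j] * s[j] / left_k + r * r / (nt - left_k);
  }
}

// standardize scored response columns over the node multiset:
// z = sqrt(nt) * (y - mean) / sqrt(ss); zero-variance columns -> all zero
static void standardize_node(const NumericMatrix& Y,
                             const std::vector<int>& samp,
                             const std::vector<int>& rcols,
                             std::vector<double>& Z,
                             std::vector<double>& T,
                             std::vector<double>& row2) {
  const int nt = static_cast<int>(samp.size());
  const int qs = static_cast<int>(rcols.size());
  Z.assign(static_cast<size_t>(nt) * qs, 0.0);
  T.assign(qs, 0.0);
  for (int j = 0; j < qs; ++j) {
    const int col = rcols[j];
    double mean = 0.0;
    for (int i = 0; i < nt; ++i) mean += Y(samp[i], col);
    mean /= nt;
    double ss = 0.0;
    for (int i = 0; i < nt; ++i) {
      const double d = Y(samp[i], col) - mean;
      ss += d * d;
    }
    if (ss <= 0.0) continue;  // inert column stays all-zero
    const double sc = std::sqrt(static_cast<double>(nt) / ss);
    for (int i = 0; i < nt; ++i) {
      Z[static_cast<size_t>(i) * qs + j] = sc * (Y(samp[i], col) - mean);
    }
  }
  // column sums of Z are 0 by construction; keep T exact zeros
  row2.assign(nt, 0.0);
  for (int i = 0; i < nt; ++i) {
    const double* zrow = &Z[static_cast<size_t>(i) * qs];
    double a = 0.0;
    for (int j = 0; j < qs; ++j) a += zrow[j] * zrow[j];
    row2[i] = a;
  }
}

// ---------------------------------------------------------- tree grow ----

struct TreeAcc {
  std::vector<int> depth, split_var, msrv, left, right, n_node;
  std::vector<double> split_value, gq_star;
  int add(int d, int nt) {
    depth.push_back(d);
    split_var.push_back(NA_INTEGER);
    msrv.push_back(NA_INTEGER);
    left.push_back(NA_INTEGER);
    right.push_back(NA_INTEGER);
    n_node.push_back(nt);
    split_value.push_back(NA_REAL);
    gq_star.push_back(NA_REAL);
    return static_cast<int>(depth.size()) - 1;
  }
};

static List grow_one_tree(const NumericMatrix& X, const NumericMatrix& Y,
                          int mtry, double resp_frac, int nodesize,
                          int max_depth, int nsplit, uint64_t state) {
  const int n = X.nrow(), p = X.ncol(), q = Y.ncol();
  Rng rng(state);

  IntegerVector inbag(n, 0);
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) {
    const int k = rng.below(n);
    root[i] = k;
    inbag[k] += 1;
  }

  int qs = static_cast<int>(std::ceil(resp_frac * q));
  if (qs < 1) qs = 1;
  if (qs > q) qs = q;

  TreeAcc acc;
  struct Work {
    int id, d;
    std::vector<int> samp;
  };
  std::vector<Work> stack;
  stack.push_back({acc.add(0, n), 0, std::move(root)});

  std::vector<int> cands, rcols, scratch;
  std::vector<double> Z, T, G, row2;

  while (!stack.empty()) {
    Work w = std::move(stack.back());
    stack.pop_back();
    const int nt = static_cast<int>(w.samp.size());
    if (nt < 2 * nodesize || (max_depth > 0 && w.d >= max_depth)) continue;

    sample_wor(p, mtry, rng, scratch, cands);
    if (qs < q) {
      sample_wor(q, qs, rng, scratch, rcols);
    } else {
      rcols.resize(q);
      for (int j = 0; j < q; ++j) rcols[j] = j;
    }

    standardize_node(Y, w.samp, rcols, Z, T, row2);
    BestSplit best =
        search_split(X, w.samp, cands, Z, T, row2, qs, nodesize, nsplit, rng);
    if (!best.found) continue;

    split_g_vector(X, w.samp, best.var, best.left_k, Z, T, qs, G);
    int mj = 0;
    for (int j = 1; j < qs; ++j) {
      if (G[j] > G[mj]) mj = j;  // strict: ties keep smallest index
    }

    std::vector<int> ls, rs;
    ls.reserve(best.left_k);
    rs.reserve(nt - best.left_k);
    for (int i = 0; i < nt; ++i) {
      if (X(w.samp[i], best.var) <= best.value) {
        ls.push_back(w.samp[i]);
      } else {
        rs.push_back(w.samp[i]);
      }
    }

    const int lid = acc.add(w.d + 1, static_cast<int>(ls.size()));
    const int rid = acc.add(w.d + 1, static_cast<int>(rs.size()));
    acc.split_var[w.id] = best.var + 1;
    acc.split_value[w.id] = best.value;
    acc.msrv[w.id] = rcols[mj] + 1;
    acc.gq_star[w.id] = best.gq;
    acc.left[w.id] = lid + 1;
    acc.right[w.id] = rid + 1;
    stack.push_back({rid, w.d + 1, std::move(rs)});
    stack.push_back({lid, w.d + 1, std::move(ls)});
  }

  return List::create(
      _["inbag"] = inbag, _["depth"] = wrap(acc.depth),
      _["splitVar"] = wrap(acc.split_var),
      _["splitValue"] = wrap(acc.split_value), _["msrv"] = wrap(acc.msrv),
      _["gqStar"] = wrap(acc.gq_star), _["left"] = wrap(acc.left),
      _["right"] = wrap(acc.right), _["nNode"] = wrap(acc.n_node));
}

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, NumericMatrix Y, int ntree, int mtry,
                     double resp_frac, int nodesize, int max_depth,
                     int nsplit, int seed) {
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    trees[b] = grow_one_tree(X, Y, mtry, resp_frac, nodesize, max_depth,
                             nsplit, mix_seed(seed, b));
  }
  return trees;
}

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, NumericMatrix Y, int mtry,
                   double resp_frac, int nodesize, int max_depth, int nsplit,
                   int seed, int tree_index) {
  return grow_one_tree(X, Y, mtry, resp_frac, nodesize, max_depth, nsplit,
                       mix_seed(seed, tree_index));
}

// Best split on a prepared node: Ystar columns are already standardized and
// all scored. Exposed for oracle testing and as the find-best-split surface.
// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix Xnode, NumericMatrix Ystar,
                    IntegerVector candidates, int nodesize, int nsplit,
                    int seed) {
  const int nt = Xnode.nrow(), qs = Ystar.ncol();
  std::vector<int> samp(nt), cands(candidates.size());
  for (int i = 0; i < nt; ++i) samp[i] = i;
  for (int i = 0; i < candidates.size(); ++i) cands[i] = candidates[i] - 1;
  std::sort(cands.begin(), cands.end());

  std::vector<double> Z(static_cast<size_t>(nt) * qs), T(qs, 0.0);
  std::vector<double> row2(nt, 0.0);
  for (int i = 0; i < nt; ++i) {
    for (int j = 0; j < qs; ++j) {
      const double z = Ystar(i, j);
      Z[static_cast<size_t>(i) * qs + j] = z;
      row2[i] += z * z;
    }
  }
  for (int j = 0; j < qs; ++j) {
    double t = 0.0;
    for (int i = 0; i < nt; ++i) t += Ystar(i, j);
    // treat tiny accumulation residue of centered input as exact zero so
    // the fast path and the tree grower agree
    T[j] = (std::abs(t) < 1e-9 * nt) ? 0.0 : t;
  }

  Rng rng(mix_seed(seed, 0));
  BestSplit best =
      search_split(Xnode, samp, cands, Z, T, row2, qs, nodesize, nsplit, rng);
  if (!best.found) {
    return List::create(_["found"] = false);
  }
  std::vector<double> G;
  split_g_vector(Xnode, samp, best.var, best.left_k, Z, T, qs, G);
  return List::create(_["found"] = true, _["splitVar"] = best.var + 1,
                      _["splitValue"] = best.value, _["G"] = wrap(G),
                      _["gqStar"] = best.gq);
}

// Terminal node id (1-based) of every row of X in every tree.
// [[Rcpp::export(name = ".forest_assign_cpp")]]
IntegerMatrix forest_assign_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  IntegerMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector splitVar = tr["splitVar"], left = tr["left"],
                  right = tr["right"];
    NumericVector splitValue = tr["splitValue"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (splitVar[node] != NA_INTEGER) {
        node = (X(i, splitVar[node] - 1) <= splitValue[node])
                   ? left[node] - 1
                   : right[node] - 1;
      }
      out(i, b) = node + 1;
    }
  }
  return out;
}
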