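// Degree-preserving randomization of a bipartite sample x segment incidence
// matrix via checkerboard (switch) moves, plus batched computation of the
// null statistics used by the network significance tests. A proposal picks
// two 1-cells uniformly at random (collisions allowed, making the chain
// lazy and aperiodic) and, when the complementary cells are empty, swaps
// [[1,0],[0,1]] <-> [[0,1],[1,0]]. Row and column sums are invariant by
// construction.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XS128 {
  uint64_t s0, s1;
  explicit XS128(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t r = z;
      r = (r ^ (r >> 30)) * 0xBF58476D1CE4E5B9ULL;
      r = (r ^ (r >> 27)) * 0x94D049BB133111EBULL;
      r = r ^ (r >> 31);
      if (i == 0) s0 = r; else s1 = r;
    }
    if (!(s0 | s1)) s0 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // Lemire multiply-shift; bias is negligible for the ranges used here
  inline int below(int n) {
    return (int)(((uint64_t)(uint32_t)next() * (uint64_t)(uint32_t)n) >> 32);
  }
};

struct Chain {
  int n, m;                       // rows (samples), cols (segments)
  std::vector<uint8_t> mat;       // n * m, row-major
  std::vector<int> ones_r, ones_c;
  long long successes = 0;

  void init(const IntegerMatrix& inc) {
    n = inc.nrow(); m = inc.ncol();
    mat.assign((size_t)n * m, 0);
    ones_r.clear(); ones_c.clear();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j)
        if (inc(i, j) != 0) {
          mat[(size_t)i * m + j] = 1;
          ones_r.push_back(i);
          ones_c.push_back(j);
        }
  }

  // run `attempts` proposals; k (n_block x m, row-major by block) tracks
  // per-block column counts when non-null
  void run(XS128& rng, long long attempts, std::vector<int>* k,
           const int* row_block) {
    const int nones = (int)ones_r.size();
    if (nones < 2) return;
    for (long long t = 0; t < attempts; ++t) {
      int i = rng.below(nones), j = rng.below(nones);
      if (i == j) continue;
      int r1 = ones_r[i], c1 = ones_c[i];
      int r2 = ones_r[j], c2 = ones_c[j];
      if (r1 == r2 || c1 == c2) continue;
      size_t p12 = (size_t)r1 * m + c2, p21 = (size_t)r2 * m + c1;
      if (mat[p12] || mat[p21]) continue;
      mat[(size_t)r1 * m + c1] = 0;
      mat[(size_t)r2 * m + c2] = 0;
      mat[p12] = 1;
      mat[p21] = 1;
      ones_c[i] = c2;
      ones_c[j] = c1;
      ++successes;
      if (k) {
        int b1 = row_block[r1], b2 = row_block[r2];
        std::vector<int>& kk = *k;
        kk[(size_t)b1 * m + c1]--; kk[(size_t)b1 * m + c2]++;
        kk[(size_t)b2 * m + c2]--; kk[(size_t)b2 * m + c1]++;
      }
    }
  }
};

inline double choose2(double k) { return k * (k - 1.0) / 2.0; }

} // namespace

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix inc, double attempts, double seed) {
  Chain ch;
  ch.init(inc);
  XS128 rng((uint64_t)seed);
  ch.run(rng, (long long)attempts, nullptr, nullptr);
  IntegerMatrix out(ch.n, ch.m);
  for (int i = 0; i < ch.n; ++i)
    for (int j = 0; j < ch.m; ++j)
      out(i, j) = ch.mat[(size_t)i * ch.m + j];
  out.attr("dimnames") = inc.attr("dimnames");
  return List::create(_["incidence"] = out,
                      _["attempts"] = attempts,
                      _["successes"] = (double)ch.successes);
}

// Null ensemble: each permutation is a fresh chain from the original
// matrix. row_block assigns each row to a disease x continent block
// (0-based). Group statistics are defined by (disease, cont1, cont2)
// triples: cont1 = -1 means all continents pooled; cont1 == cont2 a
// within-continent block; cont1 != cont2 a continent pair. The statistic is
// the total within-group edge weight, computed per segment from carrier
// counts: sum_s C(k,2) (pooled or same-continent) or sum_s k1*k2 (pair).
// Edge statistics: for requested row pairs, the null co-carriage count
// (dot product of rows) is compared with the observed weight. Segment
// statistics: per (segment, disease) the within-disease carrier pair count
// C(k,2) is compared with its observed value.
// [[Rcpp::export]]
List cpp_null_ensemble(IntegerMatrix inc,
                       IntegerVector row_block,
                       IntegerVector block_disease,
                       IntegerVector block_cont,
                       IntegerVector stat_disease,
                       IntegerVector stat_c1,
                       IntegerVector stat_c2,
                       IntegerVector edge_r1,
                       IntegerVector edge_r2,
                       int n_perm,
                       double attempts,
                       double seed,
                       bool want_segments,
                       int n_disease) {
  const int n = inc.nrow(), m = inc.ncol();
  const int n_block = block_disease.size();
  const int n_stat = stat_disease.size();
  const int n_edge = edge_r1.size();

  // initial block x segment carrier counts
  std::vector<int> k0((size_t)n_block * m, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (inc(i, j) != 0) k0[(size_t)row_block[i] * m + j]++;

  // per-disease lists of blocks
  std::vector<std::vector<int>> blocks_of_disease(n_disease);
  for (int b = 0; b < n_block; ++b)
    blocks_of_disease[block_disease[b]].push_back(b);

  std::vector<double> kd(m);
  auto disease_counts = [&](const std::vector<int>& k, int d) {
    std::fill(kd.begin(), kd.end(), 0.0);
    for (int b : blocks_of_disease[d])
      for (int j = 0; j < m; ++j) kd[j] += k[(size_t)b * m + j];
  };

  auto group_stat = [&](const std::vector<int>& k, int s) {
    int d = stat_disease[s], c1 = stat_c1[s], c2 = stat_c2[s];
    double tot = 0.0;
    if (c1 < 0) {
      disease_counts(k, d);
      for (int j = 0; j < m; ++j) tot += choose2(kd[j]);
    } else {
      int b1 = -1, b2 = -1;
      for (int b : blocks_of_disease[d]) {
        if (block_cont[b] == c1) b1 = b;
        if (block_cont[b] == c2) b2 = b;
      }
      if (b1 < 0 || b2 < 0) return 0.0;
      if (c1 == c2) {
        for (int j = 0; j < m; ++j) tot += choose2((double)k[(size_t)b1 * m + j]);
      } else {
        for (int j = 0; j < m; ++j)
          tot += (double)k[(size_t)b1 * m + j] * (double)k[(size_t)b2 * m + j];
      }
    }
    return tot;
  };

  // observed statistics
  NumericVector group_obs(n_stat);
  for (int s = 0; s < n_stat; ++s) group_obs[s] = group_stat(k0, s);

  NumericMatrix seg_obs(want_segments ? m : 0, want_segments ? n_disease : 0);
  if (want_segments) {
    for (int d = 0; d < n_disease; ++d) {
      disease_counts(k0, d);
      for (int j = 0; j < m; ++j) seg_obs(j, d) = choose2(kd[j]);
    }
  }

  const int words = (m + 63) / 64;
  std::vector<uint64_t> packed((size_t)n * words);
  auto pack_rows = [&](const std::vector<uint8_t>& mat) {
    std::fill(packed.begin(), packed.end(), 0ULL);
    for (int i = 0; i < n; ++i) {
      const uint8_t* row = &mat[(size_t)i * m];
      uint64_t* prow = &packed[(size_t)i * words];
      for (int j = 0; j < m; ++j)
        if (row[j]) prow[j >> 6] |= (1ULL << (j & 63));
    }
  };
  auto row_dot = [&](int r1, int r2) {
    const uint64_t* a = &packed[(size_t)r1 * words];
    const uint64_t* b = &packed[(size_t)r2 * words];
    long long w = 0;
    for (int t = 0; t < words; ++t) w += __builtin_popcountll(a[t] & b[t]);
    return (double)w;
  };

  NumericVector edge_obs(n_edge);
  {
    Chain ch0;
    ch0.init(inc);
    pack_rows(ch0.mat);
    for (int e = 0; e < n_edge; ++e)
      edge_obs[e] = row_dot(edge_r1[e], edge_r2[e]);
  }

  NumericMatrix group_null(n_perm, n_stat);
  IntegerVector edge_exceed(n_edge);
  IntegerMatrix seg_exceed(want_segments ? m : 0,
                           want_segments ? n_disease : 0);
  NumericVector succ(n_perm);

  Chain base;
  base.init(inc);
  std::vector<int> k((size_t)n_block * m);

  for (int p = 0; p < n_perm; ++p) {
    Chain ch = base; // fresh chain from the original incidence
    ch.successes = 0;
    k = k0;
    XS128 rng((uint64_t)seed + 0x5DEECE66DULL * (uint64_t)(p + 1));
    ch.run(rng, (long long)attempts, &k, &row_block[0]);
    succ[p] = (double)ch.successes;
    for (int s = 0; s < n_stat; ++s) group_null(p, s) = group_stat(k, s);
    if (n_edge > 0) {
      pack_rows(ch.mat);
      for (int e = 0; e < n_edge; ++e)
        if (row_dot(edge_r1[e], edge_r2[e]) >= edge_obs[e]) edge_exceed[e]++;
    }
    if (want_segments) {
      for (int d = 0; d < n_disease; ++d) {
        disease_counts(k, d);
        for (int j = 0; j < m; ++j)
          if (choose2(kd[j]) >= seg_obs(j, d)) seg_exceed(j, d)++;
      }
    }
    if ((p & 31) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["group_obs"] = group_obs,
                      _["group_null"] = group_null,
                      _["edge_obs"] = edge_obs,
                      _["edge_exceed"] = edge_exceed,
                      _["seg_obs"] = seg_obs,
                      _["seg_exceed"] = seg_exceed,
                      _["successes"] = succ);
}
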