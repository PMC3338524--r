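#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simulate neutral alignments on a fixed tree and pool the per-column
// divergence scores at one node partition.  This is the hot loop of the
// null calibration: everything is gap-free, so every column is scorable.
//
// edge:       (nedge x 2) parent/child node ids, 1-based, parents before
//             children (cladewise order); root = ntip + 1.
// cum_probs:  20 x (20 * ncat * nedge) matrix; column block for edge e,
//             category c, parent state s is cumulative transition
//             probabilities to the 20 child states.
// root_cum:   cumulative equilibrium frequencies (length 20).
// rows_a/b/o: 1-based tip indices of clade A, clade B, outgroup.
// blosum:     20 x 20 substitution scores.
// n_reps:     number of replicate alignments.
// L:          columns per replicate.
//
// Returns a numeric vector of n_reps * L pooled scores.  Uses R's RNG,
// so results are reproducible with set.seed().
// [[Rcpp::export]]
NumericVector null_fd_pool(IntegerMatrix edge, int n_nodes, int ntip,
                           NumericMatrix cum_probs, NumericVector root_cum,
                           IntegerVector rows_a, IntegerVector rows_b,
                           IntegerVector rows_o, NumericMatrix blosum,
                           int ncat, int n_reps, int L, double se_floor) {
  const int nedge = edge.nrow();
  const int root = ntip;            // 0-based root index = ntip
  const int na = rows_a.size(), nb = rows_b.size(), no = rows_o.size();
  NumericVector out((R_xlen_t)n_reps * L);
  std::vector<int> states((size_t)n_nodes * L);
  std::vector<int> cats(L);
  R_xlen_t pos = 0;

  for (int rep = 0; rep < n_reps; ++rep) {
    // per-site rate categories, equal probability
    for (int j = 0; j < L; ++j)
      cats[j] = (int)(unif_rand() * ncat) % ncat;
    // root states from equilibrium frequencies
    for (int j = 0; j < L; ++j) {
      double u = unif_rand();
      int s = 0;
      while (s < 19 && u > root_cum[s]) ++s;
      states[(size_t)root * L + j] = s;
    }
    // evolve along each branch
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1, child = edge(e, 1) - 1;
      const int *ps = &states[(size_t)par * L];
      int *cs = &states[(size_t)child * L];
      for (int j = 0; j < L; ++j) {
        const int col = (e * ncat + cats[j]) * 20 + ps[j];
        const double *cum = &cum_probs(0, col);
        double u = unif_rand();
        int s = 0;
        while (s < 19 && u > cum[s]) ++s;
        cs[j] = s;
      }
    }
    // score each column at the partition
    for (int j = 0; j < L; ++j) {
      double s1 = 0, ss1 = 0, s2 = 0, ss2 = 0;
      for (int i = 0; i < na; ++i) {
        const int ai = states[(size_t)(rows_a[i] - 1) * L + j];
        for (int k = 0; k < no; ++k) {
          const double x = blosum(ai, states[(size_t)(rows_o[k] - 1) * L + j]);
          s1 += x; ss1 += x * x;
        }
      }
      for (int i = 0; i < nb; ++i) {
        const int bi = states[(size_t)(rows_b[i] - 1) * L + j];
        for (int k = 0; k < no; ++k) {
          const double x = blosum(bi, states[(size_t)(rows_o[k] - 1) * L + j]);
          s2 += x; ss2 += x * x;
        }
      }
      const int n1 = na * no, n2 = nb * no;
      const double m1 = s1 / n1, m2 = s2 / n2;
      double fd = 0.0;
      if (m1 != m2) {
        double v1 = n1 > 1 ? (ss1 - n1 * m1 * m1) / (n1 - 1) : 0.0;
        double v2 = n2 > 1 ? (ss2 - n2 * m2 * m2) / (n2 - 1) : 0.0;
        if (v1 < 0) v1 = 0;
        if (v2 < 0) v2 = 0;
        double se = std::sqrt(v1 / n1 + v2 / n2);
        if (se < se_floor) se = se_floor;
        fd = std::fabs(m1 - m2) / se;
      }
      out[pos++] = fd;
    }
  }
  return out;
}
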