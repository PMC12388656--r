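#include <Rcpp.h>
using namespace Rcpp;

// Accumulate mean and sd of betaMNTD over tip-shuffle nulls.
//
// Fw:    S x T abundance weights (rows sum to 1 over present taxa)
// pres:  S x T presence indicators
// D:     T x T patristic distances
// perms: R x T permutations (1-based), one tip shuffle per row
//
// For each shuffle, betaMNTD(k, l) = 1/2 [ sum_{i in k} Fw[k,i] m(i, l)
//                                        + sum_{j in l} Fw[l,j] m(j, k) ]
// with m(i, l) = min_{j in l} D[perm(i), perm(j)]. Only taxa present in
// at least one sample contribute, so mins are evaluated on that union.
// [[Rcpp::export(name = ".bmntd_null_cpp")]]
List bmntd_null_cpp(NumericMatrix Fw, LogicalMatrix pres, NumericMatrix D,
                    IntegerMatrix perms) {
  const int S = Fw.nrow();
  const int T = Fw.ncol();
  const int R = perms.nrow();

  std::vector< std::vector<int> > plist(S);
  std::vector<bool> in_union(T, false);
  for (int s = 0; s < S; ++s)
    for (int t = 0; t < T; ++t)
      if (pres(s, t)) { plist[s].push_back(t); in_union[t] = true; }
  std::vector<int> uni;
  std::vector<int> upos(T, -1);
  for (int t = 0; t < T; ++t)
    if (in_union[t]) { upos[t] = (int)uni.size(); uni.push_back(t); }
  const int U = (int)uni.size();

  NumericMatrix s1(S, S), s2(S, S);
  std::vector<double> M((size_t)U * S);
  std::vector<double> B((size_t)S * S);
  const double* Dp = REAL(D);

  for (int r = 0; r < R; ++r) {
    for (int l = 0; l < S; ++l) {
      const std::vector<int>& pl = plist[l];
      for (int u = 0; u < U; ++u) {
        const size_t pi = (size_t)(perms(r, uni[u]) - 1);
        double best = R_PosInf;
        for (size_t q = 0; q < pl.size(); ++q) {
          const size_t pj = (size_t)(perms(r, pl[q]) - 1);
          const double v = Dp[pi + (size_t)T * pj];
          if (v < best) best = v;
        }
        M[(size_t)u + (size_t)U * l] = best;
      }
    }
    for (int k = 0; k < S; ++k) {
      const std::vector<int>& pk = plist[k];
      for (int l = 0; l < S; ++l) {
        double acc = 0.0;
        for (size_t q = 0; q < pk.size(); ++q)
          acc += Fw(k, pk[q]) * M[(size_t)upos[pk[q]] + (size_t)U * l];
        B[(size_t)k + (size_t)S * l] = acc;
      }
    }
    for (int k = 0; k < S; ++k)
      for (int l = 0; l < S; ++l) {
        const double b = 0.5 * (B[(size_t)k + (size_t)S * l] +
                                B[(size_t)l + (size_t)S * k]);
        s1(k, l) += b;
        s2(k, l) += b * b;
      }
  }
  return List::create(_["sum"] = s1, _["sumsq"] = s2, _["n"] = R);
}
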