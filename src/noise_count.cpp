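#include <Rcpp.h>
using namespace Rcpp;

// Count, for each signal point (m[i], d[i]), the noise points strictly
// dominated in both coordinates: |M*| < m and D* < d.  Noise points are
// sorted by |M*| once so each signal point scans a prefix; the prefix's
// D* values still need a linear pass, giving O(G * N) worst case with a
// small constant -- fast enough for study-scale clouds.
// [[Rcpp::export(name = ".countDominatedNoise")]]
NumericVector countDominatedNoise(NumericVector noiseM, NumericVector noiseD,
                                  NumericVector m, NumericVector d) {
  const R_xlen_t n = noiseM.size(), g = m.size();
  NumericVector out(g);
  if (n == 0) return out;
  // sort noise by |M*|
  std::vector<R_xlen_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](R_xlen_t a, R_xlen_t b) {
    return noiseM[a] < noiseM[b];
  });
  std::vector<double> sm(n), sd(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    sm[i] = noiseM[ord[i]];
    sd[i] = noiseD[ord[i]];
  }
  for (R_xlen_t i = 0; i < g; ++i) {
    const double mi = m[i], di = d[i];
    // prefix of noise with |M*| < mi
    R_xlen_t hi = std::lower_bound(sm.begin(), sm.end(), mi) - sm.begin();
    double cnt = 0;
    for (R_xlen_t j = 0; j < hi; ++j)
      if (sd[j] < di) cnt += 1;
    out[i] = cnt;
  }
  return out;
}
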