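#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement on a channel x bin statistic map.
//
// For each sign separately, TFCE(cell) = sum_h e(h)^E * h^H * dh over
// thresholds h = dh, 2*dh, ... up to the map maximum, where e(h) is the
// number of cells in the supra-threshold connected component containing the
// cell. Connectivity: adjacent channel at the same bin, or same channel at an
// adjacent (+/- 1) bin. NA cells are excluded from components and returned
// as NA. dh <= 0 requests the adaptive step max/100 (per sign).
//
// nbrs: list, one integer vector per channel of 0-based neighbouring
// channel indices (symmetric).
// [[Rcpp::export]]
NumericMatrix tfce_enhance_cpp(NumericMatrix tmap, List nbrs,
                               double E, double H, double dh) {
  const int nch = tmap.nrow(), nb = tmap.ncol(), ncell = nch * nb;
  NumericMatrix out(nch, nb);
  std::vector< std::vector<int> > adj(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = nbrs[c];
    adj[c].assign(v.begin(), v.end());
  }
  std::vector<char> excluded(ncell, 0);
  for (int i = 0; i < ncell; ++i)
    if (NumericMatrix::is_na(tmap[i])) excluded[i] = 1;

  std::vector<int> stamp(ncell, -1);
  std::vector<int> stack, members;
  int iter = 0;

  for (int sign = 0; sign < 2; ++sign) {
    std::vector<double> s(ncell, 0.0);
    double hmax = 0.0;
    for (int i = 0; i < ncell; ++i) {
      if (excluded[i]) continue;
      double v = (sign == 0) ? tmap[i] : -tmap[i];
      if (v > 0.0) s[i] = v;
      if (s[i] > hmax) hmax = s[i];
    }
    if (hmax <= 0.0) continue;
    const double step = (dh > 0.0) ? dh : hmax / 100.0;
    const int K = (int) std::floor(hmax / step + 1e-9);

    for (int k = 1; k <= K; ++k) {
      const double h = k * step;
      ++iter;
      for (int c0 = 0; c0 < ncell; ++c0) {
        if (excluded[c0] || s[c0] < h || stamp[c0] == iter) continue;
        // BFS the component containing c0
        members.clear();
        stack.clear();
        stack.push_back(c0);
        stamp[c0] = iter;
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          members.push_back(cur);
          int ch = cur % nch, bin = cur / nch;
          // same channel, adjacent bin
          if (bin > 0) {
            int nxt = cur - nch;
            if (!excluded[nxt] && s[nxt] >= h && stamp[nxt] != iter) {
              stamp[nxt] = iter; stack.push_back(nxt);
            }
          }
          if (bin < nb - 1) {
            int nxt = cur + nch;
            if (!excluded[nxt] && s[nxt] >= h && stamp[nxt] != iter) {
              stamp[nxt] = iter; stack.push_back(nxt);
            }
          }
          // adjacent channel, same bin
          for (size_t a = 0; a < adj[ch].size(); ++a) {
            int nxt = adj[ch][a] + bin * nch;
            if (!excluded[nxt] && s[nxt] >= h && stamp[nxt] != iter) {
              stamp[nxt] = iter; stack.push_back(nxt);
            }
          }
        }
        const double add = std::pow((double) members.size(), E) *
                           std::pow(h, H) * step;
        const double signed_add = (sign == 0) ? add : -add;
        for (size_t mI = 0; mI < members.size(); ++mI)
          out[members[mI]] += signed_add;
      }
    }
  }
  for (int i = 0; i < ncell; ++i)
    if (excluded[i]) out[i] = NA_REAL;
  return out;
}
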