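#include <Rcpp.h>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Banded global edit distance (unit costs) between one query and one
// reference, both already truncated by the caller to the same semantics
// (here: to the shorter of the two lengths).  Distances within the band are
// exact; anything larger is reported as the cap band + 1.
static int banded_dist(const char *a, int n, const char *b, int m, int band) {
  if (band < 0) band = 0;
  const int INF = band + 1;
  if (std::abs(n - m) > band) return INF;
  // rolling rows over the band: column window for row i is [i-band, i+band]
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // row i = 0: dp[0][j] = j for j in [0, min(band, m)]; offsets outside stay INF
  for (int k = 0; k <= band && k <= m; ++k) prev[band + k] = k;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int off = 0; off < 2 * band + 1; ++off) cur[off] = INF;
    for (int j = jlo; j <= jhi; ++j) {
      int off = band + (j - i); // in [0, 2*band]
      int best = INF;
      if (j > 0 && off - 1 >= 0 && cur[off - 1] < best) best = cur[off - 1]; // insertion (j-1, same i)
      // deletion: dp[i-1][j] -> offset in prev is band + (j - (i-1)) = off + 1
      if (off + 1 <= 2 * band && prev[off + 1] < best) best = prev[off + 1];
      if (best != INF) best += 1;
      if (j > 0) {
        int diag = prev[off]; // dp[i-1][j-1]
        int sub = diag + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (sub < best) best = sub;
      } else {
        // j == 0: dp[i][0] = i (only deletions)
        best = std::min(best, i);
      }
      cur[off] = std::min(best, INF);
    }
    std::swap(prev, cur);
  }
  int off = band + (m - n);
  int d = prev[off];
  return d > band ? INF : d;
}

// [[Rcpp::export(name = ".edit_distance_banded")]]
IntegerVector edit_distance_banded_cpp(CharacterVector query, std::string ref,
                                       int band, bool truncate_to_shorter) {
  int nq = query.size();
  IntegerVector out(nq);
  const char *r = ref.c_str();
  int rlen = (int)ref.size();
  for (int i = 0; i < nq; ++i) {
    if (query[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *q = CHAR(STRING_ELT(query, i));
    int qlen = (int)LENGTH(STRING_ELT(query, i));
    int n = qlen, m = rlen;
    if (truncate_to_shorter) {
      int mm = std::min(n, m);
      n = mm; m = mm;
    }
    out[i] = banded_dist(q, n, r, m, band);
  }
  return out;
}

// Hamming distance of each string against a single reference of equal
// length; -1 where lengths differ.
// [[Rcpp::export(name = ".hamming_to_ref")]]
IntegerVector hamming_to_ref_cpp(CharacterVector x, std::string ref) {
  int nx = x.size();
  int m = (int)ref.size();
  const char *r = ref.c_str();
  IntegerVector out(nx);
  for (int i = 0; i < nx; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(x, i));
    if ((int)LENGTH(STRING_ELT(x, i)) != m) { out[i] = -1; continue; }
    int d = 0;
    for (int k = 0; k < m; ++k) d += (s[k] != r[k]);
    out[i] = d;
  }
  return out;
}
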