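#include <Rcpp.h>
#include <string>
#include <vector>
#include <cctype>
#include <cmath>

// Needleman-Wunsch global alignment with linear gap costs, returning the
// fraction of identical columns after trimming terminal-gap columns.
//
// Scoring: +match for an exact uppercase character match where both
// characters are unambiguous bases (A/C/G/T), otherwise `mismatch`; each
// gap column costs `gap`. Ambiguity codes therefore never score as (or
// count as) identical columns.
//
// Ties among optimal alignments are broken during traceback by a fixed
// preference order evaluated at every cell: diagonal (match/mismatch)
// first, then a gap in `a` (consuming a character of `b`), then a gap in
// `b`. This makes the reported identity deterministic.
//
// The hot path is an integer DP (the default scoring is integral); when a
// non-integral scoring is configured the scores are rescaled to integers
// when an exact common denominator <= 1000 exists, else scaled by 10^6
// (documented approximation, identical in practice).

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static long to_scaled_int(double x, long scale) {
  return (long)std::llround(x * (double)scale);
}

static double identity_core(const std::string& a, const std::string& b,
                            long match, long mismatch, long gap) {
  const int m = (int)a.size(), n = (int)b.size();
  const int W = n + 1;
  std::vector<long> prev((size_t)W), cur((size_t)W);
  // traceback pointers: 0 = diagonal, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<unsigned char> tb((size_t)(m + 1) * W);

  prev[0] = 0;
  for (int j = 1; j <= n; ++j) {
    prev[j] = prev[j - 1] + gap;
    tb[j] = 2;
  }
  for (int i = 1; i <= m; ++i) {
    long* p = prev.data();
    long* c = cur.data();
    unsigned char* t = tb.data() + (size_t)i * W;
    c[0] = p[0] + gap;
    t[0] = 1;
    const char ai = a[i - 1];
    const bool ai_base = is_base(ai);
    for (int j = 1; j <= n; ++j) {
      const bool eq = ai_base && (ai == b[j - 1]);
      long best = p[j - 1] + (eq ? match : mismatch);
      unsigned char ptr = 0;
      const long left = c[j - 1] + gap;   // gap in a
      if (left > best) { best = left; ptr = 2; }
      const long up = p[j] + gap;         // gap in b
      if (up > best) { best = up; ptr = 1; }
      c[j] = best;
      t[j] = ptr;
    }
    std::swap(prev, cur);
  }

  // traceback: collect column types and identity flags (in reverse)
  std::vector<unsigned char> gapcol;  // 1 if column has a gap
  std::vector<unsigned char> ident;   // 1 if identical base column
  gapcol.reserve(m + n);
  ident.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char ptr = tb[(size_t)i * W + j];
    if (i == 0) ptr = 2;
    else if (j == 0) ptr = 1;
    if (ptr == 0) {
      const bool eq = is_base(a[i - 1]) && (a[i - 1] == b[j - 1]);
      gapcol.push_back(0);
      ident.push_back(eq ? 1 : 0);
      --i; --j;
    } else if (ptr == 1) {
      gapcol.push_back(1);
      ident.push_back(0);
      --i;
    } else {
      gapcol.push_back(1);
      ident.push_back(0);
      --j;
    }
  }
  // columns are in reverse order; trim terminal-gap columns at both ends
  int L = (int)gapcol.size();
  int lo = 0, hi = L - 1;  // hi end of the reversed vector = alignment start
  while (hi >= 0 && gapcol[hi]) --hi;
  while (lo <= hi && gapcol[lo]) ++lo;
  int ncol = hi - lo + 1;
  if (ncol <= 0) return 0.0;
  int nid = 0;
  for (int k = lo; k <= hi; ++k) nid += ident[k];
  return (double)nid / (double)ncol;
}

// [[Rcpp::export]]
double cpp_global_identity(std::string a, std::string b,
                           double match, double mismatch, double gap) {
  const size_t m = a.size(), n = b.size();
  if (m == 0 || n == 0) Rcpp::stop("empty sequence");
  for (size_t i = 0; i < m; ++i) a[i] = (char)std::toupper((unsigned char)a[i]);
  for (size_t j = 0; j < n; ++j) b[j] = (char)std::toupper((unsigned char)b[j]);
  long scale = 1;
  for (; scale <= 1000; ++scale) {
    double e1 = match * scale, e2 = mismatch * scale, e3 = gap * scale;
    if (e1 == std::floor(e1) && e2 == std::floor(e2) && e3 == std::floor(e3))
      break;
  }
  if (scale > 1000) scale = 1000000;
  return identity_core(a, b, to_scaled_int(match, scale),
                       to_scaled_int(mismatch, scale),
                       to_scaled_int(gap, scale));
}
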