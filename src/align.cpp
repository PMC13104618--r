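#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (end-gap penalized) pairwise alignment with affine gap costs.
// A gap of length L costs open + L * extend.  Traceback is deterministic:
// on ties the match/mismatch state wins over a gap in the second sequence
// ("up", consuming a), which wins over a gap in the first ("left").

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  CharacterVector alphabet, double gap_open,
                  double gap_extend) {
  const int n = a.size();
  const int m = b.size();

  // residue -> submat index
  std::vector<int> lookup(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string s = as<std::string>(alphabet[k]);
    lookup[(unsigned char)s[0]] = k;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) ai[i] = lookup[(unsigned char)a[i]];
  for (int j = 0; j < m; ++j) bi[j] = lookup[(unsigned char)b[j]];

  // flat row-major copy of the substitution matrix for fast access
  const int na = alphabet.size();
  std::vector<double> sm(na * na);
  for (int r = 0; r < na; ++r)
    for (int c = 0; c < na; ++c) sm[r * na + c] = submat(r, c);

  const double go = gap_open + gap_extend;  // cost of first gap column
  const double ge = gap_extend;

  // state 0 = M (diagonal), 1 = X (gap in b, consume a), 2 = Y (gap in a)
  const int ncol = m + 1;
  std::vector<double> M((n + 1) * ncol, NEG_INF), X((n + 1) * ncol, NEG_INF),
      Y((n + 1) * ncol, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * ncol] = -(gap_open + i * ge);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * ge);

  for (int i = 1; i <= n; ++i) {
    const int r = i * ncol, p = (i - 1) * ncol;
    const double *srow = &sm[ai[i - 1] * na];
    for (int j = 1; j <= m; ++j) {
      const double s = srow[bi[j - 1]];
      double best = M[p + j - 1];
      if (X[p + j - 1] > best) best = X[p + j - 1];
      if (Y[p + j - 1] > best) best = Y[p + j - 1];
      M[r + j] = best + s;

      double x = M[p + j] - go;
      if (X[p + j] - ge > x) x = X[p + j] - ge;
      if (Y[p + j] - go > x) x = Y[p + j] - go;
      X[r + j] = x;

      double y = M[r + j - 1] - go;
      if (X[r + j - 1] - go > y) y = X[r + j - 1] - go;
      if (Y[r + j - 1] - ge > y) y = Y[r + j - 1] - ge;
      Y[r + j] = y;
    }
  }

  // traceback, tie-break M > X > Y at every decision
  int i = n, j = m;
  int state;
  {
    const int r = n * ncol + m;
    double sc = M[r];
    state = 0;
    if (X[r] > sc) { sc = X[r]; state = 1; }
    if (Y[r] > sc) { sc = Y[r]; state = 2; }
  }
  const double score = (state == 0) ? M[n * ncol + m]
                       : (state == 1) ? X[n * ncol + m]
                                      : Y[n * ncol + m];

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  while (i > 0 || j > 0) {
    const int r = i * ncol + j;
    if (state == 0) {
      // came into M via diagonal step
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      const double need = M[r] - submat(ai[i - 1], bi[j - 1]);
      const int p = (i - 1) * ncol + (j - 1);
      if (M[p] == need) state = 0;
      else if (X[p] == need) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      const int p = (i - 1) * ncol + j;
      if (i == 1 && j == 0) { --i; break; }
      if (M[p] == X[r] + go) state = 0;
      else if (X[p] == X[r] + ge) state = 1;
      else state = 2;
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      const int p = i * ncol + (j - 1);
      if (i == 0 && j == 1) { --j; break; }
      if (M[p] == Y[r] + go) state = 0;
      else if (X[p] == Y[r] + go) state = 1;
      else state = 2;
      --j;
    }
  }
  // flush any remaining leading gaps
  while (i > 0) { ra.push_back(a[--i]); rb.push_back('-'); }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[--j]); }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int identities = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && ra[k] != '-' && ra[k] != 'X') ++identities;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score, _["identities"] = identities,
                      _["columns"] = (int)ra.size());
}
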