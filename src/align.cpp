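#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Gotoh three-state global alignment with affine gaps.
//
// Gap convention: a run of L gapped columns costs gap_open +
// (L - 1) * gap_extend. With free_end_gaps, the leading gap run (the
// maximal same-direction run at the start of the alignment) and the
// trailing run cost nothing and their columns are excluded from the
// identity denominator ("identity over the aligned region").
//
// Tie-breaking is deterministic: at the end cell and during traceback
// the match/mismatch state is preferred over a gap in the second
// sequence (up), which is preferred over a gap in the first (left).

static const double NEG_INF = -1e300;

// state codes: 0 = M (diagonal), 1 = X (gap in b, consumes a, "up"),
//              2 = Y (gap in a, consumes b, "left")

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // ptr[s][idx]: predecessor state of state s at cell idx
  std::vector<uint8_t> pM((n + 1) * W), pX((n + 1) * W), pY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = free_end_gaps ? 0.0 : gap_open + (i - 1) * gap_extend;
    pX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = free_end_gaps ? 0.0 : gap_open + (j - 1) * gap_extend;
    pY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t idx = i * W + j, dg = (i - 1) * W + (j - 1),
                   up = (i - 1) * W + j, lf = i * W + (j - 1);
      const char ca = a[i - 1], cb = b[j - 1];
      const double s = (ca == cb && ca != 'N') ? match : mismatch;
      // M: preference M > X > Y on ties
      double best = M[dg]; uint8_t arg = 0;
      if (X[dg] > best) { best = X[dg]; arg = 1; }
      if (Y[dg] > best) { best = Y[dg]; arg = 2; }
      M[idx] = best + s; pM[idx] = arg;
      // X (gap in b): open from M/Y, extend from X
      best = M[up] + gap_open; arg = 0;
      if (X[up] + gap_extend > best) { best = X[up] + gap_extend; arg = 1; }
      if (Y[up] + gap_open > best) { best = Y[up] + gap_open; arg = 2; }
      X[idx] = best; pX[idx] = arg;
      // Y (gap in a)
      best = M[lf] + gap_open; arg = 0;
      if (X[lf] + gap_open > best) { best = X[lf] + gap_open; arg = 1; }
      if (Y[lf] + gap_extend > best) { best = Y[lf] + gap_extend; arg = 2; }
      Y[idx] = best; pY[idx] = arg;
    }
  }

  // choose end cell; with free end gaps the best may sit anywhere on the
  // last row/column, the remainder being an unpenalized overhang
  int ei = n, ej = m;
  const size_t endidx = n * W + m;
  double score = M[endidx]; uint8_t estate = 0;
  if (X[endidx] > score) { score = X[endidx]; estate = 1; }
  if (Y[endidx] > score) { score = Y[endidx]; estate = 2; }
  if (free_end_gaps) {
    // prefer (n, m); then larger i along last column, larger j along last
    // row; i = 0 / j = 0 cover alignments where one sequence is entirely
    // leading overhang and the other entirely trailing
    for (int i = n - 1; i >= 0; --i) {
      const size_t idx = i * W + m;
      double c = M[idx]; uint8_t st = 0;
      if (X[idx] > c) { c = X[idx]; st = 1; }
      if (Y[idx] > c) { c = Y[idx]; st = 2; }
      if (c > score) { score = c; estate = st; ei = i; ej = m; }
    }
    for (int j = m - 1; j >= 0; --j) {
      const size_t idx = n * W + j;
      double c = M[idx]; uint8_t st = 0;
      if (X[idx] > c) { c = X[idx]; st = 1; }
      if (Y[idx] > c) { c = Y[idx]; st = 2; }
      if (c > score) { score = c; estate = st; ei = n; ej = j; }
    }
  }

  // traceback from (ei, ej)
  std::string aln_a, aln_b;
  {
    // trailing overhang (free end gaps only)
    for (int i = n; i > ei; --i) { aln_a += a[i - 1]; aln_b += '-'; }
    for (int j = m; j > ej; --j) { aln_a += '-'; aln_b += b[j - 1]; }
    int i = ei, j = ej; uint8_t st = estate;
    while (i > 0 || j > 0) {
      const size_t idx = i * W + j;
      if (st == 0) {
        aln_a += a[i - 1]; aln_b += b[j - 1];
        st = pM[idx]; --i; --j;
      } else if (st == 1) {
        aln_a += a[i - 1]; aln_b += '-';
        st = pX[idx]; --i;
      } else {
        aln_a += '-'; aln_b += b[j - 1];
        st = pY[idx]; --j;
      }
    }
    std::reverse(aln_a.begin(), aln_a.end());
    std::reverse(aln_b.begin(), aln_b.end());
  }

  // identity: matches / columns, excluding terminal overhang runs
  const int L = aln_a.size();
  int lead = 0, trail = 0;
  if (free_end_gaps) {
    if (aln_a[0] == '-' || aln_b[0] == '-') {
      const bool ga = aln_a[0] == '-';
      while (lead < L && (ga ? aln_a[lead] : aln_b[lead]) == '-') ++lead;
    }
    if (aln_a[L - 1] == '-' || aln_b[L - 1] == '-') {
      const bool ga = aln_a[L - 1] == '-';
      while (trail < L - lead &&
             (ga ? aln_a[L - 1 - trail] : aln_b[L - 1 - trail]) == '-')
        ++trail;
    }
  }
  int matches = 0, columns = 0;
  for (int k = lead; k < L - trail; ++k) {
    ++columns;
    if (aln_a[k] == aln_b[k] && aln_a[k] != '-' && aln_a[k] != 'N') ++matches;
  }

  return List::create(
      _["score"] = score, _["matches"] = matches, _["columns"] = columns,
      _["identity"] = columns > 0 ? 100.0 * matches / columns : 0.0,
      _["aligned_a"] = aln_a, _["aligned_b"] = aln_b);
}

// proportion of differing sites between equal-length sequences
// [[Rcpp::export]]
NumericMatrix p_distance_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  const size_t L = s[0].size();
  for (int i = 1; i < n; ++i)
    if (s[i].size() != L) stop("sequences must have equal length");
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      size_t diff = 0;
      for (size_t k = 0; k < L; ++k)
        if (s[i][k] != s[j][k]) ++diff;
      out(i, j) = out(j, i) = double(diff) / L;
    }
  return out;
}
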