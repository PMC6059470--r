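#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment machinery shared by the progressive aligner
// (profile-profile merges on a precomputed column-score matrix) and the
// pairwise search used for best-match identification.
//
// Gap model: a run of k gap columns costs gap_open + (k - 1) * gap_ext
// (both passed as positive numbers). State preference on ties is
// M (diagonal) > X (consume A) > Y (consume B), which makes the traceback
// deterministic.

static const double NEG_INF = -1e18;

struct NWResult {
  std::vector<int> path_a; // 1-based column index in A, 0 = gap
  std::vector<int> path_b;
  double score;
};

static NWResult affine_nw(const NumericMatrix &S, double gap_open,
                          double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  // state 0 = M (diagonal), 1 = X (gap in B, consume A), 2 = Y (consume B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = NEG_INF;
  Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    Y(i, 0) = NEG_INF;
    X(i, 0) = -gap_open - (i - 1) * gap_ext;
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = -gap_open - (j - 1) * gap_ext;
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal extension from any state
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      int st = 0;
      double best = dm;
      if (dx > best) { best = dx; st = 1; }
      if (dy > best) { best = dy; st = 2; }
      M(i, j) = best + S(i - 1, j - 1);
      tbM(i, j) = st;

      // X: consume a column of A against a gap
      double xm = M(i - 1, j) - gap_open;
      double xx = X(i - 1, j) - gap_ext;
      double xy = Y(i - 1, j) - gap_open;
      st = 0; best = xm;
      if (xx > best) { best = xx; st = 1; }
      if (xy > best) { best = xy; st = 2; }
      X(i, j) = best;
      tbX(i, j) = st;

      // Y: consume a column of B against a gap
      double ym = M(i, j - 1) - gap_open;
      double yx = X(i, j - 1) - gap_open;
      double yy = Y(i, j - 1) - gap_ext;
      st = 0; best = ym;
      if (yx > best) { best = yx; st = 1; }
      if (yy > best) { best = yy; st = 2; }
      Y(i, j) = best;
      tbY(i, j) = st;
    }
  }

  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  NWResult res;
  res.score = best;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      res.path_a.push_back(i);
      res.path_b.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      res.path_a.push_back(i);
      res.path_b.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tbY(i, j);
      res.path_a.push_back(0);
      res.path_b.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(res.path_a.begin(), res.path_a.end());
  std::reverse(res.path_b.begin(), res.path_b.end());
  return res;
}

// [[Rcpp::export]]
List profile_nw_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  NWResult r = affine_nw(S, gap_open, gap_ext);
  return List::create(_["path_a"] = wrap(r.path_a),
                      _["path_b"] = wrap(r.path_b),
                      _["score"] = r.score);
}

// Global affine alignment of two integer-coded sequences (1..4 = ACGT,
// 0 = ambiguity/other). Returns alignment statistics with end gaps
// excluded from the identity denominator (semi-global identity
// convention): matches / aligned columns between the first and last
// column where both sequences have a residue.
// [[Rcpp::export]]
List pair_align_stats_cpp(IntegerVector a, IntegerVector b, double match,
                          double mismatch, double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      S(i, j) = (a[i] > 0 && a[i] == b[j]) ? match : mismatch;
  NWResult r = affine_nw(S, gap_open, gap_ext);

  const int L = (int)r.path_a.size();
  int first = -1, last = -1;
  for (int c = 0; c < L; ++c) {
    if (r.path_a[c] > 0 && r.path_b[c] > 0) {
      if (first < 0) first = c;
      last = c;
    }
  }
  int matches = 0, aligned_cols = 0, a_span = 0, b_span = 0;
  if (first >= 0) {
    for (int c = first; c <= last; ++c) {
      ++aligned_cols;
      int ia = r.path_a[c], ib = r.path_b[c];
      if (ia > 0) ++a_span;
      if (ib > 0) ++b_span;
      if (ia > 0 && ib > 0 && a[ia - 1] > 0 && a[ia - 1] == b[ib - 1])
        ++matches;
    }
  }
  return List::create(_["matches"] = matches,
                      _["aligned_cols"] = aligned_cols,
                      _["a_span"] = a_span,
                      _["b_span"] = b_span,
                      _["total_cols"] = L,
                      _["score"] = r.score);
}

// Transition/transversion/site counts for every pair of rows of an
// integer-coded alignment (1 = A, 2 = C, 3 = G, 4 = T; 0 = gap or
// ambiguity, excluded pairwise). Purines {A, G}, pyrimidines {C, T}.
// [[Rcpp::export]]
List k2p_counts_cpp(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix ts(n, n), tv(n, n), ns(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int cts = 0, ctv = 0, cn = 0;
      for (int s = 0; s < L; ++s) {
        int x = seqs(i, s), y = seqs(j, s);
        if (x == 0 || y == 0) continue;
        ++cn;
        if (x != y) {
          bool xpur = (x == 1 || x == 3), ypur = (y == 1 || y == 3);
          if (xpur == ypur) ++cts; else ++ctv;
        }
      }
      ts(i, j) = ts(j, i) = cts;
      tv(i, j) = tv(j, i) = ctv;
      ns(i, j) = ns(j, i) = cn;
    }
  }
  return List::create(_["transitions"] = ts, _["transversions"] = tv,
                      _["n_sites"] = ns);
}
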