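#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Ends-free (overlap) pairwise alignment with affine gap penalties, the
// BLAST-like identity convention for near-full-length marker genes:
// identity = matches / alignment columns, where columns cover only the
// aligned region (terminal gaps are free and excluded). A gap of length L
// costs gap_open + L * gap_ext, matching the usual convention of alignment
// libraries. Traceback prefers substitution over a gap in the second
// sequence over a gap in the first, so results are deterministic.
//
// States: 0 = M (aligned pair), 1 = Ix (gap in b, consumes a), 2 = Iy.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_overlap_cpp")]]
List align_overlap_cpp(std::string a, std::string b,
                       double match = 1.0, double mismatch = -2.0,
                       double gap_open = 10.0, double gap_ext = 1.0) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  // traceback: predecessor state of each cell, -1 = alignment starts here
  std::vector<signed char> tbM((n + 1) * (m + 1), -2);
  std::vector<signed char> tbX((n + 1) * (m + 1), -2);
  std::vector<signed char> tbY((n + 1) * (m + 1), -2);

#define IDX(i, j) ((i) * (m + 1) + (j))

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      bool amb = (ca == 'N' || cb == 'N');
      double sub = (!amb && ca == cb) ? match : mismatch;

      // M: diagonal predecessor; free start when a prefix of one sequence
      // is skipped entirely (boundary cell)
      double bestp;
      signed char from;
      if (i == 1 || j == 1) { bestp = 0.0; from = -1; }
      else { bestp = NEG_INF; from = -2; }
      int p = IDX(i - 1, j - 1);
      if (M[p] > bestp) { bestp = M[p]; from = 0; }
      if (Ix[p] > bestp) { bestp = Ix[p]; from = 1; }
      if (Iy[p] > bestp) { bestp = Iy[p]; from = 2; }
      M[IDX(i, j)] = bestp + sub;
      tbM[IDX(i, j)] = from;

      // Ix: gap in b (consume a[i])
      if (i >= 2) {
        int q = IDX(i - 1, j);
        double o = M[q] - (gap_open + gap_ext);
        double e = Ix[q] - gap_ext;
        double y = Iy[q] - (gap_open + gap_ext);
        if (o >= e && o >= y) { Ix[IDX(i, j)] = o; tbX[IDX(i, j)] = 0; }
        else if (e >= y)      { Ix[IDX(i, j)] = e; tbX[IDX(i, j)] = 1; }
        else                  { Ix[IDX(i, j)] = y; tbX[IDX(i, j)] = 2; }
      }
      // Iy: gap in a (consume b[j])
      if (j >= 2) {
        int q = IDX(i, j - 1);
        double o = M[q] - (gap_open + gap_ext);
        double e = Iy[q] - gap_ext;
        double x = Ix[q] - (gap_open + gap_ext);
        if (o >= e && o >= x) { Iy[IDX(i, j)] = o; tbY[IDX(i, j)] = 0; }
        else if (e >= x)      { Iy[IDX(i, j)] = e; tbY[IDX(i, j)] = 2; }
        else                  { Iy[IDX(i, j)] = x; tbY[IDX(i, j)] = 1; }
      }
    }
  }

  // best end over last row / last column; trailing gaps are free
  double best = NEG_INF;
  int bi = n, bj = m, bs = 0;
  for (int j = m; j >= 1; --j) {
    double cand[3] = {M[IDX(n, j)], Ix[IDX(n, j)], Iy[IDX(n, j)]};
    for (int s = 0; s < 3; ++s)
      if (cand[s] > best) { best = cand[s]; bi = n; bj = j; bs = s; }
  }
  for (int i = n; i >= 1; --i) {
    double cand[3] = {M[IDX(i, m)], Ix[IDX(i, m)], Iy[IDX(i, m)]};
    for (int s = 0; s < 3; ++s)
      if (cand[s] > best) { best = cand[s]; bi = i; bj = m; bs = s; }
  }

  // traceback
  int i = bi, j = bj, s = bs;
  long matches = 0, columns = 0;
  while (true) {
    if (s == 0) {
      char ca = a[i - 1], cb = b[j - 1];
      bool amb = (ca == 'N' || cb == 'N');
      if (!amb && ca == cb) ++matches;
      ++columns;
      signed char from = tbM[IDX(i, j)];
      --i; --j;
      if (from == -1) break;
      s = from;
    } else if (s == 1) {
      ++columns;
      signed char from = tbX[IDX(i, j)];
      --i;
      s = from;
    } else {
      ++columns;
      signed char from = tbY[IDX(i, j)];
      --j;
      s = from;
    }
    if (s < 0) stop("internal error: broken traceback");
  }
#undef IDX

  return List::create(_["score"] = best, _["matches"] = (double)matches,
                      _["columns"] = (double)columns,
                      _["identity"] = (double)matches / (double)columns);
}
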