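#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local-alignment scoring used throughout: match/mismatch on single
// nucleotides, 'N' scores as a mismatch against everything (including 'N').
static inline int base_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

//' Smith-Waterman local alignment score
//'
//' Standard local-alignment dynamic program with a linear gap penalty:
//' first row/column zero, H[i,j] = max(H[i-1,j-1] + s(a_i,b_j),
//' H[i-1,j] - gap, H[i,j-1] - gap, 0); the score is the matrix maximum.
//'
//' @param a,b nucleotide strings over A,C,G,T,N
//' @param match positive match score
//' @param mismatch non-positive mismatch score
//' @param gap positive per-position gap penalty
//' @return integer local alignment score (>= 0)
//' @keywords internal
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string a, std::string b, int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int s = prev[j - 1] + base_score(a[i - 1], b[j - 1], match, mismatch);
      int up = prev[j] - gap;
      int left = cur[j - 1] - gap;
      int v = s;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Exhaustive oracle: enumerate every local alignment as a monotone matching
// of residue pairs; columns between consecutive pairs are gaps charged per
// position. Exponential - usable only for tiny sequences; structurally
// independent of the DP above (no H matrix, no zero floor in the recursion).
static int enum_extend(const std::string &a, const std::string &b,
                       int i, int j, int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  int best = 0; // stop the alignment here
  for (int i2 = i + 1; i2 <= n; ++i2) {
    for (int j2 = j + 1; j2 <= m; ++j2) {
      int s = base_score(a[i2 - 1], b[j2 - 1], match, mismatch)
        - gap * ((i2 - i - 1) + (j2 - j - 1))
        + enum_extend(a, b, i2, j2, match, mismatch, gap);
      if (s > best) best = s;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_enumerate_cpp")]]
int sw_enumerate_cpp(std::string a, std::string b, int match, int mismatch, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (n > 10 || m > 10) stop("enumeration oracle limited to length <= 10");
  int best = 0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int s = base_score(a[i - 1], b[j - 1], match, mismatch)
        + enum_extend(a, b, i, j, match, mismatch, gap);
      if (s > best) best = s;
    }
  return best;
}
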