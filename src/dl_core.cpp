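#include <Rcpp.h>
#include <queue>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// All routines take 0-based integer-coded sequences (codes in [0, s)).
// DP values are doubles; sums of costs below 2^53 are exact, so equality
// comparisons on integer-valued cost models are safe.

// Full (m+1) x (n+1) dynamic-programming matrix.
// refined = false: Lowrance-Wagner case 4, H[k-1,l-1] + (i-k-1)D + T + (j-l-1)I,
//   applied whenever both k and l exist.
// refined = true: the restricted case 4, applied only when a_i != b_j and
//   (j-l == 1, giving H[k-1,j-2] + (i-k-1)D + T, or
//    i-k == 1, giving H[i-2,l-1] + (j-l-1)I + T).
// [[Rcpp::export]]
List cpp_full_matrix(IntegerVector a, IntegerVector b, double S, double I,
                     double D, double T, bool refined) {
  int m = a.size(), n = b.size();
  int s = 1;
  for (int i = 0; i < m; ++i) s = std::max(s, a[i] + 1);
  for (int j = 0; j < n; ++j) s = std::max(s, b[j] + 1);
  NumericMatrix H(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) H(i, 0) = i * D;
  for (int j = 0; j <= n; ++j) H(0, j) = j * I;
  std::vector<int> lastA(s, 0);  // last row k < i with a[k] == c (1-based, 0 = none)
  for (int i = 1; i <= m; ++i) {
    int ai = a[i - 1];
    std::vector<int> lastB(s, 0);  // last column l < j with b[l] == c
    for (int j = 1; j <= n; ++j) {
      int bj = b[j - 1];
      double best = H(i - 1, j - 1) + ((ai == bj) ? 0.0 : S);
      best = std::min(best, H(i, j - 1) + I);
      best = std::min(best, H(i - 1, j) + D);
      int k = lastA[bj], l = lastB[ai];
      if (!refined) {
        if (k > 0 && l > 0)
          best = std::min(best, H(k - 1, l - 1) + (i - k - 1) * D + T + (j - l - 1) * I);
      } else if (ai != bj) {
        if (l > 0 && j - l == 1 && k > 0)
          best = std::min(best, H(k - 1, j - 2) + (i - k - 1) * D + T);
        if (k > 0 && i - k == 1 && l > 0)
          best = std::min(best, H(i - 2, l - 1) + (j - l - 1) * I + T);
      }
      H(i, j) = best;
      lastB[bj] = j;
    }
    lastA[ai] = i;
  }
  return List::create(_["H"] = H, _["distance"] = H(m, n));
}

// Linear-space distance.  Arrays R, R1, FR are indexed q = -1..n with the
// value for q stored at slot q + 1.  On return:
//   R[q]  = H[m, q],   R1[q] = H[m-1, q],
//   FR[q] = H[k-1, q-2] for k the last row with A[k] == B[q] (maxVal if none).
// [[Rcpp::export]]
List cpp_ls_dl2(IntegerVector a, IntegerVector b, int s, double S, double I,
                double D, double T, double maxVal) {
  int m = a.size(), n = b.size();
  int sz = std::max(s, 1);
  NumericVector R(n + 2), R1(n + 2), FR(n + 2);
  std::vector<int> last_row_id(sz, 0);
  for (int t = 0; t < n + 2; ++t) { R1[t] = maxVal; FR[t] = maxVal; }
  R[0] = maxVal;  // augmented column -1
  for (int q = 0; q <= n; ++q) R[q + 1] = q * I;  // row 0
  for (int i = 1; i <= m; ++i) {
    std::swap(R, R1);  // now R1 = row i-1, R = row i-2 (stale, overwritten in place)
    int ai = a[i - 1];
    double last_i2l1 = R[1];  // H[i-2, 0]
    R[1] = i * D;             // H[i, 0]
    double Tval = maxVal;     // H[i-2, l-1] for the current l (undefined yet)
    int last_col_id = 0;      // l: last column < j with B[l] == A[i]
    for (int j = 1; j <= n; ++j) {
      int bj = b[j - 1];
      double diag = R1[j] + ((ai == bj) ? 0.0 : S);   // H[i-1, j-1]
      double left = R[j] + I;                          // H[i, j-1]
      double up = R1[j + 1] + D;                       // H[i-1, j]
      double temp = std::min(diag, std::min(left, up));
      if (ai == bj) {
        FR[j + 1] = R1[j - 1];  // H[i-1, j-2]: k becomes i for column j
        Tval = last_i2l1;       // H[i-2, j-1]: l becomes j
        last_col_id = j;
      } else {
        int k = last_row_id[bj];
        int l = last_col_id;
        if (l > 0 && j - l == 1 && k > 0)
          temp = std::min(temp, FR[j + 1] + (i - k - 1) * D + T);
        if (k > 0 && i - k == 1 && l > 0)
          temp = std::min(temp, Tval + (j - l - 1) * I + T);
      }
      last_i2l1 = R[j + 1];  // H[i-2, j]
      R[j + 1] = temp;       // H[i, j]
    }
    last_row_id[ai] = i;
  }
  double dp_elements = 3.0 * (n + 2) + sz;
  return List::create(_["distance"] = R[n + 1], _["R"] = R, _["R1"] = R1,
                      _["FR"] = FR, _["dp_elements"] = dp_elements);
}

// Strip (cache-blocked) variant: columns are processed in vertical strips of
// width q; state crosses strips through C, C1, FC (indexed i = -1..m at slot
// i + 1).  After the final strip:
//   C[i]  = H[i, n],  C1[i] = H[i, n-1],
//   FC[i] = H[i-2, l-1] for l the last column with B[l] == A[i] (maxVal if none).
// [[Rcpp::export]]
List cpp_strip_dl2(IntegerVector a, IntegerVector b, int s, double S, double I,
                   double D, double T, int q, double maxVal) {
  int m = a.size(), n = b.size();
  int sz = std::max(s, 1);
  NumericVector C(m + 2), C1(m + 2), FC(m + 2);
  C[0] = maxVal;
  for (int i = 0; i <= m; ++i) C[i + 1] = i * D;  // column 0
  for (int t = 0; t < m + 2; ++t) { C1[t] = maxVal; FC[t] = maxVal; }
  std::vector<int> last_col_of(sz, 0);  // last column in completed strips with B == c
  std::vector<int> last_row_id(sz, 0);
  int nstrips = (n + q - 1) / q;
  // local row arrays over columns js-2 .. je (slot c - (js - 2))
  std::vector<double> R(q + 3), R1(q + 3), FR(q + 3);
  for (int t = 0; t < nstrips; ++t) {
    int js = t * q + 1, je = std::min(n, (t + 1) * q);
    int off = js - 2;
    for (int c = js - 2; c <= je; ++c) {
      R[c - off] = (c >= 0) ? c * I : maxVal;  // row 0
      R1[c - off] = maxVal;                    // row -1
      FR[c - off] = maxVal;
    }
    std::fill(last_row_id.begin(), last_row_id.end(), 0);
    double cp_im1 = C[1];   // previous strip's H[i-1, js-1] (here i = 1)
    double cp_im2 = C[0];   // H[i-2, js-1] = maxVal for i = 1
    double c1p_im1 = C1[1]; // H[i-1, js-2]
    for (int i = 1; i <= m; ++i) {
      int ai = a[i - 1];
      double cp_i = C[i + 1];    // H[i, js-1]
      double c1p_i = C1[i + 1];  // H[i, js-2]
      std::swap(R, R1);
      // refresh the two boundary slots this row needs from the previous strip
      R1[js - 1 - off] = cp_im1;
      R1[js - 2 - off] = c1p_im1;
      R[js - 1 - off] = cp_i;
      double last_i2l1 = cp_im2;  // H[i-2, js-1]
      double Tval = FC[i + 1];
      int last_col_id = last_col_of[ai];
      for (int j = js; j <= je; ++j) {
        int bj = b[j - 1];
        double diag = R1[j - 1 - off] + ((ai == bj) ? 0.0 : S);
        double left = R[j - 1 - off] + I;
        double up = R1[j - off] + D;
        double temp = std::min(diag, std::min(left, up));
        if (ai == bj) {
          FR[j - off] = R1[j - 2 - off];
          Tval = last_i2l1;
          last_col_id = j;
        } else {
          int k = last_row_id[bj];
          int l = last_col_id;
          if (l > 0 && j - l == 1 && k > 0)
            temp = std::min(temp, FR[j - off] + (i - k - 1) * D + T);
          if (k > 0 && i - k == 1 && l > 0)
            temp = std::min(temp, Tval + (j - l - 1) * I + T);
        }
        last_i2l1 = R[j - off];
        R[j - off] = temp;
      }
      last_row_id[ai] = i;
      C[i + 1] = R[je - off];
      C1[i + 1] = R[je - 1 - off];  // je == js falls back on the seeded boundary slot
      FC[i + 1] = Tval;
      cp_im2 = cp_im1;
      cp_im1 = cp_i;
      c1p_im1 = c1p_i;
    }
    C[1] = je * I;  // H[0, je]
    C1[1] = (je >= 1) ? (je - 1) * I : maxVal;
    for (int j = js; j <= je; ++j) last_col_of[b[j - 1]] = j;
  }
  double dp_elements = 3.0 * (m + 2) + 2.0 * sz + 3.0 * (q + 3);
  return List::create(_["distance"] = C[m + 1], _["C"] = C, _["C1"] = C1,
                      _["FC"] = FC, _["dp_elements"] = dp_elements);
}

// Weighted Levenshtein (no transpositions) from x to y; used as an
// admissible, consistent heuristic for the edit-sequence search below.
static double wlev(const std::string &x, const std::string &y, double S,
                   double I, double D) {
  size_t lx = x.size(), ly = y.size();
  std::vector<double> prev(ly + 1), cur(ly + 1);
  for (size_t j = 0; j <= ly; ++j) prev[j] = j * I;
  for (size_t i = 1; i <= lx; ++i) {
    cur[0] = i * D;
    for (size_t j = 1; j <= ly; ++j) {
      double best = prev[j - 1] + ((x[i - 1] == y[j - 1]) ? 0.0 : S);
      best = std::min(best, cur[j - 1] + I);
      best = std::min(best, prev[j] + D);
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[ly];
}

struct SearchNode {
  double f, g;
  std::string str;
  bool operator<(const SearchNode &o) const {
    if (f != o.f) return f > o.f;  // min-heap on f
    return g > o.g;
  }
};

// Cost-ordered search over evolving strings: single-character substitution,
// insertion, deletion, and adjacent-pair swap, with costs S/I/D/T.  Guided by
// the weighted-Levenshtein lower bound with substitution cost min(S, T/2)
// (a transposition can always be simulated by two substitutions).  Returns
// R_PosInf when no edit sequence within `bound` exists.
// [[Rcpp::export]]
double cpp_bfs_dl(IntegerVector a, IntegerVector b, int s, double S, double I,
                  double D, double T, double bound, int max_states) {
  std::string A, B;
  for (int i = 0; i < a.size(); ++i) A.push_back((char)(a[i] + 1));
  for (int j = 0; j < b.size(); ++j) B.push_back((char)(b[j] + 1));
  double Slb = std::min(S, T / 2.0);
  std::priority_queue<SearchNode> pq;
  std::unordered_map<std::string, double> best;
  double h0 = wlev(A, B, Slb, I, D);
  if (h0 <= bound) {
    best[A] = 0.0;
    pq.push({h0, 0.0, A});
  }
  while (!pq.empty()) {
    SearchNode nd = pq.top();
    pq.pop();
    if (nd.str == B) return nd.g;
    auto it = best.find(nd.str);
    if (it != best.end() && nd.g > it->second) continue;  // stale entry
    const std::string &x = nd.str;
    size_t len = x.size();
    auto relax = [&](const std::string &y, double g2) {
      if (g2 > bound) return;
      double h = wlev(y, B, Slb, I, D);
      if (g2 + h > bound) return;
      auto jt = best.find(y);
      if (jt == best.end() || g2 < jt->second) {
        best[y] = g2;
        pq.push({g2 + h, g2, y});
      }
    };
    for (size_t p = 0; p < len; ++p) {  // substitutions
      for (int c = 0; c < s; ++c) {
        char ch = (char)(c + 1);
        if (x[p] == ch) continue;
        std::string y = x;
        y[p] = ch;
        relax(y, nd.g + S);
      }
    }
    for (size_t p = 0; p <= len; ++p) {  // insertions
      for (int c = 0; c < s; ++c) {
        std::string y = x;
        y.insert(y.begin() + p, (char)(c + 1));
        relax(y, nd.g + I);
      }
    }
    for (size_t p = 0; p < len; ++p) {  // deletions
      std::string y = x;
      y.erase(y.begin() + p);
      relax(y, nd.g + D);
    }
    for (size_t p = 0; p + 1 < len; ++p) {  // adjacent swaps
      if (x[p] == x[p + 1]) continue;
      std::string y = x;
      std::swap(y[p], y[p + 1]);
      relax(y, nd.g + T);
    }
    if ((int)best.size() > max_states)
      stop("edit-sequence search exceeded the state budget");
  }
  return R_PosInf;
}
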