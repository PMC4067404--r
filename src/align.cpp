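#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L costs open + L * ext,
// matching the gapOpening/gapExtension convention used by Biostrings, so test
// oracles can compare scores directly.

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// Best local alignment score of `read` against each reference.
// [[Rcpp::export(name = ".sw_score_multi")]]
NumericVector sw_score_multi(std::string read, CharacterVector refs,
                             int match, int mismatch, int gap_open, int gap_ext) {
  int n = read.size();
  int nref = refs.size();
  NumericVector out(nref);
  int go = gap_open + gap_ext;  // cost of a length-1 gap
  const int NEG = INT_MIN / 4;
  // Column sweep over the reference; H and F are kept per read position.
  std::vector<int> H(n + 1), F(n + 1);
  for (int r = 0; r < nref; ++r) {
    std::string ref = as<std::string>(refs[r]);
    int m = ref.size();
    std::fill(H.begin(), H.end(), 0);
    std::fill(F.begin(), F.end(), NEG);
    int best = 0;
    for (int j = 1; j <= m; ++j) {
      int diag = 0;   // H[i-1][j-1]
      int e = NEG;    // E[i][j]: gap in ref, depends on i-1 within this column
      char rc = ref[j - 1];
      for (int i = 1; i <= n; ++i) {
        int h_left = H[i]; // H[i][j-1] before overwrite
        F[i] = std::max(h_left - go, F[i] - gap_ext);  // gap in read (consume ref)
        int h = diag + subst(read[i - 1], rc, match, mismatch);
        if (e > h) h = e;
        if (F[i] > h) h = F[i];
        if (h < 0) h = 0;
        diag = h_left;
        H[i] = h;
        if (h > best) best = h;
        e = std::max(h - go, e - gap_ext);             // E[i+1][j]
      }
    }
    out[r] = best;
  }
  return out;
}

// Full local alignment with traceback. Returns 1-based inclusive coordinates
// and aligned strings with '-' for gaps. Ties during traceback prefer
// diagonal, then gap-in-ref (read insertion), then gap-in-read; the maximal
// cell chosen is the first encountered scanning read positions then ref
// positions (smallest read end, then smallest ref end), which makes the
// output deterministic.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string read, std::string ref,
              int match, int mismatch, int gap_open, int gap_ext) {
  int n = read.size(), m = ref.size();
  int go = gap_open + gap_ext;
  const int NEG = INT_MIN / 4;
  // full matrices: n up to ~400, m ~300 -> fine
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG), F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[at(i - 1, j)] - go, E[at(i - 1, j)] - gap_ext); // gap in ref
      int f = std::max(H[at(i, j - 1)] - go, F[at(i, j - 1)] - gap_ext); // gap in read
      int h = H[at(i - 1, j - 1)] + subst(read[i - 1], ref[j - 1], match, mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string ar, as;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E (gap in ref), 2 = F (gap in read)
  while (i > 0 && j > 0 && !(state == 0 && H[at(i, j)] == 0)) {
    if (state == 0) {
      int h = H[at(i, j)];
      int d = H[at(i - 1, j - 1)] + subst(read[i - 1], ref[j - 1], match, mismatch);
      if (h == d) {
        ar += read[i - 1]; as += ref[j - 1]; --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in ref; consumed read base
      ar += read[i - 1]; as += '-';
      int e = E[at(i, j)];
      if (e == H[at(i - 1, j)] - go) state = 0;
      --i;
    } else { // gap in read
      ar += '-'; as += ref[j - 1];
      int f = F[at(i, j)];
      if (f == H[at(i, j - 1)] - go) state = 0;
      --j;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(as.begin(), as.end());
  return List::create(_["score"] = best,
                      _["read_start"] = i + 1, _["read_end"] = bi,
                      _["ref_start"] = j + 1, _["ref_end"] = bj,
                      _["aligned_read"] = ar, _["aligned_ref"] = as);
}

// Longest common exact substring between two sequences (ungapped core used
// for D-segment matching). Returns length and 1-based start positions.
// Ties resolved by smallest a_start, then smallest b_start.
// [[Rcpp::export(name = ".lcs_substring")]]
List lcs_substring(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0, ai = 0, bi = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) { best = cur[j]; ai = i; bi = j; }
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
  return List::create(_["length"] = best,
                      _["a_start"] = best > 0 ? ai - best + 1 : NA_INTEGER,
                      _["b_start"] = best > 0 ? bi - best + 1 : NA_INTEGER);
}

// Global (Needleman-Wunsch) affine-gap alignment of two short sequences,
// used for edge reconciliation where both sequences must be consumed
// entirely. Same scoring convention as the local aligner.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              int match, int mismatch, int gap_open, int gap_ext) {
  int n = a.size(), m = b.size();
  int go = gap_open + gap_ext;
  const int NEG = INT_MIN / 4;
  std::vector<int> H((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG), F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  H[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    E[at(i, 0)] = -go - (i - 1) * gap_ext;
    H[at(i, 0)] = E[at(i, 0)];
  }
  for (int j = 1; j <= m; ++j) {
    F[at(0, j)] = -go - (j - 1) * gap_ext;
    H[at(0, j)] = F[at(0, j)];
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[at(i - 1, j)] - go, E[at(i - 1, j)] - gap_ext);
      int f = std::max(H[at(i, j - 1)] - go, F[at(i, j - 1)] - gap_ext);
      int h = H[at(i - 1, j - 1)] + subst(a[i - 1], b[j - 1], match, mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
    }
  }
  std::string ar, as;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0 &&
          H[at(i, j)] == H[at(i - 1, j - 1)] + subst(a[i - 1], b[j - 1], match, mismatch)) {
        ar += a[i - 1]; as += b[j - 1]; --i; --j;
      } else if (i > 0 && H[at(i, j)] == E[at(i, j)]) {
        state = 1;
      } else if (j > 0) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) {
      ar += a[i - 1]; as += '-';
      if (E[at(i, j)] == H[at(i - 1, j)] - go) state = 0;
      --i;
    } else {
      ar += '-'; as += b[j - 1];
      if (F[at(i, j)] == H[at(i, j - 1)] - go) state = 0;
      --j;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(as.begin(), as.end());
  return List::create(_["score"] = H[at(n, m)],
                      _["aligned_a"] = ar, _["aligned_b"] = as);
}
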