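#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstdlib>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) with traceback, identity computed as
// matching columns over alignment columns with terminal gap runs excluded,
// plus an IUPAC-aware semi-global primer search. These are the inner loops
// of clustering, chimera scanning and primer trimming; everything else in
// the package stays in R.

static const int NEG = std::numeric_limits<int>::min() / 4;

struct AlnResult {
  int matches;
  int columns;   // alignment columns excluding terminal gap runs
  int score;
  std::vector<int> diff_at;  // per a-position diff increments (size n + 1)
};

// Global alignment of a (rows) vs b (cols), end gaps penalized. band <= 0
// means full matrix; otherwise cells with |i - j| > band are excluded (the
// band is widened to cover |n - m| so the corner stays reachable). Storage
// is band-diagonal: row i holds offsets j - i + band in [0, 2*band].
static AlnResult aln_core(const std::string& a, const std::string& b,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int band, bool want_profile) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band <= 0) band = std::max(n, m);
  if (band < std::abs(n - m) + 1) band = std::abs(n - m) + 1;
  const int W = 2 * band + 1;
  std::vector<int> H((size_t)(n + 1) * W, NEG), E(H), F(H);
  // pointers: hp 0=diag 1=fromE 2=fromF; ep/fp 1=extend
  std::vector<unsigned char> hp((size_t)(n + 1) * W, 0), ep(hp.size(), 0),
      fp(hp.size(), 0);
  const int go = gap_open, ge = gap_ext;
#define IDX(i, j) ((size_t)(i)*W + ((j) - (i) + band))
  H[IDX(0, 0)] = 0;
  for (int j = 1; j <= std::min(m, band); ++j) {
    E[IDX(0, j)] = -go - ge * j;
    H[IDX(0, j)] = E[IDX(0, j)];
    hp[IDX(0, j)] = 1;
    ep[IDX(0, j)] = (unsigned char)(j > 1);
  }
  for (int i = 1; i <= std::min(n, band); ++i) {
    F[IDX(i, 0)] = -go - ge * i;
    H[IDX(i, 0)] = F[IDX(i, 0)];
    hp[IDX(i, 0)] = 2;
    fp[IDX(i, 0)] = (unsigned char)(i > 1);
  }
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      // E: gap in a, consumes b_j; predecessor (i, j-1)
      int e_open = NEG, e_ext = NEG;
      if (j - 1 >= i - band) {
        if (H[IDX(i, j - 1)] != NEG) e_open = H[IDX(i, j - 1)] - go - ge;
        if (E[IDX(i, j - 1)] != NEG) e_ext = E[IDX(i, j - 1)] - ge;
      }
      size_t c = IDX(i, j);
      if (e_ext > e_open) {
        E[c] = e_ext;
        ep[c] = 1;
      } else {
        E[c] = e_open;
        ep[c] = 0;
      }
      // F: gap in b, consumes a_i; predecessor (i-1, j)
      int f_open = NEG, f_ext = NEG;
      if (j <= i - 1 + band) {
        if (H[IDX(i - 1, j)] != NEG) f_open = H[IDX(i - 1, j)] - go - ge;
        if (F[IDX(i - 1, j)] != NEG) f_ext = F[IDX(i - 1, j)] - ge;
      }
      if (f_ext > f_open) {
        F[c] = f_ext;
        fp[c] = 1;
      } else {
        F[c] = f_open;
        fp[c] = 0;
      }
      int diag = H[IDX(i - 1, j - 1)];
      int hd = (diag == NEG) ? NEG
                             : diag + (a[i - 1] == b[j - 1] ? match : mismatch);
      int best = hd;
      unsigned char ptr = 0;
      if (E[c] > best) {
        best = E[c];
        ptr = 1;
      }
      if (F[c] > best) {
        best = F[c];
        ptr = 2;
      }
      H[c] = best;
      hp[c] = ptr;
    }
  }
  AlnResult res;
  res.matches = 0;
  res.columns = 0;
  res.score = H[IDX(n, m)];
  if (want_profile) res.diff_at.assign((size_t)n + 1, 0);
  // traceback from (n, m) to (0, 0); strip terminal gap runs from columns
  int i = n, j = m;
  int state = 0;  // 0=H 1=E 2=F
  int total_cols = 0, trailing_gap = 0, leading_gap = 0;
  bool seen_diag = false;
  int gap_run = 0;  // current run of gap columns (while tracing backwards)
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char p = hp[IDX(i, j)];
      if (p == 0) {
        total_cols++;
        bool is_match = a[i - 1] == b[j - 1];
        if (is_match)
          res.matches++;
        else if (want_profile)
          res.diff_at[i]++;
        if (!seen_diag) {
          trailing_gap = gap_run;  // gaps after the last diagonal column
          seen_diag = true;
        }
        gap_run = 0;
        --i;
        --j;
      } else {
        state = p;
      }
    } else if (state == 1) {  // gap in a, consumes b_j
      total_cols++;
      gap_run++;
      if (want_profile) res.diff_at[std::max(i, 1)]++;
      unsigned char p = ep[IDX(i, j)];
      --j;
      if (!p) state = 0;
    } else {  // gap in b, consumes a_i
      total_cols++;
      gap_run++;
      if (want_profile) res.diff_at[i]++;
      unsigned char p = fp[IDX(i, j)];
      --i;
      if (!p) state = 0;
    }
  }
#undef IDX
  if (!seen_diag) {
    // degenerate: the whole alignment is gaps
    res.columns = 0;
  } else {
    leading_gap = gap_run;  // gaps before the first diagonal column
    res.columns = total_cols - trailing_gap - leading_gap;
  }
  return res;
}

// [[Rcpp::export(name = ".ovl_align")]]
IntegerVector ovl_align_cpp(std::string a, std::string b, int match = 2,
                            int mismatch = -4, int gap_open = 10,
                            int gap_ext = 1, int band = 0) {
  AlnResult r = aln_core(a, b, match, mismatch, gap_open, gap_ext, band, false);
  return IntegerVector::create(_["matches"] = r.matches,
                               _["columns"] = r.columns,
                               _["score"] = r.score);
}

// Cumulative alignment differences between query a and reference b, indexed
// by query position: element i = substitutions + gap columns charged to
// query positions 1..i (gaps consuming only b are charged to the flanking
// query position). Used by the chimera breakpoint scan.
// [[Rcpp::export(name = ".ovl_diff_profile")]]
IntegerVector ovl_diff_profile_cpp(std::string a, std::string b,
                                   int match = 2, int mismatch = -4,
                                   int gap_open = 10, int gap_ext = 1,
                                   int band = 0) {
  AlnResult r = aln_core(a, b, match, mismatch, gap_open, gap_ext, band, true);
  int n = (int)a.size();
  IntegerVector out(n);
  int acc = 0;
  for (int i = 1; i <= n; ++i) {
    acc += r.diff_at[i];
    out[i - 1] = acc;
  }
  return out;
}

static inline unsigned char iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 15;
    default: return 0;
  }
}

// Semi-global edit-distance search of an IUPAC primer inside each window:
// the primer is aligned end-to-end, the window has free ends. Returns one
// row per window: best unit-cost edit distance and the 1-based window
// position where the primer alignment ends.
// [[Rcpp::export(name = ".primer_search")]]
IntegerMatrix primer_search_cpp(CharacterVector windows, std::string primer) {
  const int np = (int)primer.size();
  std::vector<unsigned char> pm(np);
  for (int i = 0; i < np; ++i) pm[i] = iupac_mask(primer[i]);
  IntegerMatrix out(windows.size(), 2);
  colnames(out) = CharacterVector::create("dist", "end");
  std::vector<int> prev, cur;
  for (R_xlen_t w = 0; w < windows.size(); ++w) {
    std::string win = as<std::string>(windows[w]);
    const int nw = (int)win.size();
    prev.assign(nw + 1, 0);  // D[0][j] = 0 (free start in window)
    cur.assign(nw + 1, 0);
    int best = np, bestj = 0;  // primer vs empty window = np deletions
    for (int i = 1; i <= np; ++i) {
      cur[0] = i;
      unsigned char pmi = pm[i - 1];
      for (int j = 1; j <= nw; ++j) {
        unsigned char sm = iupac_mask(win[j - 1]);
        int sub = prev[j - 1] + ((pmi & sm) ? 0 : 1);
        int del = prev[j] + 1;
        int ins = cur[j - 1] + 1;
        int v = sub < del ? sub : del;
        cur[j] = v < ins ? v : ins;
      }
      std::swap(prev, cur);
    }
    for (int j = 0; j <= nw; ++j) {
      if (prev[j] < best) {
        best = prev[j];
        bestj = j;
      }
    }
    out(w, 0) = best;
    out(w, 1) = bestj;
  }
  return out;
}
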