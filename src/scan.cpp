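#include <Rcpp.h>
using namespace Rcpp;

// DNA codes: 1=A, 2=C, 3=G, 4=T, 0=N/other. Weight matrix w is 4 x l
// (rows A,C,G,T in that order); a window score is the sum of the
// per-position weights of its bases. Windows containing code 0 are invalid.

static inline double score_plus(const int* c, int j, const NumericMatrix& w, int l) {
  double s = 0.0;
  for (int i = 0; i < l; ++i) {
    int b = c[j + i];
    if (b == 0) return NA_REAL;
    s += w(b - 1, i);
  }
  return s;
}

// minus orientation: the matched spelling is the reverse complement of the
// window, so motif position i reads the complement of the base at j+l-1-i.
static inline double score_minus(const int* c, int j, const NumericMatrix& w, int l) {
  double s = 0.0;
  for (int i = 0; i < l; ++i) {
    int b = c[j + l - 1 - i];
    if (b == 0) return NA_REAL;
    s += w(4 - b, i);  // complement code is 5-b; 0-based row index 4-b
  }
  return s;
}

// Best window over codes[from..to] (0-based, inclusive window starts).
// Tie-break: lower offset first, '+' before '-' (strict > keeps the first).
static void best_in_range(const int* c, int from, int to, const NumericMatrix& w,
                          int l, bool both, double& bs, int& bo, int& bstr) {
  bs = NA_REAL; bo = NA_INTEGER; bstr = NA_INTEGER;
  for (int j = from; j <= to; ++j) {
    double sp = score_plus(c, j, w, l);
    if (!ISNA(sp) && (ISNA(bs) || sp > bs)) { bs = sp; bo = j; bstr = 1; }
    if (both) {
      double sm = score_minus(c, j, w, l);
      if (!ISNA(sm) && (ISNA(bs) || sm > bs)) { bs = sm; bo = j; bstr = -1; }
    }
  }
}

// [[Rcpp::export]]
List cpp_best_window(IntegerVector codes, NumericMatrix w, bool both_strands) {
  int l = w.ncol();
  int n = codes.size();
  double bs; int bo, bstr;
  if (n < l) {
    return List::create(_["score"] = NA_REAL, _["offset"] = NA_INTEGER,
                        _["strand"] = NA_INTEGER);
  }
  best_in_range(codes.begin(), 0, n - l, w, l, both_strands, bs, bo, bstr);
  return List::create(_["score"] = bs, _["offset"] = bo, _["strand"] = bstr);
}

// Best window within each length-L stretch codes[starts[k]..starts[k]+L-1]
// (starts are 1-based). Used to scan many random coding substrings without
// materializing them.
// [[Rcpp::export]]
DataFrame cpp_best_windows_at(IntegerVector codes, IntegerVector starts, int L,
                              NumericMatrix w, bool both_strands) {
  int l = w.ncol();
  int K = starts.size();
  NumericVector score(K);
  IntegerVector offset(K), strand(K);
  const int* c = codes.begin();
  for (int k = 0; k < K; ++k) {
    int s0 = starts[k] - 1;
    if (s0 < 0 || s0 + L > codes.size())
      stop("null sample start out of range");
    double bs; int bo, bstr;
    if (L < l) { bs = NA_REAL; bo = NA_INTEGER; bstr = NA_INTEGER; }
    else best_in_range(c, s0, s0 + L - l, w, l, both_strands, bs, bo, bstr);
    score[k] = bs;
    offset[k] = (bo == NA_INTEGER) ? NA_INTEGER : bo - s0;  // 0-based in stretch
    strand[k] = bstr;
  }
  return DataFrame::create(_["score"] = score, _["offset"] = offset,
                           _["strand"] = strand);
}

// Extract l-mers starting at 1-based positions, one column per window,
// in matched spelling: strand[k] == -1 reverse-complements the window.
// [[Rcpp::export]]
IntegerMatrix cpp_extract_windows(IntegerVector codes, IntegerVector starts,
                                  IntegerVector strand, int l) {
  int K = starts.size();
  IntegerMatrix out(l, K);
  for (int k = 0; k < K; ++k) {
    int s0 = starts[k] - 1;
    if (IntegerVector::is_na(starts[k])) {
      for (int i = 0; i < l; ++i) out(i, k) = NA_INTEGER;
      continue;
    }
    if (s0 < 0 || s0 + l > codes.size()) stop("window start out of range");
    if (strand[k] == -1) {
      for (int i = 0; i < l; ++i) {
        int b = codes[s0 + l - 1 - i];
        out(i, k) = (b == 0) ? 0 : 5 - b;
      }
    } else {
      for (int i = 0; i < l; ++i) out(i, k) = codes[s0 + i];
    }
  }
  return out;
}

// Hamming distance between columns of two code matrices (same dim).
// [[Rcpp::export]]
IntegerVector cpp_hamming_cols(IntegerMatrix a, IntegerMatrix b) {
  if (a.nrow() != b.nrow() || a.ncol() != b.ncol())
    stop("dimension mismatch");
  int K = a.ncol(), l = a.nrow();
  IntegerVector d(K);
  for (int k = 0; k < K; ++k) {
    int dd = 0;
    for (int i = 0; i < l; ++i) if (a(i, k) != b(i, k)) ++dd;
    d[k] = dd;
  }
  return d;
}
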