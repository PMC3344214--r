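#include <Rcpp.h>
using namespace Rcpp;

// IUPAC nucleotide bit masks; two residues "match" when their base sets
// intersect (so consensus letters like K score as matches against G or T).
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  case 'R': return 5; case 'Y': return 10; case 'S': return 6; case 'W': return 9;
  case 'K': return 12; case 'M': return 3; case 'B': return 14; case 'D': return 13;
  case 'H': return 11; case 'V': return 7; case 'N': return 15;
  default: return 0; // '-' or unknown: never matches
  }
}

static inline double cell_score(int ma, int mb, double match, double mismatch) {
  return (ma & mb) ? match : mismatch;
}

// [[Rcpp::export(name = ".nw_score_cpp")]]
double nw_score_cpp(std::string a, std::string b,
                    double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> am(n), bm(m);
  for (int i = 0; i < n; ++i) am[i] = iupac_mask(a[i]);
  for (int j = 0; j < m; ++j) bm[j] = iupac_mask(b[j]);
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      double diag = prev[j - 1] + cell_score(am[i - 1], bm[j - 1], match, mismatch);
      double up = prev[j] + gap;
      double left = cur[j - 1] + gap;
      double s = diag;
      if (up > s) s = up;
      if (left > s) s = left;
      cur[j] = s;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise global-alignment scores (used for center-star center choice).
// [[Rcpp::export(name = ".nw_score_matrix_cpp")]]
NumericMatrix nw_score_matrix_cpp(CharacterVector seqs,
                                  double match, double mismatch, double gap) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = nw_score_cpp(ss[i], ss[j], match, mismatch, gap);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}

// Global Needleman-Wunsch with linear gaps and a deterministic traceback:
// ties resolved diagonal first, then up (gap in b), then left (gap in a).
// [[Rcpp::export(name = ".nw_align_cpp")]]
CharacterVector nw_align_cpp(std::string a, std::string b,
                             double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> am(n), bm(m);
  for (int i = 0; i < n; ++i) am[i] = iupac_mask(a[i]);
  for (int j = 0; j < m; ++j) bm[j] = iupac_mask(b[j]);
  NumericMatrix M(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) M(i, 0) = i * gap;
  for (int j = 0; j <= m; ++j) M(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = M(i - 1, j - 1) + cell_score(am[i - 1], bm[j - 1], match, mismatch);
      double up = M(i - 1, j) + gap;
      double left = M(i, j - 1) + gap;
      double s = diag;
      if (up > s) s = up;
      if (left > s) s = left;
      M(i, j) = s;
    }
  }
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(M(i, j) - (M(i - 1, j - 1) +
          cell_score(am[i - 1], bm[j - 1], match, mismatch))) < eps) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && std::abs(M(i, j) - (M(i - 1, j) + gap)) < eps) {
      ga.push_back(a[i - 1]); gb.push_back('-'); --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  CharacterVector out(3);
  out[0] = ga; out[1] = gb;
  out[2] = std::to_string(M(n, m));
  out.names() = CharacterVector::create("a", "b", "score");
  return out;
}
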