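#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment, affine gaps, score only.
// Gap of length L costs gap_open + L * gap_extend (the BLAST convention).
static double sw_score(const std::vector<int>& a, const std::vector<int>& b,
                       const double* submat, int nsym, double gap_open,
                       double gap_extend) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
  double best = 0.0;
  const double go = gap_open + gap_extend, ge = gap_extend;
  for (size_t i = 1; i <= n; ++i) {
    const double* srow = submat + a[i - 1] * nsym;
    double diag = 0.0;   // H[i-1][0]
    double F = R_NegInf; // vertical gap state for column j
    double Hij_prev = 0.0; // H[i][j-1]
    for (size_t j = 1; j <= m; ++j) {
      double Eij = std::max(E[j] - ge, H[j] - go);
      F = std::max(F - ge, Hij_prev - go);
      double Hij = diag + srow[b[j - 1]];
      if (Eij > Hij) Hij = Eij;
      if (F > Hij) Hij = F;
      if (Hij < 0.0) Hij = 0.0;
      diag = H[j];
      H[j] = Hij;
      E[j] = Eij;
      Hij_prev = Hij;
      if (Hij > best) best = Hij;
    }
  }
  return best;
}

static std::vector<int> encode(const std::string& s, const int* lookup,
                               int x_idx) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    unsigned char c = s[i];
    int idx = (c < 128) ? lookup[c] : -1;
    out[i] = (idx >= 0) ? idx : x_idx;
  }
  return out;
}

// frames: list (one element per gene) of character vectors of translated
// frames; pairs: m x 2 matrix of 1-based gene indices. Returns, per pair,
// the best local alignment raw score over all frame combinations.
// [[Rcpp::export(name = ".sw_best_pair_scores")]]
NumericVector sw_best_pair_scores(List frames, IntegerMatrix pairs,
                                  NumericMatrix submat,
                                  CharacterVector alphabet,
                                  double gap_open, double gap_extend) {
  int lookup[128];
  std::fill(lookup, lookup + 128, -1);
  int x_idx = 0;
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string s = as<std::string>(alphabet[k]);
    if (!s.empty()) {
      lookup[(unsigned char)s[0]] = k;
      if (s[0] == 'X') x_idx = k;
    }
  }
  const int n_genes = frames.size();
  std::vector<std::vector<std::vector<int> > > enc(n_genes);
  for (int g = 0; g < n_genes; ++g) {
    CharacterVector fr = frames[g];
    enc[g].resize(fr.size());
    for (int f = 0; f < fr.size(); ++f) {
      enc[g][f] = encode(as<std::string>(fr[f]), lookup, x_idx);
    }
  }
  const int nsym = submat.nrow();
  std::vector<double> flat(nsym * nsym);  // row-major
  for (int i = 0; i < nsym; ++i)
    for (int j = 0; j < nsym; ++j) flat[i * nsym + j] = submat(i, j);
  const int n_pairs = pairs.nrow();
  NumericVector out(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    const std::vector<std::vector<int> >& A = enc[pairs(p, 0) - 1];
    const std::vector<std::vector<int> >& B = enc[pairs(p, 1) - 1];
    double best = 0.0;
    for (size_t i = 0; i < A.size(); ++i) {
      for (size_t j = 0; j < B.size(); ++j) {
        double s = sw_score(A[i], B[j], flat.data(), nsym, gap_open,
                            gap_extend);
        if (s > best) best = s;
      }
    }
    out[p] = best;
  }
  return out;
}
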