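#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment. A gap of length L costs gap_open + L * gap_ext
// (the convention used by Biostrings::pairwiseAlignment).

static const int NEG_INF = -100000000;

static std::vector<int> encode_seq(const std::string& s, const int* lut,
                                   const std::string& label) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    unsigned char c = (unsigned char) s[i];
    int code = lut[c];
    if (code < 0)
      stop("invalid residue '%s' in %s", std::string(1, s[i]), label);
    out[i] = code;
  }
  return out;
}

static void build_lut(const IntegerMatrix& submat, int* lut,
                      std::vector<std::string>& names) {
  List dn = submat.attr("dimnames");
  CharacterVector rn = dn[0];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  names.clear();
  for (int i = 0; i < rn.size(); ++i) {
    std::string nm = as<std::string>(rn[i]);
    names.push_back(nm);
    lut[(unsigned char) nm[0]] = i;
  }
}

static int sw_score_one(const std::vector<int>& a, const std::vector<int>& b,
                        const int* S, int nres, int oe, int ext) {
  int m = (int) a.size(), n = (int) b.size();
  std::vector<int> H(n + 1, 0), F(n + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = H[0];
    int e = NEG_INF;
    const int* Srow = S + (size_t) a[i - 1] * nres;
    for (int j = 1; j <= n; ++j) {
      int fj = H[j] - oe;
      int f2 = F[j] - ext;
      F[j] = fj > f2 ? fj : f2;
      int e1 = H[j - 1] - oe;
      int e2 = e - ext;
      e = e1 > e2 ? e1 : e2;
      int h = diag + Srow[b[j - 1]];
      diag = H[j];
      if (F[j] > h) h = F[j];
      if (e > h) h = e;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_matrix")]]
NumericMatrix sw_score_matrix_cpp(CharacterVector seqs_a, CharacterVector seqs_b,
                                  IntegerMatrix submat, int gap_open, int gap_ext) {
  int lut[256];
  std::vector<std::string> resnames;
  build_lut(submat, lut, resnames);
  int nres = submat.nrow();
  std::vector<int> S((size_t) nres * nres);
  for (int i = 0; i < nres; ++i)
    for (int j = 0; j < nres; ++j)
      S[(size_t) i * nres + j] = submat(i, j);

  int na = seqs_a.size(), nb = seqs_b.size();
  std::vector<std::vector<int> > ea(na), eb(nb);
  for (int i = 0; i < na; ++i)
    ea[i] = encode_seq(as<std::string>(seqs_a[i]), lut, "query set");
  for (int j = 0; j < nb; ++j)
    eb[j] = encode_seq(as<std::string>(seqs_b[j]), lut, "subject set");

  int oe = gap_open + gap_ext;
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j)
      out(i, j) = sw_score_one(ea[i], eb[j], S.data(), nres, oe, gap_ext);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".sw_align_stats")]]
List sw_align_stats_cpp(std::string seq_a, std::string seq_b,
                        IntegerMatrix submat, int gap_open, int gap_ext) {
  int lut[256];
  std::vector<std::string> resnames;
  build_lut(submat, lut, resnames);
  int nres = submat.nrow();
  std::vector<int> a = encode_seq(seq_a, lut, "query");
  std::vector<int> b = encode_seq(seq_b, lut, "subject");
  int m = (int) a.size(), n = (int) b.size();
  int ext = gap_ext;
  int oe = gap_open + gap_ext;

  // full DP with the three state matrices so the optimal path can be walked
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG_INF);
  std::vector<int> F((m + 1) * (n + 1), NEG_INF);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t k = (size_t) i * (n + 1) + j;
      size_t up = k - (n + 1), left = k - 1, diag = up - 1;
      int e1 = H[left] - oe, e2 = E[left] - ext;
      E[k] = e1 > e2 ? e1 : e2;
      int f1 = H[up] - oe, f2 = F[up] - ext;
      F[k] = f1 > f2 ? f1 : f2;
      int h = H[diag] + submat(a[i - 1], b[j - 1]);
      if (E[k] > h) h = E[k];
      if (F[k] > h) h = F[k];
      if (h < 0) h = 0;
      H[k] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int matches = 0, columns = 0;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
  while (i > 0 && j > 0) {
    size_t k = (size_t) i * (n + 1) + j;
    size_t up = k - (n + 1), left = k - 1, diag = up - 1;
    if (state == 0) {
      if (H[k] == 0) break;
      int sub = submat(a[i - 1], b[j - 1]);
      if (H[k] == H[diag] + sub) {
        ++columns;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (H[k] == E[k]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++columns;
      if (E[k] == E[left] - ext) { --j; }
      else { --j; state = 0; }
    } else {
      ++columns;
      if (F[k] == F[up] - ext) { --i; }
      else { --i; state = 0; }
    }
  }

  return List::create(_["score"] = best,
                      _["matches"] = matches,
                      _["columns"] = columns);
}
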