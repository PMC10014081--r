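#include <Rcpp.h>
#include <string>
#include <vector>
#include <climits>

using namespace Rcpp;

// Raw-score local alignment (Gotoh affine gaps). A gap of length k costs
// gap_open + k * gap_extend, both non-positive, matching the convention of
// blastn-style raw scoring. Any base outside {A,C,G,T} scores as a mismatch
// against everything (including itself).

static const int NEG = INT_MIN / 4;

static inline int subst(char a, char b, int match, int mismatch) {
  if (a == b && (a == 'A' || a == 'C' || a == 'G' || a == 'T')) return match;
  return mismatch;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

static int sw_score_core(const std::string& a, const std::string& b,
                         int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0;     // H[i-1][j-1]
    int E = NEG;       // gap in a (consuming b)
    int Hleft = 0;     // H[i][j-1]
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hleft + gap_open + gap_extend, E + gap_extend);
      F[j] = std::max(H[j] + gap_open + gap_extend, F[j] + gap_extend);
      int h = Hdiag + subst(a[i - 1], b[j - 1], match, mismatch);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".rf_sw_score")]]
int rf_sw_score(std::string a, std::string b, int match, int mismatch,
                int gap_open, int gap_extend) {
  return sw_score_core(a, b, match, mismatch, gap_open, gap_extend);
}

// score plus the end coordinates (1-based) of the best local alignment;
// lets callers confine a full traceback to a small window of b
// [[Rcpp::export(name = ".rf_sw_score_end")]]
IntegerVector rf_sw_score_end(std::string a, std::string b, int match,
                              int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0, E = NEG, Hleft = 0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hleft + gap_open + gap_extend, E + gap_extend);
      F[j] = std::max(H[j] + gap_open + gap_extend, F[j] + gap_extend);
      int h = Hdiag + subst(a[i - 1], b[j - 1], match, mismatch);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  return IntegerVector::create(best, bi, bj);
}

// Best score of each read against any reference, either strand.
// [[Rcpp::export(name = ".rf_sw_best_scores")]]
IntegerVector rf_sw_best_scores(CharacterVector reads, CharacterVector refs,
                                int match, int mismatch, int gap_open,
                                int gap_extend) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nf);
  for (int k = 0; k < nf; ++k) R[k] = as<std::string>(refs[k]);
  IntegerVector out(nr);
  for (int i = 0; i < nr; ++i) {
    std::string q = as<std::string>(reads[i]);
    std::string qr = revcomp(q);
    int best = 0;
    for (int k = 0; k < nf; ++k) {
      int s = sw_score_core(q, R[k], match, mismatch, gap_open, gap_extend);
      if (s > best) best = s;
      s = sw_score_core(qr, R[k], match, mismatch, gap_open, gap_extend);
      if (s > best) best = s;
    }
    out[i] = best;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full local alignment with traceback. Returns 1-based coordinates of the
// aligned span on query and reference plus the two gapped alignment strings.
// [[Rcpp::export(name = ".rf_sw_align")]]
List rf_sw_align(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  // state: 0 stop, 1 diag, 2 left (gap in a), 3 up (gap in b)
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<signed char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<signed char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<signed char> tbF((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Ecur(m + 1, NEG), Fcol(m + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  std::vector<int> Eall, Fall;
  // store E and F too for exact traceback through gap runs
  std::vector<int> Emat((size_t)(n + 1) * (m + 1), NEG);
  std::vector<int> Fmat((size_t)(n + 1) * (m + 1), NEG);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t id = (size_t)i * (m + 1) + j;
      const size_t idL = id - 1;
      const size_t idU = id - (m + 1);
      const size_t idD = idU - 1;
      int eOpen = H[idL] + gap_open + gap_extend;
      int eExt = Emat[idL] + gap_extend;
      Emat[id] = std::max(eOpen, eExt);
      tbE[id] = (eExt > eOpen) ? 1 : 0;
      int fOpen = H[idU] + gap_open + gap_extend;
      int fExt = Fmat[idU] + gap_extend;
      Fmat[id] = std::max(fOpen, fExt);
      tbF[id] = (fExt > fOpen) ? 1 : 0;
      int d = H[idD] + subst(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; signed char t = 0;
      if (d > h) { h = d; t = 1; }
      if (Emat[id] > h) { h = Emat[id]; t = 2; }
      if (Fmat[id] > h) { h = Fmat[id]; t = 3; }
      H[id] = h; tbH[id] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, ra;
  int i = bi, j = bj;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    const size_t id = (size_t)i * (m + 1) + j;
    if (state == 0) {
      signed char t = tbH[id];
      if (t == 0) break;
      if (t == 1) { qa.push_back(a[i - 1]); ra.push_back(b[j - 1]); --i; --j; }
      else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in a, consume b
      qa.push_back('-'); ra.push_back(b[j - 1]);
      signed char e = tbE[id];
      --j;
      if (!e) state = 0;
    } else { // gap in b, consume a
      qa.push_back(a[i - 1]); ra.push_back('-');
      signed char f = tbF[id];
      --i;
      if (!f) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());
  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["r_start"] = j + 1, _["r_end"] = bj,
    _["q_aln"] = qa, _["r_aln"] = ra);
}

// [[Rcpp::export(name = ".rf_revcomp")]]
CharacterVector rf_revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
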