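#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Greedy overlap-layout assembler with exact suffix-prefix overlaps.
// At each step the pair (over all ordered orientations, both strands) with
// the longest exact overlap >= min_overlap is merged; overlap-length ties
// are broken by the lexicographically smaller merged sequence, then by
// input order. Per-base coverage counts constituent reads per position.

static std::string rc(const std::string& s) {
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

// longest o <= min(|a|,|b|) with suffix of a == prefix of b (KMP on b#a)
static int suffix_prefix(const std::string& a, const std::string& b) {
  const std::string s = b + '\x01' + a;
  const int L = (int)s.size();
  std::vector<int> pi(L, 0);
  for (int i = 1; i < L; ++i) {
    int k = pi[i - 1];
    while (k > 0 && s[i] != s[k]) k = pi[k - 1];
    if (s[i] == s[k]) ++k;
    pi[i] = k;
  }
  return pi[L - 1];
}

struct Ctg {
  std::string seq;
  std::vector<int> cov;
  bool active;
};

// orientations for pair (i,j): 0 i+j, 1 j+i, 2 i+rc(j), 3 rc(j)+i
static void pair_best(const Ctg& A, const Ctg& B, int min_ov,
                      int& best_o, int& best_ori) {
  best_o = 0; best_ori = -1;
  std::string Brc = rc(B.seq);
  int o;
  o = suffix_prefix(A.seq, B.seq);
  if (o >= min_ov && o > best_o) { best_o = o; best_ori = 0; }
  o = suffix_prefix(B.seq, A.seq);
  if (o >= min_ov && o > best_o) { best_o = o; best_ori = 1; }
  o = suffix_prefix(A.seq, Brc);
  if (o >= min_ov && o > best_o) { best_o = o; best_ori = 2; }
  o = suffix_prefix(Brc, A.seq);
  if (o >= min_ov && o > best_o) { best_o = o; best_ori = 3; }
}

static Ctg merge(const Ctg& A, const Ctg& B, int o, int ori) {
  const Ctg* x; const Ctg* y;
  Ctg Brc;
  switch (ori) {
    case 0: x = &A; y = &B; break;
    case 1: x = &B; y = &A; break;
    case 2: Brc.seq = rc(B.seq);
            Brc.cov.assign(B.cov.rbegin(), B.cov.rend());
            x = &A; y = &Brc; break;
    default: Brc.seq = rc(B.seq);
             Brc.cov.assign(B.cov.rbegin(), B.cov.rend());
             x = &Brc; y = &A; break;
  }
  Ctg M;
  M.active = true;
  const int lx = (int)x->seq.size();
  M.seq = x->seq + y->seq.substr(o);
  M.cov = x->cov;
  M.cov.resize(M.seq.size(), 0);
  for (size_t k = 0; k < y->cov.size(); ++k)
    M.cov[lx - o + k] += y->cov[k];
  return M;
}

static std::string merged_seq_preview(const Ctg& A, const Ctg& B, int o, int ori) {
  switch (ori) {
    case 0: return A.seq + B.seq.substr(o);
    case 1: return B.seq + A.seq.substr(o);
    case 2: { std::string r = rc(B.seq); return A.seq + r.substr(o); }
    default: { std::string r = rc(B.seq); return r + A.seq.substr(o); }
  }
}

// [[Rcpp::export(name = ".rf_greedy_assemble")]]
List rf_greedy_assemble(CharacterVector reads, int min_overlap) {
  const int n = reads.size();
  std::vector<Ctg> C(n);
  for (int i = 0; i < n; ++i) {
    C[i].seq = as<std::string>(reads[i]);
    C[i].cov.assign(C[i].seq.size(), 1);
    C[i].active = true;
  }
  // pairwise best overlap cache, upper triangle i<j
  std::vector<int> ov((size_t)n * n, 0);
  std::vector<signed char> ori((size_t)n * n, -1);
  std::vector<int> act;
  for (int i = 0; i < n; ++i) act.push_back(i);
  for (size_t ii = 0; ii < act.size(); ++ii) {
    for (size_t jj = ii + 1; jj < act.size(); ++jj) {
      int i = act[ii], j = act[jj];
      int o, r;
      pair_best(C[i], C[j], min_overlap, o, r);
      ov[(size_t)i * n + j] = o;
      ori[(size_t)i * n + j] = (signed char)r;
    }
    Rcpp::checkUserInterrupt();
  }
  while (true) {
    // global best
    int bo = 0;
    std::vector<std::pair<int,int> > cand;
    for (size_t ii = 0; ii < act.size(); ++ii) {
      for (size_t jj = ii + 1; jj < act.size(); ++jj) {
        int i = act[ii], j = act[jj];
        int o = ov[(size_t)i * n + j];
        if (o > bo) { bo = o; cand.clear(); cand.push_back(std::make_pair(i, j)); }
        else if (o == bo && o > 0) cand.push_back(std::make_pair(i, j));
      }
    }
    if (bo < min_overlap || cand.empty()) break;
    // tie-break: lexicographically smallest merged sequence, then input order
    int bi = -1, bj = -1;
    std::string bseq;
    for (size_t c = 0; c < cand.size(); ++c) {
      int i = cand[c].first, j = cand[c].second;
      std::string s = merged_seq_preview(C[i], C[j], bo,
                                         ori[(size_t)i * n + j]);
      if (bi < 0 || s < bseq) { bi = i; bj = j; bseq = s; }
    }
    C[bi] = merge(C[bi], C[bj], bo, ori[(size_t)bi * n + bj]);
    C[bj].active = false;
    act.clear();
    for (int i = 0; i < n; ++i) if (C[i].active) act.push_back(i);
    // refresh overlaps involving bi
    for (size_t k = 0; k < act.size(); ++k) {
      int j = act[k];
      if (j == bi) continue;
      int lo = std::min(bi, j), hi = std::max(bi, j);
      int o, r;
      if (lo == bi) pair_best(C[bi], C[j], min_overlap, o, r);
      else {
        pair_best(C[j], C[bi], min_overlap, o, r);
      }
      ov[(size_t)lo * n + hi] = o;
      ori[(size_t)lo * n + hi] = (signed char)r;
    }
    Rcpp::checkUserInterrupt();
  }
  List seqs(act.size()), covs(act.size());
  CharacterVector sv(act.size());
  for (size_t k = 0; k < act.size(); ++k) {
    sv[k] = C[act[k]].seq;
    covs[k] = IntegerVector(C[act[k]].cov.begin(), C[act[k]].cov.end());
  }
  return List::create(_["sequence"] = sv, _["coverage"] = covs);
}
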