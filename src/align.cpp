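#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment maximizing total score with linear
// gap cost. Optimal alignments are disambiguated lexicographically:
// maximize score, then matches, then diagonal steps (shortest alignment).
// 'N' matches nothing: an N column scores like a mismatch and never
// counts as a match.

static inline bool better(double s1, int m1, int d1,
                          double s2, int m2, int d2) {
  if (s1 != s2) return s1 > s2;
  if (m1 != m2) return m1 > m2;
  return d1 > d2;
}

// Identity-only DP with two rolling rows: matches and diagonal steps are
// carried through the recurrence, so no traceback is needed.
static void nw_identity_core(const std::string &a, const std::string &b,
                             double match, double mismatch, double gap,
                             double &score, int &matches, int &alen) {
  int na = a.size(), nb = b.size();
  std::vector<double> Sp(nb + 1), Sc(nb + 1);
  std::vector<int> Mp(nb + 1), Mc(nb + 1), Dp(nb + 1), Dc(nb + 1);
  for (int j = 0; j <= nb; ++j) { Sp[j] = gap * j; Mp[j] = 0; Dp[j] = 0; }
  for (int i = 1; i <= na; ++i) {
    Sc[0] = gap * i; Mc[0] = 0; Dc[0] = 0;
    char ca = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      bool is_match = (ca == b[j - 1]) && ca != 'N';
      double sd = Sp[j - 1] + (is_match ? match : mismatch);
      int md = Mp[j - 1] + (is_match ? 1 : 0);
      int dd = Dp[j - 1] + 1;
      double su = Sp[j] + gap;
      double sl = Sc[j - 1] + gap;
      // preference order at exact ties: D, U, L
      double bs = sd; int bm = md, bd = dd;
      if (better(su, Mp[j], Dp[j], bs, bm, bd)) {
        bs = su; bm = Mp[j]; bd = Dp[j];
      }
      if (better(sl, Mc[j - 1], Dc[j - 1], bs, bm, bd)) {
        bs = sl; bm = Mc[j - 1]; bd = Dc[j - 1];
      }
      Sc[j] = bs; Mc[j] = bm; Dc[j] = bd;
    }
    std::swap(Sp, Sc); std::swap(Mp, Mc); std::swap(Dp, Dc);
  }
  score = Sp[nb];
  matches = Mp[nb];
  alen = na + nb - Dp[nb];
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
NumericVector nw_identity_cpp(std::string a, std::string b,
                              double match = 1.0, double mismatch = 0.0,
                              double gap = -1.0) {
  double s; int m, alen;
  nw_identity_core(a, b, match, mismatch, gap, s, m, alen);
  double identity = alen > 0 ? (double)m / alen : 1.0;
  return NumericVector::create(_["score"] = s, _["matches"] = m,
                               _["alen"] = alen, _["identity"] = identity);
}

// Full DP with pointers, for traceback (consensus alignment only).
struct Cell { double s; int m; int dg; char ptr; };

static void nw_fill(const std::string &a, const std::string &b,
                    double match, double mismatch, double gap,
                    std::vector<Cell> &T, int &na, int &nb) {
  na = a.size();
  nb = b.size();
  T.assign((size_t)(na + 1) * (nb + 1), Cell());
  for (int j = 0; j <= nb; ++j) T[j] = {gap * j, 0, 0, 'L'};
  for (int i = 1; i <= na; ++i) {
    T[(size_t)i * (nb + 1)] = {gap * i, 0, 0, 'U'};
    for (int j = 1; j <= nb; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      bool is_match = (ca == cb) && ca != 'N';
      const Cell &d = T[(size_t)(i - 1) * (nb + 1) + (j - 1)];
      const Cell &u = T[(size_t)(i - 1) * (nb + 1) + j];
      const Cell &l = T[(size_t)i * (nb + 1) + (j - 1)];
      Cell best = {d.s + (is_match ? match : mismatch),
                   d.m + (is_match ? 1 : 0), d.dg + 1, 'D'};
      if (better(u.s + gap, u.m, u.dg, best.s, best.m, best.dg))
        best = {u.s + gap, u.m, u.dg, 'U'};
      if (better(l.s + gap, l.m, l.dg, best.s, best.m, best.dg))
        best = {l.s + gap, l.m, l.dg, 'L'};
      T[(size_t)i * (nb + 1) + j] = best;
    }
  }
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, double match = 1.0,
                  double mismatch = 0.0, double gap = -1.0) {
  std::vector<Cell> T;
  int na, nb;
  nw_fill(a, b, match, mismatch, gap, T, na, nb);
  std::string aa, bb;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    char p = T[(size_t)i * (nb + 1) + j].ptr;
    if (i > 0 && j > 0 && p == 'D') {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (p == 'U' || j == 0)) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  const Cell &fin = T[(size_t)na * (nb + 1) + nb];
  int alen = na + nb - fin.dg;
  double identity = alen > 0 ? (double)fin.m / alen : 1.0;
  return List::create(_["a"] = aa, _["b"] = bb, _["identity"] = identity,
                      _["score"] = fin.s);
}

// Sorted unique 2-bit-encoded k-mer hashes (k <= 15); k-mers containing
// N (or any non-ACGT) are skipped.
static std::vector<uint32_t> kmer_hashes(const std::string &s, int k) {
  std::vector<uint32_t> out;
  int L = s.size();
  for (int i = 0; i + k <= L; ++i) {
    uint32_t h = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int code;
      switch (s[i + j]) {
        case 'A': code = 0; break;
        case 'C': code = 1; break;
        case 'G': code = 2; break;
        case 'T': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { ok = false; break; }
      h = (h << 2) | code;
    }
    if (ok) out.push_back(h);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static double kmer_share(const std::vector<uint32_t> &a,
                         const std::vector<uint32_t> &b) {
  if (a.empty() || b.empty()) return 0.0;
  size_t i = 0, j = 0, common = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++common; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return (double)common / std::min(a.size(), b.size());
}

// [[Rcpp::export(name = ".kmer_share_cpp")]]
NumericVector kmer_share_cpp(std::string query, CharacterVector seqs,
                             int kmer = 8) {
  std::vector<uint32_t> qk = kmer_hashes(query, kmer);
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = kmer_share(qk, kmer_hashes(as<std::string>(seqs[i]), kmer));
  return out;
}

// [[Rcpp::export(name = ".identity_matrix_cpp")]]
NumericMatrix identity_matrix_cpp(CharacterVector seqs, double match = 1.0,
                                  double mismatch = 0.0, double gap = -1.0,
                                  double prescreen = 0.0, int kmer = 8) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  // optional k-mer prescreen: pairs sharing fewer than `prescreen` of
  // their k-mers are reported as identity 0 without alignment (they are
  // far below any OTU threshold of interest)
  std::vector<std::vector<uint32_t>> km;
  if (prescreen > 0.0) {
    km.resize(n);
    for (int i = 0; i < n; ++i) km[i] = kmer_hashes(ss[i], kmer);
  }
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      if (prescreen > 0.0 && kmer_share(km[i], km[j]) < prescreen) {
        out(i, j) = 0.0;
        out(j, i) = 0.0;
        continue;
      }
      double s; int m, alen;
      nw_identity_core(ss[i], ss[j], match, mismatch, gap, s, m, alen);
      double id = alen > 0 ? (double)m / alen : 1.0;
      out(i, j) = id;
      out(j, i) = id;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
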