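#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <climits>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, 3-state DP) with traceback.
// Gap of length L costs gap_open + L * gap_ext (BLAST convention).
// q, s: 0-based residue codes into sm. Returns 1-based coordinates.
// Tie-break: first-best end cell in row-major order; within a cell the
// match state is preferred over gap states, which favours longer,
// earlier-starting alignments deterministically.
// [[Rcpp::export]]
List sw_align_c(IntegerVector q, IntegerVector s, IntegerMatrix sm,
                double gap_open, double gap_ext) {
  const int m = q.size(), n = s.size();
  const int A = sm.nrow();
  const int NEG = INT_MIN / 4;
  const int go = (int)gap_open, ge = (int)gap_ext;
  const int gop = go + ge;
  std::vector<int> SM(A * A);
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < A; ++b) SM[a * A + b] = sm(a, b);
  std::vector<int> sc(s.begin(), s.end());
  std::vector<int> Hm(n + 1, 0), Hx(n + 1, NEG), Hy(n + 1, NEG);
  std::vector<int> pHm(n + 1, 0), pHx(n + 1, NEG), pHy(n + 1, NEG);
  // traceback codes: Hm: 0 start, 1 from M, 2 from X, 3 from Y ; Hx/Hy: 1 open, 2 extend
  std::vector<unsigned char> tbm((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbx((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tby((size_t)(m + 1) * (n + 1), 0);
  int best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    std::swap(Hm, pHm); std::swap(Hx, pHx); std::swap(Hy, pHy);
    Hm[0] = 0; Hx[0] = NEG; Hy[0] = NEG;
    const int* srow = SM.data() + (size_t)q[i - 1] * A;
    const int* pm = pHm.data(); const int* px = pHx.data(); const int* py = pHy.data();
    int* hm_ = Hm.data(); int* hx_ = Hx.data(); int* hy_ = Hy.data();
    unsigned char* tm = tbm.data() + (size_t)i * (n + 1);
    unsigned char* tx = tbx.data() + (size_t)i * (n + 1);
    unsigned char* ty = tby.data() + (size_t)i * (n + 1);
    int hyprev = NEG, hmprev = 0;
    for (int j = 1; j <= n; ++j) {
      // match/mismatch state (branchless: max first, then derive the code)
      const int pm1 = pm[j - 1], px1 = px[j - 1], py1 = py[j - 1];
      int from = std::max(std::max(pm1, px1), std::max(py1, 0));
      unsigned char c = (from == pm1) ? 1 : ((from == px1) ? 2 : ((from == py1) ? 3 : 0));
      const int hmraw = from + srow[sc[j - 1]];
      const int hm = std::max(hmraw, 0);
      c = (hmraw < 0) ? 0 : c;
      hm_[j] = hm; tm[j] = c;
      // gap in subject (consume query): from row i-1, same j
      const int xo = pm[j] - gop, xe = px[j] - ge;
      hx_[j] = std::max(xo, xe); tx[j] = (xo >= xe) ? 1 : 2;
      // gap in query (consume subject): same row, j-1
      const int yo = hmprev - gop, ye = hyprev - ge;
      hyprev = std::max(yo, ye);
      hy_[j] = hyprev; ty[j] = (yo >= ye) ? 1 : 2;
      hmprev = hm;
      if (hm > best) { best = hm; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER,
                        _["pairs"] = IntegerMatrix(2, 0));
  }
  // traceback from (bi, bj) in state M
  std::vector<int> qp, sp;
  int i = bi, j = bj, st = 0; // 0 = M, 1 = X, 2 = Y
  while (i > 0 && j > 0) {
    size_t row = (size_t)i * (n + 1);
    if (st == 0) {
      unsigned char c = tbm[row + j];
      qp.push_back(i); sp.push_back(j);
      --i; --j;
      if (c == 0) break;
      st = (c == 1) ? 0 : (c == 2 ? 1 : 2);
    } else if (st == 1) {
      unsigned char c = tbx[row + j];
      qp.push_back(i); sp.push_back(0);
      --i;
      st = (c == 1) ? 0 : 1;
    } else {
      unsigned char c = tby[row + j];
      qp.push_back(0); sp.push_back(j);
      --j;
      st = (c == 1) ? 0 : 2;
    }
  }
  const int L = qp.size();
  IntegerMatrix pairs(2, L);
  int qs0 = 0, ss0 = 0;
  for (int k = 0; k < L; ++k) {
    pairs(0, k) = qp[L - 1 - k];
    pairs(1, k) = sp[L - 1 - k];
    if (pairs(0, k) > 0 && qs0 == 0) qs0 = pairs(0, k);
    if (pairs(1, k) > 0 && ss0 == 0) ss0 = pairs(1, k);
  }
  return List::create(_["score"] = (double)best, _["q_start"] = qs0, _["q_end"] = bi,
                      _["s_start"] = ss0, _["s_end"] = bj, _["pairs"] = pairs);
}

// Score-only local alignment of many queries against one subject.
// [[Rcpp::export]]
NumericVector sw_score_multi_c(List qs, IntegerVector s, IntegerMatrix sm,
                               double gap_open, double gap_ext) {
  const int n = s.size(), nq = qs.size();
  const int A = sm.nrow();
  const int NEG = INT_MIN / 4;
  const int go = (int)gap_open, ge = (int)gap_ext;
  const int gop = go + ge;
  std::vector<int> SM(A * A);
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < A; ++b) SM[a * A + b] = sm(a, b);
  std::vector<int> sc(s.begin(), s.end());
  NumericVector out(nq);
  std::vector<int> Hm(n + 1), Hx(n + 1), Hy(n + 1);
  std::vector<int> pHm(n + 1), pHx(n + 1), pHy(n + 1);
  for (int k = 0; k < nq; ++k) {
    IntegerVector q = qs[k];
    const int m = q.size();
    std::fill(pHm.begin(), pHm.end(), 0);
    std::fill(pHx.begin(), pHx.end(), NEG);
    std::fill(pHy.begin(), pHy.end(), NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      Hm[0] = 0; Hx[0] = NEG; Hy[0] = NEG;
      const int* srow = SM.data() + (size_t)q[i - 1] * A;
      const int* pm = pHm.data(); const int* px = pHx.data(); const int* py = pHy.data();
      int* hm_ = Hm.data(); int* hx_ = Hx.data(); int* hy_ = Hy.data();
      int hyprev = NEG, hmprev = 0;
      for (int j = 1; j <= n; ++j) {
        int from = std::max(std::max(pm[j - 1], px[j - 1]),
                            std::max(py[j - 1], 0));
        int hm = std::max(from + srow[sc[j - 1]], 0);
        hm_[j] = hm;
        hx_[j] = std::max(pm[j] - gop, px[j] - ge);
        hyprev = std::max(hmprev - gop, hyprev - ge);
        hy_[j] = hyprev;
        hmprev = hm;
        best = std::max(best, hm);
      }
      std::swap(Hm, pHm); std::swap(Hx, pHx); std::swap(Hy, pHy);
    }
    out[k] = best;
  }
  return out;
}

static inline double lse(double a, double b) {
  if (a < b) std::swap(a, b);
  if (b <= -1e29) return a;
  return a + std::log1p(std::exp(b - a));
}

// Per-offset scoring of a position-specific profile against a DNA sequence.
// logodds: 4 x P matrix (rows A,C,G,T) of per-column emission log-odds (nats).
// seqv: 0..3 codes, -1 for ambiguity (scored as the column minimum).
// Paths align all P columns starting at each offset, with banded insertions
// (sequence char consumed, background emission) and deletions (column skipped),
// each costing a flat penalty in nats.
// Row 1: best-path (Viterbi-style) score; Row 2: log-sum over paths
// (forward-style); Row 3: net length drift k of the best path (consumed = P+k).
// Offsets where no path fits get -Inf.
// [[Rcpp::export]]
NumericMatrix profile_scan_c(NumericMatrix logodds, IntegerVector seqv,
                             double del_pen, double ins_pen, int band) {
  const int P = logodds.ncol(), W = seqv.size();
  const int nk = 2 * band + 1;
  const double NEG = -1e30;
  NumericMatrix out(3, W);
  std::vector<double> colmin(P);
  for (int i = 0; i < P; ++i) {
    double mn = logodds(0, i);
    for (int b = 1; b < 4; ++b) if (logodds(b, i) < mn) mn = logodds(b, i);
    colmin[i] = mn;
  }
  std::vector<double> v(nk), f(nk), pv(nk), pf(nk);
  for (int j = 0; j < W; ++j) {
    // init i = 0: only k = 0 live
    for (int k = 0; k < nk; ++k) { pv[k] = NEG; pf[k] = NEG; }
    pv[band] = 0.0; pf[band] = 0.0;
    for (int i = 1; i <= P; ++i) {
      for (int kk = 0; kk < nk; ++kk) { v[kk] = NEG; f[kk] = NEG; }
      for (int kk = 0; kk < nk; ++kk) {
        const int k = kk - band;
        const int pos = j + i + k - 1; // seq index consumed by matching column i
        double vm = NEG, fm = NEG;
        if (pos >= 0 && pos < W && pv[kk] > NEG / 2) {
          const int b = seqv[pos];
          const double e = (b >= 0) ? logodds(b, i - 1) : colmin[i - 1];
          vm = pv[kk] + e; fm = pf[kk] + e;
        }
        double vd = NEG, fd = NEG;
        if (kk + 1 < nk && pv[kk + 1] > NEG / 2) {
          vd = pv[kk + 1] - del_pen; fd = pf[kk + 1] - del_pen;
        }
        double vi = NEG, fi = NEG;
        if (kk - 1 >= 0 && v[kk - 1] > NEG / 2) {
          // insertion consumes seq char pos (background emission, log-odds 0)
          if (pos >= 0 && pos < W) { vi = v[kk - 1] - ins_pen; fi = lse(f[kk - 1] - ins_pen, NEG); }
        }
        double vv = vm; if (vd > vv) vv = vd; if (vi > vv) vv = vi;
        v[kk] = vv;
        f[kk] = lse(lse(fm, fd), fi);
      }
      std::swap(v, pv); std::swap(f, pf);
    }
    double vbest = NEG, fsum = NEG; int kbest = 0;
    for (int kk = 0; kk < nk; ++kk) {
      if (pv[kk] > vbest) { vbest = pv[kk]; kbest = kk - band; }
      fsum = lse(fsum, pf[kk]);
    }
    out(0, j) = vbest > NEG / 2 ? vbest : R_NegInf;
    out(1, j) = fsum > NEG / 2 ? fsum : R_NegInf;
    out(2, j) = kbest;
  }
  return out;
}

// Six-frame translation. code64: amino acids indexed by codon
// 16*b1 + 4*b2 + b3 with A=0, C=1, G=2, T=3; ambiguous codons emit 'X'.
// Returns frames +0, +1, +2, -0, -1, -2 (minus frames read off the
// reverse complement).
// [[Rcpp::export]]
CharacterVector translate_frames_c(std::string dna, std::string code64) {
  const int L = dna.size();
  std::vector<int> f(L), r(L);
  for (int i = 0; i < L; ++i) {
    int c;
    switch (dna[i]) {
      case 'A': case 'a': c = 0; break;
      case 'C': case 'c': c = 1; break;
      case 'G': case 'g': c = 2; break;
      case 'T': case 't': c = 3; break;
      default: c = -1;
    }
    f[i] = c;
    r[L - 1 - i] = (c < 0) ? -1 : 3 - c;
  }
  CharacterVector out(6);
  for (int s = 0; s < 2; ++s) {
    const std::vector<int>& v = (s == 0) ? f : r;
    for (int fr = 0; fr < 3; ++fr) {
      int n = (L - fr) / 3;
      if (n < 0) n = 0;
      std::string p(n, 'X');
      for (int k = 0; k < n; ++k) {
        int a = v[fr + 3 * k], b = v[fr + 3 * k + 1], c = v[fr + 3 * k + 2];
        if (a >= 0 && b >= 0 && c >= 0) p[k] = code64[16 * a + 4 * b + c];
      }
      out[3 * s + fr] = p;
    }
  }
  return out;
}
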