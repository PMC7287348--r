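#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman of an encoded query against a subject window.
// Gap of length g costs gap_open + g * gap_extend. Returns the single best
// local alignment in the window with traceback statistics.
struct SwHit {
  int qstart, qend, sstart, send; // 0-based half-open
  double score;
  int matches, aln_len, gaps;
  bool ok;
};

static SwHit sw_window(const std::vector<int> &q, const int *s, int n,
                       const NumericMatrix &submat, double go, double ge) {
  const int m = (int)q.size();
  SwHit out; out.ok = false; out.score = 0.0;
  if (m == 0 || n == 0) return out;
  const double NEG = -1e18;
  std::vector<double> M((m + 1) * (n + 1), 0.0), Ix((m + 1) * (n + 1), NEG),
      Iy((m + 1) * (n + 1), NEG);
  // traceback: 0 stop, 1 diag-from-M, 2 diag-from-Ix, 3 diag-from-Iy
  std::vector<uint8_t> tbM((m + 1) * (n + 1), 0), tbX((m + 1) * (n + 1), 0),
      tbY((m + 1) * (n + 1), 0); // tbX/tbY: 1 = opened from M, 0 = extended
  double best = 0.0; int bi = -1, bj = -1;
  const int W = n + 1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      // Ix: gap in subject (consume query)
      double xo = M[(i - 1) * W + j] - (go + ge);
      double xe = Ix[(i - 1) * W + j] - ge;
      if (xo >= xe) { Ix[idx] = xo; tbX[idx] = 1; } else { Ix[idx] = xe; tbX[idx] = 0; }
      // Iy: gap in query (consume subject)
      double yo = M[i * W + (j - 1)] - (go + ge);
      double ye = Iy[i * W + (j - 1)] - ge;
      if (yo >= ye) { Iy[idx] = yo; tbY[idx] = 1; } else { Iy[idx] = ye; tbY[idx] = 0; }
      // M
      double sub = submat(q[i - 1], s[j - 1]);
      double dM = M[(i - 1) * W + (j - 1)], dX = Ix[(i - 1) * W + (j - 1)],
             dY = Iy[(i - 1) * W + (j - 1)];
      double dbest = dM; uint8_t from = 1;
      if (dX > dbest) { dbest = dX; from = 2; }
      if (dY > dbest) { dbest = dY; from = 3; }
      double v = dbest + sub;
      if (v <= 0.0) { M[idx] = 0.0; tbM[idx] = 0; }
      else { M[idx] = v; tbM[idx] = from; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  if (bi < 0 || best <= 0.0) return out;
  // traceback from best M cell
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
  int matches = 0, aln = 0, gaps = 0;
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 0) {
      uint8_t t = tbM[idx];
      if (t == 0) break;
      ++aln;
      if (q[i - 1] == s[j - 1]) ++matches;
      --i; --j;
      if (t == 1) state = 0; else if (t == 2) state = 1; else state = 2;
      if (state == 0 && tbM[i * W + j] == 0 && M[i * W + j] <= 0.0) break;
    } else if (state == 1) {
      ++aln; ++gaps;
      uint8_t t = tbX[idx];
      --i;
      state = t == 1 ? 0 : 1;
    } else {
      ++aln; ++gaps;
      uint8_t t = tbY[idx];
      --j;
      state = t == 1 ? 0 : 2;
    }
  }
  out.qstart = i; out.qend = bi; out.sstart = j; out.send = bj;
  out.score = best; out.matches = matches; out.aln_len = aln; out.gaps = gaps;
  out.ok = true;
  return out;
}

// Seed-and-extend search of multiple encoded queries against one encoded
// subject strand. Letters are 0..(nletters-1); codes >= nletters (e.g. N)
// never seed and score via the matrix's last row/column if provided there.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(List queries, IntegerVector subject,
                          NumericMatrix submat, double gap_open,
                          double gap_extend, int word_size, int nletters,
                          double min_score, int diag_band, int max_window) {
  const int n = subject.size();
  const int nq = queries.size();
  std::vector<int> subj(subject.begin(), subject.end());
  // map: word hash -> list of (query, qpos)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> wmap;
  std::vector<std::vector<int>> qenc(nq);
  uint64_t base = (uint64_t)nletters;
  for (int qi = 0; qi < nq; ++qi) {
    IntegerVector qv = queries[qi];
    qenc[qi].assign(qv.begin(), qv.end());
    const std::vector<int> &q = qenc[qi];
    const int m = (int)q.size();
    for (int p = 0; p + word_size <= m; ++p) {
      uint64_t h = 0; bool ok = true;
      for (int k = 0; k < word_size; ++k) {
        if (q[p + k] < 0 || q[p + k] >= nletters) { ok = false; break; }
        h = h * base + (uint64_t)q[p + k];
      }
      if (ok) wmap[h].emplace_back(qi, p);
    }
  }
  // scan subject, collect seeds per query: (diag, spos)
  std::vector<std::vector<std::pair<long,int>>> seeds(nq);
  if (n >= word_size) {
    uint64_t h = 0, mod = 1;
    for (int k = 0; k < word_size - 1; ++k) mod *= base;
    int valid = 0; // length of current run of in-alphabet letters
    for (int j = 0; j < n; ++j) {
      int c = subj[j];
      if (c < 0 || c >= nletters) { valid = 0; h = 0; continue; }
      if (valid >= word_size) h -= (uint64_t)subj[j - word_size] * mod;
      h = h * base + (uint64_t)c;
      ++valid;
      if (valid >= word_size) {
        int sp = j - word_size + 1;
        auto it = wmap.find(h);
        if (it != wmap.end())
          for (auto &pr : it->second)
            seeds[pr.first].emplace_back((long)sp - pr.second, sp);
      }
    }
  }
  std::vector<int> r_q, r_qs, r_qe, r_ss, r_se, r_mat, r_len, r_gap;
  std::vector<double> r_sc;
  for (int qi = 0; qi < nq; ++qi) {
    auto &sv = seeds[qi];
    if (sv.empty()) continue;
    std::sort(sv.begin(), sv.end());
    const std::vector<int> &q = qenc[qi];
    const int m = (int)q.size();
    size_t a = 0;
    while (a < sv.size()) {
      size_t b = a + 1;
      long dmin = sv[a].first; int smax = sv[a].second;
      while (b < sv.size() && sv[b].first - dmin <= diag_band &&
             (sv[b].second >= smax - 2 * m && sv[b].second <= smax + 2 * m)) {
        smax = std::max(smax, sv[b].second);
        ++b;
      }
      int smin = sv[a].second;
      for (size_t k = a; k < b; ++k) smin = std::min(smin, sv[k].second);
      int ws = std::max(0, smin - m - 16);
      int we = std::min(n, smax + word_size + m + 16);
      if (we - ws > max_window) we = ws + max_window;
      SwHit h = sw_window(q, subj.data() + ws, we - ws, submat, gap_open,
                          gap_extend);
      if (h.ok && h.score >= min_score) {
        r_q.push_back(qi + 1);
        r_qs.push_back(h.qstart); r_qe.push_back(h.qend);
        r_ss.push_back(ws + h.sstart); r_se.push_back(ws + h.send);
        r_sc.push_back(h.score);
        r_mat.push_back(h.matches); r_len.push_back(h.aln_len);
        r_gap.push_back(h.gaps);
      }
      a = b;
    }
  }
  return DataFrame::create(
      _["query"] = r_q, _["qstart"] = r_qs, _["qend"] = r_qe,
      _["sstart"] = r_ss, _["send"] = r_se, _["score"] = r_sc,
      _["matches"] = r_mat, _["aln_len"] = r_len, _["gaps"] = r_gap);
}

// Score every window of a PSSM along an encoded sequence; letters outside
// 0..3 (e.g. N) contribute the value in row 5 of the matrix (usually 0).
// [[Rcpp::export]]
DataFrame cpp_pssm_scan(NumericMatrix pssm, IntegerVector seq,
                        double threshold) {
  const int W = pssm.ncol();
  const int n = seq.size();
  std::vector<int> r_pos; std::vector<double> r_sc;
  if (n >= W) {
    for (int p = 0; p + W <= n; ++p) {
      double sc = 0.0;
      for (int k = 0; k < W; ++k) {
        int c = seq[p + k];
        sc += pssm((c >= 0 && c < 4) ? c : 4, k);
      }
      if (sc >= threshold) { r_pos.push_back(p); r_sc.push_back(sc); }
    }
  }
  return DataFrame::create(_["pos"] = r_pos, _["score"] = r_sc);
}

// Max window score per non-overlapping block, for null calibration.
// [[Rcpp::export]]
NumericVector cpp_pssm_block_max(NumericMatrix pssm, IntegerVector seq,
                                 int block) {
  const int W = pssm.ncol();
  const int n = seq.size();
  int nb = n / block;
  NumericVector out(nb, R_NegInf);
  for (int b = 0; b < nb; ++b) {
    int lo = b * block, hi = std::min(n - W, (b + 1) * block - 1);
    double mx = R_NegInf;
    for (int p = lo; p <= hi; ++p) {
      double sc = 0.0;
      for (int k = 0; k < W; ++k) {
        int c = seq[p + k];
        sc += pssm((c >= 0 && c < 4) ? c : 4, k);
      }
      if (sc > mx) mx = sc;
    }
    out[b] = mx;
  }
  return out;
}

// DH RSS pattern scan: revcomp(nonamer) N12 revcomp(heptamer) core heptamer
// N12 nonamer, with core length in [core_min, core_max]. Mismatches counted
// over the four signal elements only. Returns every placement with total
// mismatches <= max_mm, plus a flag for exact CAC/GTG heptamer anchors.
// [[Rcpp::export]]
DataFrame cpp_dh_scan(IntegerVector seq, IntegerVector hept,
                      IntegerVector nona, int spacer, int core_min,
                      int core_max, int max_mm) {
  const int n = seq.size();
  const int H = hept.size(), N9 = nona.size();
  std::vector<int> rc_h(H), rc_n(N9);
  for (int i = 0; i < H; ++i) rc_h[i] = 3 - hept[H - 1 - i];
  for (int i = 0; i < N9; ++i) rc_n[i] = 3 - nona[N9 - 1 - i];
  std::vector<int> r_start, r_cs, r_ce, r_mm; std::vector<bool> r_anchor;
  for (int core = core_min; core <= core_max; ++core) {
    const int plen = N9 + spacer + H + core + H + spacer + N9;
    for (int p = 0; p + plen <= n; ++p) {
      int mm = 0;
      const int lh = p + N9 + spacer;            // left (revcomp) heptamer
      const int rh = lh + H + core;              // right heptamer
      const int rn = rh + H + spacer;            // right nonamer
      for (int k = 0; k < N9 && mm <= max_mm; ++k)
        if (seq[p + k] != rc_n[k]) ++mm;
      for (int k = 0; k < H && mm <= max_mm; ++k)
        if (seq[lh + k] != rc_h[k]) ++mm;
      for (int k = 0; k < H && mm <= max_mm; ++k)
        if (seq[rh + k] != hept[k]) ++mm;
      for (int k = 0; k < N9 && mm <= max_mm; ++k)
        if (seq[rn + k] != nona[k]) ++mm;
      if (mm <= max_mm) {
        // anchors: heptamer positions 1-3 exact on both copies. On the plus
        // strand the opposite-sense copy carries them as its final 3 bases.
        bool anchor = true;
        for (int k = 0; k < 3; ++k) {
          if (seq[rh + k] != hept[k]) anchor = false;
          if (seq[lh + H - 1 - k] != 3 - hept[k]) anchor = false;
        }
        r_start.push_back(p);
        r_cs.push_back(lh + H);
        r_ce.push_back(rh);
        r_mm.push_back(mm);
        r_anchor.push_back(anchor);
      }
    }
  }
  return DataFrame::create(_["start"] = r_start, _["core_start"] = r_cs,
                           _["core_end"] = r_ce, _["mismatches"] = r_mm,
                           _["anchors_exact"] = r_anchor);
}

// Global (Needleman-Wunsch) alignment of two column profiles for progressive
// MSA. Profiles are 4 x L frequency matrices over A,C,G,T (gap mass implicit:
// columns may sum to < 1). Column-pair score: sum fa_i fb_j s_ij with
// s_ii = match, s_ij = mismatch; linear gap penalty per column.
// Returns an integer path: 0 = both advance, 1 = gap in B, 2 = gap in A.
// [[Rcpp::export]]
IntegerVector cpp_profile_nw(NumericMatrix pa, NumericMatrix pb, double match,
                             double mismatch, double gap) {
  const int la = pa.ncol(), lb = pb.ncol();
  const int W = lb + 1;
  std::vector<double> S((la + 1) * (lb + 1));
  std::vector<uint8_t> tb((la + 1) * (lb + 1));
  S[0] = 0; tb[0] = 0;
  for (int j = 1; j <= lb; ++j) { S[j] = S[j - 1] + gap; tb[j] = 2; }
  for (int i = 1; i <= la; ++i) {
    S[i * W] = S[(i - 1) * W] + gap; tb[i * W] = 1;
    for (int j = 1; j <= lb; ++j) {
      double colsc = 0.0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          colsc += pa(x, i - 1) * pb(y, j - 1) * (x == y ? match : mismatch);
      double d = S[(i - 1) * W + (j - 1)] + colsc;
      double u = S[(i - 1) * W + j] + gap;
      double l = S[i * W + (j - 1)] + gap;
      double b = d; uint8_t t = 0;
      if (u > b) { b = u; t = 1; }
      if (l > b) { b = l; t = 2; }
      S[i * W + j] = b; tb[i * W + j] = t;
    }
  }
  std::vector<int> path;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    uint8_t t = tb[i * W + j];
    path.push_back(t);
    if (t == 0) { --i; --j; }
    else if (t == 1) --i;
    else --j;
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
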