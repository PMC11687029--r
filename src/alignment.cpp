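// Pairwise alignment and read-mapping engine.
//
// Provides an affine-gap Needleman-Wunsch aligner (global and semi-global),
// a seed-and-extend read mapper over a k-mer index, and strand-aware pileup
// accumulation. Scores are integer; a gap of length L costs gap_open +
// L * gap_extend (both passed as negative numbers).

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG_INF = INT32_MIN / 4;

// matrix ids: 0 = M (diagonal), 1 = E (gap in query a, consumes ref b),
// 2 = F (gap in ref b, consumes query a).
// Tie preference everywhere: M > E > F (match/mismatch > gap-in-query >
// gap-in-ref).

static inline int argmax3(int m, int e, int f, int& val) {
  val = m; int w = 0;
  if (e > val) { val = e; w = 1; }
  if (f > val) { val = f; w = 2; }
  return w;
}

struct AlnResult {
  int score;
  std::string a_aln;
  std::string b_aln;
  int b_start;  // 0-based count of unaligned ref prefix columns (semiglobal)
};

// a = query (rows), b = reference (columns).
// semiglobal: leading/trailing unaligned flanks of b are free.
static AlnResult nw_affine(const std::string& a, const std::string& b,
                           int match, int mismatch, int gap_open,
                           int gap_extend, bool semiglobal) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> M(m + 1), E(m + 1), F(m + 1);
  std::vector<int> Mp(m + 1), Ep(m + 1), Fp(m + 1);
  // per-cell packed sources: bits 0-1 = source matrix of M, 2-3 = of E,
  // 4-5 = of F
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  auto TB = [&](int i, int j) -> uint8_t& { return tb[(size_t)i * (m + 1) + j]; };

  // row 0: only E states reachable (or the free-start in semiglobal mode)
  Mp[0] = 0; Ep[0] = NEG_INF; Fp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Fp[j] = NEG_INF;
    Ep[j] = semiglobal ? 0 : gap_open + j * gap_extend;
    TB(0, j) |= (1 << 2);  // E from E
  }

  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF; E[0] = NEG_INF;
    F[0] = gap_open + i * gap_extend;
    TB(i, 0) |= (2 << 4);  // F from F
    for (int j = 1; j <= m; ++j) {
      const int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v;
      int msrc = argmax3(Mp[j - 1], Ep[j - 1], Fp[j - 1], v);
      M[j] = (v <= NEG_INF) ? NEG_INF : v + s;
      // E: consumes b[j-1]; open from best cell at (i, j-1) or extend E
      int lv;
      int lsrc = argmax3(M[j - 1], E[j - 1], F[j - 1], lv);
      int eopen = (lv <= NEG_INF) ? NEG_INF : lv + gap_open + gap_extend;
      int eext = (E[j - 1] <= NEG_INF) ? NEG_INF : E[j - 1] + gap_extend;
      int esrc;
      if (eext >= eopen) { E[j] = eext; esrc = 1; }
      else { E[j] = eopen; esrc = lsrc; }
      // F: consumes a[i-1]; open from best cell at (i-1, j) or extend F
      int uv;
      int usrc = argmax3(Mp[j], Ep[j], Fp[j], uv);
      int fopen = (uv <= NEG_INF) ? NEG_INF : uv + gap_open + gap_extend;
      int fext = (Fp[j] <= NEG_INF) ? NEG_INF : Fp[j] + gap_extend;
      int fsrc;
      if (fext >= fopen) { F[j] = fext; fsrc = 2; }
      else { F[j] = fopen; fsrc = usrc; }
      TB(i, j) = (uint8_t)(msrc | (esrc << 2) | (fsrc << 4));
    }
    std::swap(M, Mp); std::swap(E, Ep); std::swap(F, Fp);
  }

  // choose end cell
  int end_j = m, end_val;
  int cur = argmax3(Mp[m], Ep[m], Fp[m], end_val);
  if (semiglobal) {
    // scores were only kept for the last row in Mp/Ep/Fp after the final swap
    // -> recompute best over j by rescanning is impossible with rolling rows;
    // so track it during the loop instead (handled below).
    ;
  }
  // For semiglobal we need max over last-row cells; rerun the last row is
  // avoided by storing it: Mp/Ep/Fp ARE the last row here.
  if (semiglobal) {
    int bv = NEG_INF, bj = m, bcur = 0;
    for (int j = 0; j <= m; ++j) {
      int v; int w = argmax3(Mp[j], Ep[j], Fp[j], v);
      if (v > bv) { bv = v; bj = j; bcur = w; }
    }
    end_val = bv; end_j = bj; cur = bcur;
  }

  AlnResult res;
  res.score = end_val;

  // traceback
  std::string ra, rb;
  int i = n, j = end_j;
  while (i > 0 || j > 0) {
    if (semiglobal && i == 0) break;  // free leading flank of b
    uint8_t code = TB(i, j);
    if (cur == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      cur = code & 3; --i; --j;
    } else if (cur == 1) {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      cur = (code >> 2) & 3; --j;
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-');
      cur = (code >> 4) & 3; --i;
    }
  }
  res.b_start = j;
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.a_aln = ra;
  res.b_aln = rb;
  return res;
}

// Banded semiglobal affine DP: only cells with |j - i - off| <= bw are
// computed, where off is the expected diagonal offset of the query within
// the reference window (leading/trailing flanks of b free). Equivalent to
// the full semiglobal DP whenever the optimal path stays within the band.
static AlnResult nw_affine_banded(const std::string& a, const std::string& b,
                                  int match, int mismatch, int gap_open,
                                  int gap_extend, int off, int bw) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = 2 * bw + 1;
  // rolling rows indexed by j - (i + off - bw) in [0, W)
  std::vector<int> M(W), E(W), F(W), Mp(W), Ep(W), Fp(W);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  auto bidx = [&](int i, int j) { return j - (i + off - bw); };
  auto TB = [&](int i, int j) -> uint8_t& {
    return tb[(size_t)i * W + bidx(i, j)];
  };
  auto getp = [&](const std::vector<int>& row, int i, int j) {
    // row holds values for row i; valid j range is the band at row i
    int x = bidx(i, j);
    if (x < 0 || x >= W || j < 0 || j > m) return NEG_INF;
    return row[x];
  };

  // row 0: free leading flank of b within the band
  for (int x = 0; x < W; ++x) { Mp[x] = NEG_INF; Ep[x] = NEG_INF; Fp[x] = NEG_INF; }
  for (int j = std::max(0, off - bw); j <= std::min(m, off + bw); ++j) {
    Mp[bidx(0, j)] = 0;
  }

  for (int i = 1; i <= n; ++i) {
    for (int x = 0; x < W; ++x) { M[x] = NEG_INF; E[x] = NEG_INF; F[x] = NEG_INF; }
    const int jlo = std::max(0, i + off - bw);
    const int jhi = std::min(m, i + off + bw);
    for (int j = jlo; j <= jhi; ++j) {
      if (j == 0) {
        F[bidx(i, 0)] = gap_open + i * gap_extend;
        TB(i, 0) |= (2 << 4);
        continue;
      }
      const int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int v;
      int msrc = argmax3(getp(Mp, i - 1, j - 1), getp(Ep, i - 1, j - 1),
                         getp(Fp, i - 1, j - 1), v);
      const int x = bidx(i, j);
      M[x] = (v <= NEG_INF) ? NEG_INF : v + s;
      int lv;
      int lsrc = argmax3(getp(M, i, j - 1), getp(E, i, j - 1),
                         getp(F, i, j - 1), lv);
      int eopen = (lv <= NEG_INF) ? NEG_INF : lv + gap_open + gap_extend;
      int eprev = getp(E, i, j - 1);
      int eext = (eprev <= NEG_INF) ? NEG_INF : eprev + gap_extend;
      int esrc;
      if (eext >= eopen) { E[x] = eext; esrc = 1; }
      else { E[x] = eopen; esrc = lsrc; }
      int uv;
      int usrc = argmax3(getp(Mp, i - 1, j), getp(Ep, i - 1, j),
                         getp(Fp, i - 1, j), uv);
      int fopen = (uv <= NEG_INF) ? NEG_INF : uv + gap_open + gap_extend;
      int fprev = getp(Fp, i - 1, j);
      int fext = (fprev <= NEG_INF) ? NEG_INF : fprev + gap_extend;
      int fsrc;
      if (fext >= fopen) { F[x] = fext; fsrc = 2; }
      else { F[x] = fopen; fsrc = usrc; }
      TB(i, j) = (uint8_t)(msrc | (esrc << 2) | (fsrc << 4));
    }
    std::swap(M, Mp); std::swap(E, Ep); std::swap(F, Fp);
  }

  // best end cell over the banded part of the last row (free trailing flank)
  int bv = NEG_INF, bj = std::max(0, n + off - bw), cur = 0;
  for (int j = std::max(0, n + off - bw); j <= std::min(m, n + off + bw); ++j) {
    int v;
    int w = argmax3(getp(Mp, n, j), getp(Ep, n, j), getp(Fp, n, j), v);
    if (v > bv) { bv = v; bj = j; cur = w; }
  }

  AlnResult res;
  res.score = bv;
  std::string ra, rb;
  int i = n, j = bj;
  while (i > 0) {
    uint8_t code = TB(i, j);
    if (cur == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      cur = code & 3; --i; --j;
    } else if (cur == 1) {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      cur = (code >> 2) & 3; --j;
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-');
      cur = (code >> 4) & 3; --i;
    }
  }
  res.b_start = j;
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.a_aln = ra;
  res.b_aln = rb;
  return res;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend, bool semiglobal = false) {
  AlnResult r = nw_affine(a, b, match, mismatch, gap_open, gap_extend,
                          semiglobal);
  return List::create(_["score"] = r.score,
                      _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln,
                      _["b_start"] = r.b_start + 1);
}

// Banded semiglobal alignment (testing hook for the mapper fallback).
// [[Rcpp::export]]
List nw_banded_cpp(std::string a, std::string b, int match, int mismatch,
                   int gap_open, int gap_extend, int off, int bw) {
  AlnResult r = nw_affine_banded(a, b, match, mismatch, gap_open, gap_extend,
                                 off, bw);
  return List::create(_["score"] = r.score,
                      _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln,
                      _["b_start"] = r.b_start + 1);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp_base(c);
    out[i] = r;
  }
  out.names() = x.names();
  return out;
}

// sorted (kmer, pos) index over a reference string
struct KmerIndex {
  int k;
  std::vector<std::pair<uint64_t, int>> entries;  // pos 0-based
  void build(const std::string& ref, int k_) {
    k = k_;
    entries.clear();
    if ((int)ref.size() < k) return;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int i = 0; i < (int)ref.size(); ++i) {
      int c = base_code(ref[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= k) entries.push_back({key, i - k + 1});
    }
    std::sort(entries.begin(), entries.end());
  }
  void lookup(uint64_t key, std::vector<int>& hits, int cap) const {
    auto lo = std::lower_bound(entries.begin(), entries.end(),
                               std::make_pair(key, INT32_MIN));
    int c = 0;
    for (auto it = lo; it != entries.end() && it->first == key; ++it) {
      if (++c > cap) return;
      hits.push_back(it->second);
    }
  }
};

struct MapHit {
  bool mapped = false;
  bool fwd = true;
  int score = NEG_INF;
  double identity = 0.0;
  AlnResult aln;
  int win_start = 0;  // 0-based ref offset of alignment window
};

// most-voted diagonal. best_diag is the bucketed winner (tolerates small
// indels, used to place the banded-alignment window); exact_diag is the
// modal exact diagonal (used for the gapless fast path); n_votes counts
// seed hits supporting the winning bucket.
static bool best_candidate(const std::string& read, const KmerIndex& idx,
                           int& best_diag, int& exact_diag, int& n_votes) {
  const int k = idx.k;
  const int n = (int)read.size();
  if (n < k) return false;
  std::vector<std::pair<int, int>> votes;  // (bucket, diag)
  uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  std::vector<int> hits;
  const int stride = 4;
  for (int i = 0; i < n; ++i) {
    int c = base_code(read[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    ++valid;
    int qpos = i - k + 1;
    if (valid >= k && (qpos % stride) == 0) {
      hits.clear();
      idx.lookup(key, hits, 128);
      for (int rp : hits) votes.push_back({(rp - qpos) >> 4, rp - qpos});
    }
  }
  if (votes.empty()) return false;
  std::sort(votes.begin(), votes.end());
  int bestc = 0, curc = 0;
  size_t besti = 0;
  for (size_t i = 0; i < votes.size(); ++i) {
    if (i == 0 || votes[i].first != votes[i - 1].first) curc = 0;
    ++curc;
    if (curc > bestc) { bestc = curc; besti = i; }
  }
  best_diag = votes[besti].second;
  n_votes = bestc;
  // modal exact diagonal over all votes (one pass over the sorted list)
  int ebest = 0, ecur = 0;
  for (size_t i = 0; i < votes.size(); ++i) {
    if (i == 0 || votes[i].second != votes[i - 1].second) ecur = 0;
    ++ecur;
    if (ecur > ebest) { ebest = ecur; exact_diag = votes[i].second; }
  }
  return true;
}

// Gapless fast path: place the read at one exact diagonal with no gaps and
// count mismatches, bailing out past max_mm. With this package's scoring
// (mismatch delta 5, minimum gap cost 7) a gapless placement with <= 1
// mismatch is score-optimal, so pileup counts from it are exact; mapping-
// status-only callers may use a larger mismatch budget.
static bool gapless_hit(const std::string& q, const std::string& ref,
                        int diag, int max_mm, int match, int mismatch,
                        bool want_alignment, MapHit& out) {
  const int n = (int)q.size();
  if (diag < 0 || diag + n > (int)ref.size()) return false;
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (q[i] != ref[diag + i]) {
      if (++mm > max_mm) return false;
    }
  }
  out.mapped = true;
  out.score = (n - mm) * match + mm * mismatch;
  out.identity = (double)(n - mm) / n;
  out.win_start = diag;
  out.aln.score = out.score;
  out.aln.b_start = 0;
  if (want_alignment) {
    out.aln.a_aln = q;
    out.aln.b_aln = ref.substr(diag, n);
  }
  return true;
}

// fast_max_mm: mismatch budget of the gapless fast path (<= 1 keeps pileup
// counts exact; mapping-status-only callers may pass the identity-floor
// budget). want_alignment controls whether aligned strings are materialized
// on the fast path.
static MapHit map_read(const std::string& read, const std::string& ref,
                       const KmerIndex& idx, int band, int match, int mismatch,
                       int gap_open, int gap_extend, bool try_revcomp,
                       int fast_max_mm, bool want_alignment) {
  MapHit best;
  std::string rc;
  if (try_revcomp) {
    rc.assign(read.rbegin(), read.rend());
    for (auto& c : rc) c = comp_base(c);
  }
  const int n_ori = try_revcomp ? 2 : 1;
  int diag[2], ediag[2], nv[2] = {0, 0};
  bool cand[2] = {false, false};
  cand[0] = best_candidate(read, idx, diag[0], ediag[0], nv[0]);
  if (try_revcomp) cand[1] = best_candidate(rc, idx, diag[1], ediag[1], nv[1]);
  // try the better-seeded orientation first so its fast path can short-cut
  int order[2] = {0, 1};
  if (try_revcomp && cand[1] && (!cand[0] || nv[1] > nv[0])) {
    order[0] = 1; order[1] = 0;
  }
  for (int oi = 0; oi < n_ori; ++oi) {
    const int ori = order[oi];
    if (!cand[ori]) continue;
    const std::string& q = (ori == 0) ? read : rc;
    MapHit fh;
    if (gapless_hit(q, ref, ediag[ori], fast_max_mm, match, mismatch,
                    want_alignment, fh)) {
      // a near-perfect gapless placement cannot be beaten by the other
      // orientation or by a gapped alignment at this scoring
      fh.fwd = (ori == 0);
      return fh;
    }
    int ws = std::max(0, diag[ori] - band);
    int we = std::min((int)ref.size(), diag[ori] + (int)q.size() + band);
    if (we <= ws) continue;
    std::string win = ref.substr(ws, we - ws);
    AlnResult a = nw_affine_banded(q, win, match, mismatch, gap_open,
                                   gap_extend, diag[ori] - ws, band);
    if (a.score > best.score) {
      best.mapped = true;
      best.fwd = (ori == 0);
      best.score = a.score;
      best.aln = a;
      best.win_start = ws;
      int matches = 0, cols = 0;
      for (size_t i = 0; i < a.a_aln.size(); ++i) {
        ++cols;
        if (a.a_aln[i] == a.b_aln[i]) ++matches;
      }
      best.identity = (cols > 0) ? (double)matches / cols : 0.0;
    }
  }
  return best;
}

// Map reads to a reference and accumulate a strand-aware pileup.
// Returns per-position base/deletion counts by strand (rows A,C,G,T,del),
// insertion events anchored to the preceding reference position (1-based),
// and per-read mapping status.
// end_trim: number of aligned bases at each read end excluded from the
// counts. Reads ending one base past a deletion (or starting one base into
// one) have a score-optimal gapless alignment whose terminal base is a
// spurious substitution; trimming read ends removes that recurrent indel
// edge artifact, as aligner/caller stacks do via local realignment or
// read-position filters.
// [[Rcpp::export]]
List pileup_from_reads_cpp(CharacterVector reads, std::string ref, int k,
                           int band, int match, int mismatch, int gap_open,
                           int gap_extend, double identity_floor,
                           bool try_revcomp = true, bool build_pileup = true,
                           int end_trim = 2) {
  KmerIndex idx;
  idx.build(ref, k);
  const int L = (int)ref.size();
  IntegerMatrix fwd(build_pileup ? 5 : 0, build_pileup ? L : 0);
  IntegerMatrix rev(build_pileup ? 5 : 0, build_pileup ? L : 0);
  std::vector<int> ins_pos;
  std::vector<std::string> ins_seq;
  std::vector<int> ins_fwd;
  LogicalVector mapped(reads.size());
  IntegerVector strand(reads.size());

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    // exact pileups need a provably score-optimal fast path (<= 1 mismatch);
    // mapping-status-only calls can accept any gapless placement that
    // already clears the identity floor
    int fast_mm = build_pileup
      ? 1 : (int)((double)read.size() * (1.0 - identity_floor));
    MapHit h = map_read(read, ref, idx, band, match, mismatch, gap_open,
                        gap_extend, try_revcomp, fast_mm, build_pileup);
    bool ok = h.mapped && h.identity >= identity_floor;
    mapped[r] = ok;
    strand[r] = h.mapped ? (h.fwd ? 1 : -1) : NA_INTEGER;
    if (!ok || !build_pileup) continue;
    IntegerMatrix& cnt = h.fwd ? fwd : rev;
    int refpos = h.win_start + h.aln.b_start;  // 0-based next ref column
    const std::string& qa = h.aln.a_aln;
    const std::string& ba = h.aln.b_aln;
    int qlen = 0;
    for (char c : qa) if (c != '-') ++qlen;
    int qi = 0;  // query bases consumed so far
    size_t i = 0;
    while (i < qa.size()) {
      if (ba[i] == '-') {
        // insertion run in the read; anchor to the preceding ref position
        std::string s;
        while (i < qa.size() && ba[i] == '-') { s.push_back(qa[i]); ++i; }
        // drop unanchored/terminal runs and runs inside the trimmed ends
        if (refpos > 0 && i < qa.size() && qi >= end_trim &&
            qi + (int)s.size() <= qlen - end_trim) {
          ins_pos.push_back(refpos);        // 1-based preceding position
          ins_seq.push_back(s);
          ins_fwd.push_back(h.fwd ? 1 : 0);
        }
        qi += (int)s.size();
        continue;
      }
      if (qa[i] == '-') {
        // deletion between query bases qi-1 and qi; count only when both
        // flanks lie in the untrimmed interior
        if (qi >= end_trim && qlen - qi >= end_trim) cnt(4, refpos) += 1;
      } else {
        if (qi >= end_trim && qi < qlen - end_trim) {
          int c = base_code(qa[i]);
          if (c >= 0) cnt(c, refpos) += 1;
        }
        ++qi;
      }
      ++refpos;
      ++i;
    }
  }

  return List::create(_["fwd"] = fwd, _["rev"] = rev,
                      _["ins_pos"] = wrap(ins_pos),
                      _["ins_seq"] = wrap(ins_seq),
                      _["ins_fwd"] = wrap(ins_fwd),
                      _["mapped"] = mapped, _["strand"] = strand);
}

// Probe one seed at q[qpos, qpos+k) and accept a gapless placement within
// the mismatch budget at any seeded diagonal.
static bool probe_seed_at(const std::string& q, int qpos,
                          const std::string& ref, const KmerIndex& idx,
                          int max_mm, std::vector<int>& hits) {
  const int k = idx.k;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t key = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(q[qpos + i]);
    if (c < 0) return false;
    key = ((key << 2) | (uint64_t)c) & mask;
  }
  hits.clear();
  idx.lookup(key, hits, 64);
  MapHit dummy;
  for (int rp : hits) {
    if (gapless_hit(q, ref, rp - qpos, max_mm, 1, 0, false, dummy)) {
      return true;
    }
  }
  return false;
}

// Alternate forward/reverse seed probes so either orientation settles after
// a couple of index lookups.
static bool seed_probe_gapless(const std::string& fwd, const std::string& rc,
                               const std::string& ref, const KmerIndex& idx,
                               int max_mm, bool try_revcomp) {
  const int k = idx.k;
  const int n = (int)fwd.size();
  if (n < k) return false;
  std::vector<int> hits;
  for (int qpos = 0; qpos + k <= n; qpos += k) {
    if (probe_seed_at(fwd, qpos, ref, idx, max_mm, hits)) return true;
    if (try_revcomp &&
        probe_seed_at(rc, qpos, ref, idx, max_mm, hits)) return true;
  }
  return false;
}

// Identity-floor mapping status only (used for copy-number mapping stats).
// A gapless placement at a seeded diagonal that clears the identity floor
// settles a read immediately; only the remainder goes through the full
// seed-and-extend banded aligner.
// [[Rcpp::export]]
LogicalVector reads_mapped_cpp(CharacterVector reads, std::string ref, int k,
                               int band, int match, int mismatch, int gap_open,
                               int gap_extend, double identity_floor,
                               bool try_revcomp = true) {
  KmerIndex idx;
  idx.build(ref, k);
  LogicalVector mapped(reads.size());
  std::string rc;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    int budget = (int)((double)read.size() * (1.0 - identity_floor));
    if (try_revcomp) {
      rc.assign(read.rbegin(), read.rend());
      for (auto& c : rc) c = comp_base(c);
    }
    if (seed_probe_gapless(read, rc, ref, idx, budget, try_revcomp)) {
      mapped[r] = true;
      continue;
    }
    MapHit h = map_read(read, ref, idx, band, match, mismatch, gap_open,
                        gap_extend, try_revcomp, budget, false);
    mapped[r] = h.mapped && h.identity >= identity_floor;
  }
  return mapped;
}
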