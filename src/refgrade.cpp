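// Core sequence kernels: k-mer indexed unique read mapper with gapped
// extension, pileup construction with left-normalised anchored indels,
// quality-trim / adapter-clip scanning, per-base error injection and
// long-read local hit finding. Desk-scale replacements for the roles an
// external short/long read aligner plays in the full-size pipeline.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// ---------------------------------------------------------------------------
// Genome representation: chromosomes concatenated into one string; global
// coordinates are mapped back to (chrom, local) via the offset table.
struct Genome {
  std::string seq;                  // concatenated
  std::vector<size_t> offset;       // start of each chrom in seq
  std::vector<size_t> len;          // chrom lengths

  void build(const CharacterVector& refs) {
    size_t total = 0;
    for (R_xlen_t i = 0; i < refs.size(); ++i) total += LENGTH(STRING_ELT(refs, i));
    seq.reserve(total);
    for (R_xlen_t i = 0; i < refs.size(); ++i) {
      offset.push_back(seq.size());
      std::string s = as<std::string>(refs[i]);
      len.push_back(s.size());
      seq += s;
    }
  }
  // chrom index (0-based) containing global pos
  int chrom_of(size_t g) const {
    int lo = 0, hi = (int)offset.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (offset[mid] <= g) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

// Sorted (kmer, position) index.
struct KmerIndex {
  int k;
  std::vector<std::pair<uint64_t, uint32_t>> idx;

  void build(const Genome& g, int k_) {
    k = k_;
    const std::string& s = g.seq;
    if ((int)s.size() < k) return;
    idx.reserve(s.size());
    // recompute kmer from scratch at chrom starts / after non-ACGT
    for (size_t ci = 0; ci < g.offset.size(); ++ci) {
      size_t beg = g.offset[ci], end = beg + g.len[ci];
      if (g.len[ci] < (size_t)k) continue;
      uint64_t kmer = 0; int valid = 0;
      for (size_t i = beg; i < end; ++i) {
        int c = base_code(s[i]);
        if (c == 4) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & ((k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1));
        if (++valid >= k) idx.emplace_back(kmer, (uint32_t)(i - k + 1));
      }
    }
    std::sort(idx.begin(), idx.end());
  }

  void lookup(uint64_t kmer, std::vector<uint32_t>& out, size_t cap) const {
    auto lo = std::lower_bound(idx.begin(), idx.end(),
                               std::make_pair(kmer, (uint32_t)0));
    for (auto it = lo; it != idx.end() && it->first == kmer && out.size() < cap; ++it)
      out.push_back(it->second);
  }
};

static bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& kmer) {
  kmer = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c == 4) return false;
    kmer = (kmer << 2) | (uint64_t)c;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Semiglobal alignment (read global, reference-window ends free) with affine
// gaps: match +1, mismatch -2, gap open -3, gap extend -1. Window sizes are
// tiny (read length + 2*pad) so a full DP is used.
struct AlnResult {
  int score = INT32_MIN;
  size_t ref_start = 0;       // within window
  std::string cigar;
  int nm = 0;
};

static const int MATCH = 1, MISM = -2, GAP_OPEN = -3, GAP_EXT = -1;
static const int NEG = -100000000;

static AlnResult align_window(const std::string& read, const std::string& ref) {
  const int n = (int)read.size(), m = (int)ref.size();
  std::vector<int> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<char> tb((n + 1) * (m + 1), 0); // bits: which matrix best came from
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) M[at(0, j)] = 0;           // free ref prefix
  for (int i = 1; i <= n; ++i)                            // read-only = insertion
    X[at(i, 0)] = GAP_OPEN + (i - 1) * GAP_EXT;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (base_code(read[i - 1]) != 4 &&
               base_code(read[i - 1]) == base_code(ref[j - 1])) ? MATCH : MISM;
      int mm = std::max({M[at(i - 1, j - 1)], X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]});
      M[at(i, j)] = mm + s;
      // X: gap in ref (read base consumed, insertion in read)
      int xo = std::max({M[at(i - 1, j)], Y[at(i - 1, j)]}) + GAP_OPEN;
      int xe = X[at(i - 1, j)] + GAP_EXT;
      X[at(i, j)] = std::max(xo, xe);
      // Y: gap in read (ref base consumed, deletion from read)
      int yo = std::max({M[at(i, j - 1)], X[at(i, j - 1)]}) + GAP_OPEN;
      int ye = Y[at(i, j - 1)] + GAP_EXT;
      Y[at(i, j)] = std::max(yo, ye);
    }
  }
  AlnResult res;
  int bj = m;
  for (int j = 0; j <= m; ++j) {
    int v = std::max(M[at(n, j)], X[at(n, j)]); // Y at end would be trailing D, skip
    if (v > res.score) { res.score = v; bj = j; }
  }
  // traceback
  int i = n, j = bj;
  int state; // 0 = M, 1 = X, 2 = Y
  {
    int vm = M[at(i, j)], vx = X[at(i, j)];
    state = (vm >= vx) ? 0 : 1;
  }
  std::vector<std::pair<char, int>> ops; // reversed
  int nm = 0;
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.emplace_back(op, 1);
  };
  while (i > 0) {
    if (state == 0) {
      int s = (base_code(read[i - 1]) != 4 &&
               base_code(read[i - 1]) == base_code(ref[j - 1])) ? MATCH : MISM;
      if (s == MISM) nm++;
      push('M');
      int prev = M[at(i, j)] - s;
      if (M[at(i - 1, j - 1)] == prev) state = 0;
      else if (X[at(i - 1, j - 1)] == prev) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      push('I'); nm++;
      if (X[at(i, j)] == X[at(i - 1, j)] + GAP_EXT) state = 1;
      else state = (M[at(i - 1, j)] >= Y[at(i - 1, j)]) ? 0 : 2;
      --i;
    } else {
      if (i < n) { push('D'); nm++; }
      if (Y[at(i, j)] == Y[at(i, j - 1)] + GAP_EXT) state = 2;
      else state = (M[at(i, j - 1)] >= X[at(i, j - 1)]) ? 0 : 1;
      --j;
    }
  }
  res.ref_start = (size_t)j;
  // expand to per-column ops (in alignment order) for end soft-clipping
  std::vector<char> col;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    for (int t = 0; t < it->second; ++t) col.push_back(it->first);
  // per-column info: read/ref consumption and score delta
  const int nc = (int)col.size();
  std::vector<int> delta(nc);
  std::vector<bool> colmm(nc, false);
  {
    int qi = 0; size_t rj = res.ref_start;
    char prev = 0;
    for (int c2 = 0; c2 < nc; ++c2) {
      if (col[c2] == 'M') {
        bool mm = !(base_code(read[qi]) != 4 &&
                    base_code(read[qi]) == base_code(ref[rj]));
        colmm[c2] = mm;
        delta[c2] = mm ? MISM : MATCH;
        ++qi; ++rj;
      } else if (col[c2] == 'I') {
        delta[c2] = (prev == 'I') ? GAP_EXT : GAP_OPEN;
        colmm[c2] = true;
        ++qi;
      } else { // D
        delta[c2] = (prev == 'D') ? GAP_EXT : GAP_OPEN;
        colmm[c2] = true;
        ++rj;
      }
      prev = col[c2];
    }
  }
  // soft-clip a leading/trailing stretch whose partial score is negative
  // (a production aligner clips breakpoint-overhang tails the same way;
  // forcing them to align pollutes flanking pileup columns)
  int lo = 0, hi = nc;
  {
    int run = 0, minv = 0, cut = 0;
    for (int c2 = 0; c2 < nc; ++c2) {
      run += delta[c2];
      if (run < minv) { minv = run; cut = c2 + 1; }
    }
    if (minv < 0) lo = cut;
    run = 0; minv = 0; cut = nc;
    for (int c2 = nc - 1; c2 >= lo; --c2) {
      run += delta[c2];
      if (run < minv) { minv = run; cut = c2; }
    }
    if (minv < 0) hi = cut;
  }
  int clip5 = 0, clip3 = 0, nm2 = 0, score2 = 0;
  size_t ref_shift = 0;
  for (int c2 = 0; c2 < lo; ++c2) {
    if (col[c2] == 'M' || col[c2] == 'I') ++clip5;
    if (col[c2] == 'M' || col[c2] == 'D') ++ref_shift;
  }
  for (int c2 = hi; c2 < nc; ++c2)
    if (col[c2] == 'M' || col[c2] == 'I') ++clip3;
  std::vector<std::pair<char, int>> ops2;
  auto push2 = [&ops2](char op, int k) {
    if (k <= 0) return;
    if (!ops2.empty() && ops2.back().first == op) ops2.back().second += k;
    else ops2.emplace_back(op, k);
  };
  push2('S', clip5);
  for (int c2 = lo; c2 < hi; ++c2) {
    push2(col[c2], 1);
    score2 += delta[c2];
    if (colmm[c2]) ++nm2;
  }
  push2('S', clip3);
  // drop leading/trailing D inside the kept region (cannot border a clip)
  while (!ops2.empty() && ops2.front().first == 'S' && ops2.size() > 1 &&
         ops2[1].first == 'D') {
    ref_shift += ops2[1].second;
    score2 -= (GAP_OPEN + (ops2[1].second - 1) * GAP_EXT);
    nm2 -= ops2[1].second;
    ops2.erase(ops2.begin() + 1);
  }
  while (ops2.size() > 1 && ops2.back().first == 'S' &&
         ops2[ops2.size() - 2].first == 'D') {
    score2 -= (GAP_OPEN + (ops2[ops2.size() - 2].second - 1) * GAP_EXT);
    nm2 -= ops2[ops2.size() - 2].second;
    ops2.erase(ops2.end() - 2);
  }
  res.ref_start += ref_shift;
  res.score = score2;
  res.nm = nm2;
  std::string cg;
  for (auto& o : ops2) cg += std::to_string(o.second) + o.first;
  res.cigar = cg;
  return res;
}

static int count_mismatch(const std::string& read, const std::string& g,
                          size_t gpos, int cap) {
  int mism = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    int a = base_code(read[i]), b = base_code(g[gpos + i]);
    if (a == 4 || a != b) { if (++mism > cap) return mism; }
  }
  return mism;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                        int k = 21, int margin = 6, int score_slack = 16,
                        int seed_cap = 64) {
  Genome g; g.build(ref_seqs);
  KmerIndex ki; ki.build(g, k);
  const int n = read_seqs.size();
  IntegerVector out_chrom(n), out_pos(n), out_mapq(n), out_nm(n), out_score(n);
  CharacterVector out_strand(n), out_cigar(n), out_place(n);

  struct Cand { int score; size_t gstart; int strand; std::string cigar; int nm; };
  std::vector<uint32_t> occ;

  for (int r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    const int L = (int)fwd.size();
    std::vector<Cand> cands;
    if (L >= k) {
      std::string rc = revcomp(fwd);
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& s = (strand == 0) ? fwd : rc;
        std::vector<long long> raw;
        int offs[3] = {0, (L - k) / 2, L - k};
        for (int oi = 0; oi < 3; ++oi) {
          int o = offs[oi];
          if (oi > 0 && o == offs[oi - 1]) continue;
          uint64_t kmer;
          if (!encode_kmer(s, (size_t)o, k, kmer)) continue;
          occ.clear();
          ki.lookup(kmer, occ, (size_t)seed_cap);
          for (uint32_t p : occ) raw.push_back((long long)p - o);
        }
        std::sort(raw.begin(), raw.end());
        raw.erase(std::unique(raw.begin(), raw.end()), raw.end());
        long long last = -1000000;
        for (long long cand : raw) {
          if (cand - last <= 6) continue; // merged into previous candidate
          last = cand;
          if (cand < 0) cand = 0;
          int ci = g.chrom_of((size_t)std::min<long long>(cand, (long long)g.seq.size() - 1));
          long long cbeg = (long long)g.offset[ci];
          long long cend = cbeg + (long long)g.len[ci];
          if (cand + L > cend) cand = cend - L;
          if (cand < cbeg) continue; // read longer than chrom
          // accept ungapped only when perfect; otherwise the full DP decides
          // (a shifted ungapped alignment can fake few mismatches around an
          // indel in periodic sequence)
          int mism = count_mismatch(s, g.seq, (size_t)cand, 0);
          if (mism == 0) {
            cands.push_back({L - 3 * mism, (size_t)cand, strand,
                             std::to_string(L) + "M", mism});
          } else {
            long long w0 = std::max(cbeg, cand - 6);
            long long w1 = std::min(cend, cand + L + 6);
            AlnResult a = align_window(s, g.seq.substr((size_t)w0, (size_t)(w1 - w0)));
            cands.push_back({a.score, (size_t)w0 + a.ref_start, strand, a.cigar, a.nm});
          }
        }
      }
    }
    // dedupe identical placements, keep best score
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.gstart != b.gstart) return a.gstart < b.gstart;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.score > b.score;
    });
    std::vector<Cand> uniq;
    for (auto& c : cands) {
      if (!uniq.empty() && uniq.back().strand == c.strand &&
          (c.gstart - uniq.back().gstart) <= 4) continue;
      uniq.push_back(c);
    }
    int best = -1, second = -1;
    for (size_t i = 0; i < uniq.size(); ++i) {
      if (best < 0 || uniq[i].score > uniq[best].score) { second = best; best = (int)i; }
      else if (second < 0 || uniq[i].score > uniq[second].score) second = (int)i;
    }
    int min_score = L - score_slack;
    if (best < 0 || uniq[best].score < min_score) {
      out_place[r] = "unmapped"; out_chrom[r] = NA_INTEGER; out_pos[r] = NA_INTEGER;
      out_mapq[r] = 0; out_strand[r] = "+"; out_cigar[r] = NA_STRING;
      out_nm[r] = NA_INTEGER; out_score[r] = NA_INTEGER;
      continue;
    }
    const Cand& b = uniq[best];
    int ci = g.chrom_of(b.gstart);
    out_chrom[r] = ci + 1;
    out_pos[r] = (int)(b.gstart - g.offset[ci]) + 1;
    out_strand[r] = (b.strand == 0) ? "+" : "-";
    out_cigar[r] = b.cigar;
    out_nm[r] = b.nm;
    out_score[r] = b.score;
    bool tied = (second >= 0 && uniq[second].score >= b.score - margin);
    out_place[r] = tied ? "multiple" : "unique";
    out_mapq[r] = tied ? 0 : 60;
  }
  return DataFrame::create(
      _["chrom"] = out_chrom, _["pos"] = out_pos, _["strand"] = out_strand,
      _["mapq"] = out_mapq, _["cigar"] = out_cigar, _["nm"] = out_nm,
      _["score"] = out_score, _["placement"] = out_place,
      _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Pileup: base counts per reference column plus anchored, left-normalised
// indel alleles. Positions are 1-based. seq[i] must be oriented to the
// reference (reverse-complemented beforehand for minus-strand records).
// [[Rcpp::export]]
List cpp_build_pileup(CharacterVector ref_seqs, IntegerVector chrom,
                      IntegerVector pos, CharacterVector cigar,
                      CharacterVector seq) {
  const int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);
  std::vector<std::vector<int>> counts(nref);
  for (int i = 0; i < nref; ++i) counts[i].assign(5 * refs[i].size(), 0);

  // indel key -> count; key = chrom, anchor(0-based), type(0 ins/1 del), seq
  std::map<std::tuple<int, long long, int, std::string>, int> indels;

  const int n = chrom.size();
  for (int r = 0; r < n; ++r) {
    if (chrom[r] == NA_INTEGER) continue;
    int ci = chrom[r] - 1;
    const std::string& ref = refs[ci];
    std::string s = as<std::string>(seq[r]);
    std::string cg = as<std::string>(cigar[r]);
    long long rp = (long long)pos[r] - 1; // 0-based ref cursor
    size_t qp = 0;                        // read cursor
    size_t i = 0;
    while (i < cg.size()) {
      size_t j = i;
      int len = 0;
      while (j < cg.size() && cg[j] >= '0' && cg[j] <= '9') {
        len = len * 10 + (cg[j] - '0');
        ++j;
      }
      char op = cg[j];
      i = j + 1;
      if (op == 'M' || op == '=' || op == 'X') {
        for (int t = 0; t < len; ++t) {
          if (rp + t >= 0 && rp + t < (long long)ref.size())
            counts[ci][5 * (rp + t) + base_code(s[qp + t])]++;
        }
        rp += len; qp += len;
      } else if (op == 'I') {
        std::string ins = s.substr(qp, len);
        long long anchor = rp - 1; // base left of insertion, 0-based
        // left-normalise: shift while ref base at anchor equals last inserted base
        while (anchor >= 0 && base_code(ref[anchor]) != 4 &&
               base_code(ref[anchor]) == base_code(ins.back())) {
          ins = ins.back() + ins.substr(0, ins.size() - 1);
          anchor--;
        }
        if (anchor >= 0)
          indels[std::make_tuple(ci, anchor, 0, ins)]++;
        qp += len;
      } else if (op == 'D') {
        long long dstart = rp; // first deleted ref base, 0-based
        while (dstart > 0 &&
               base_code(ref[dstart - 1]) == base_code(ref[dstart + len - 1]))
          dstart--;
        long long anchor = dstart - 1;
        if (anchor >= 0)
          indels[std::make_tuple(ci, anchor,  1,
                                 ref.substr(dstart, len))]++;
        rp += len;
      } else if (op == 'S') {
        qp += len;
      } else if (op == 'N') {
        rp += len;
      } else if (op == 'H' || op == 'P') {
        // consume nothing
      } else {
        stop("unsupported CIGAR op");
      }
    }
  }

  List mats(nref);
  for (int i = 0; i < nref; ++i) {
    IntegerMatrix m(5, refs[i].size());
    std::copy(counts[i].begin(), counts[i].end(), m.begin());
    m.attr("dimnames") = List::create(
        CharacterVector::create("A", "C", "G", "T", "N"), R_NilValue);
    mats[i] = m;
  }
  int ni = (int)indels.size();
  IntegerVector ic(ni), ip(ni), il(ni), icount(ni);
  CharacterVector itype(ni), iseq(ni);
  int w = 0;
  for (auto& kv : indels) {
    ic[w] = std::get<0>(kv.first) + 1;
    ip[w] = (int)std::get<1>(kv.first) + 1; // back to 1-based anchor
    itype[w] = (std::get<2>(kv.first) == 0) ? "ins" : "del";
    iseq[w] = std::get<3>(kv.first);
    il[w] = (int)std::get<3>(kv.first).size();
    icount[w] = kv.second;
    ++w;
  }
  DataFrame idf = DataFrame::create(
      _["chrom"] = ic, _["anchor"] = ip, _["type"] = itype, _["len"] = il,
      _["seq"] = iseq, _["count"] = icount, _["stringsAsFactors"] = false);
  return List::create(_["counts"] = mats, _["indels"] = idf);
}

// ---------------------------------------------------------------------------
// Quality trimming bounds: scan inward from each end to the first pair of
// consecutive bases with quality >= threshold. Returns 1-based [start, end];
// start 0 means the whole read is discarded.
// [[Rcpp::export]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int threshold = 20,
                              int phred_offset = 33) {
  const int n = quals.size();
  IntegerMatrix out(n, 2);
  const int thr = threshold + phred_offset;
  for (int r = 0; r < n; ++r) {
    const char* q = CHAR(STRING_ELT(quals, r));
    int L = (int)LENGTH(STRING_ELT(quals, r));
    int start = -1, end = -1;
    for (int i = 0; i + 1 < L; ++i)
      if (q[i] >= thr && q[i + 1] >= thr) { start = i; break; }
    for (int i = L - 1; i >= 1; --i)
      if (q[i] >= thr && q[i - 1] >= thr) { end = i; break; }
    if (start < 0 || end < 0 || end < start) { out(r, 0) = 0; out(r, 1) = 0; }
    else { out(r, 0) = start + 1; out(r, 1) = end + 1; }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Adapter clipping: leftmost 3'-anchored occurrence of any adapter with
// overlap >= min_match and mismatches <= floor(overlap * max_mm_frac).
// An occurrence either covers the full adapter or runs to the read end.
// Returns the kept length (sequence truncated before the occurrence).
// [[Rcpp::export]]
IntegerVector cpp_clip_length(CharacterVector seqs, CharacterVector adapters,
                              int min_match = 5, double max_mm_frac = 0.10) {
  const int n = seqs.size();
  IntegerVector out(n);
  std::vector<std::string> ads;
  for (R_xlen_t a = 0; a < adapters.size(); ++a)
    ads.push_back(as<std::string>(adapters[a]));
  for (int r = 0; r < n; ++r) {
    const std::string s = as<std::string>(seqs[r]);
    const int L = (int)s.size();
    int cut = L;
    for (const auto& ad : ads) {
      const int alen = (int)ad.size();
      for (int i = 0; i < cut; ++i) {
        int overlap = std::min(L - i, alen);
        if (overlap < min_match) break;
        int allowed = (int)(overlap * max_mm_frac);
        int mism = 0;
        bool ok = true;
        for (int t = 0; t < overlap; ++t) {
          if (base_code(s[i + t]) != base_code(ad[t]) ||
              base_code(ad[t]) == 4) {
            if (++mism > allowed) { ok = false; break; }
          }
        }
        if (ok) { cut = i; break; }
      }
    }
    out[r] = cut;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-base substitution errors at a fixed rate, using R's RNG so that
// set.seed() governs the outcome.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
  const int n = seqs.size();
  CharacterVector out(n);
  const char* bases = "ACGT";
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() < rate) {
        int c = base_code(s[i]);
        if (c == 4) continue;
        int nc = (c + 1 + (int)(unif_rand() * 3)) % 4;
        if (nc == c) nc = (c + 1) % 4;
        s[i] = bases[nc];
      }
    }
    out[r] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Long-read local hits: k-mer seeding, diagonal clustering, greedy X-drop
// extension. Coordinates are 1-based closed; for minus-strand hits the read
// interval refers to the reverse-complemented read.
// [[Rcpp::export]]
DataFrame cpp_local_hits(CharacterVector ref_seqs, CharacterVector read_seqs,
                         int k = 15, int min_len = 40, double min_identity = 0.8,
                         int margin = 6, int xdrop = 12, int seed_cap = 100) {
  Genome g; g.build(ref_seqs);
  KmerIndex ki; ki.build(g, k);

  std::vector<int> o_read, o_chrom, o_rs, o_re, o_gs, o_ge, o_score, o_nm;
  std::vector<std::string> o_strand;
  std::vector<int> o_amb;

  std::vector<uint32_t> occ;
  for (int r = 0; r < read_seqs.size(); ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    const int L = (int)fwd.size();
    struct Hit { int rs, re; long long gs, ge; int score, nm, strand; bool amb = false; };
    std::vector<Hit> hits;
    if (L >= k) {
      std::string rc = revcomp(fwd);
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& s = (strand == 0) ? fwd : rc;
        std::vector<std::pair<long long, int>> seeds; // (diag, readpos)
        for (int i = 0; i + k <= L; i += 2) {
          uint64_t kmer;
          if (!encode_kmer(s, (size_t)i, k, kmer)) continue;
          occ.clear();
          ki.lookup(kmer, occ, (size_t)seed_cap);
          for (uint32_t p : occ) seeds.emplace_back((long long)p - i, i);
        }
        std::sort(seeds.begin(), seeds.end());
        size_t a = 0;
        while (a < seeds.size()) {
          size_t b = a + 1;
          int rmin = seeds[a].second, rmax = seeds[a].second;
          long long dref = seeds[a].first;
          while (b < seeds.size() && seeds[b].first - seeds[b - 1].first <= 8 &&
                 seeds[b].first - dref <= 8) {
            rmin = std::min(rmin, seeds[b].second);
            rmax = std::max(rmax, seeds[b].second);
            ++b;
          }
          // chain on (near-)constant diagonal
          long long g0 = dref + rmin, g1 = dref + rmax + k;
          int r0 = rmin, r1 = rmax + k;
          int ci = g.chrom_of((size_t)std::max(0LL, std::min(g0, (long long)g.seq.size() - 1)));
          long long cbeg = (long long)g.offset[ci], cend = cbeg + (long long)g.len[ci];
          if (g0 < cbeg || g1 > cend) { a = b; continue; }
          int score = r1 - r0, nm = 0;
          // greedy extension with X-drop
          {
            int cur = 0, bestd = 0, besti = 0;
            int i2 = r0 - 1; long long j2 = g0 - 1;
            int step = 0;
            while (i2 >= 0 && j2 >= cbeg) {
              cur += (base_code(s[i2]) == base_code(g.seq[(size_t)j2]) &&
                      base_code(s[i2]) != 4) ? MATCH : -5;
              ++step;
              if (cur > bestd) { bestd = cur; besti = step; }
              if (bestd - cur > xdrop) break;
              --i2; --j2;
            }
            for (int t = 1; t <= besti; ++t)
              if (base_code(s[r0 - t]) != base_code(g.seq[(size_t)(g0 - t)])) nm++;
            score += bestd; r0 -= besti; g0 -= besti;
          }
          {
            int cur = 0, bestd = 0, besti = 0;
            int i2 = r1; long long j2 = g1;
            int step = 0;
            while (i2 < L && j2 < cend) {
              cur += (base_code(s[i2]) == base_code(g.seq[(size_t)j2]) &&
                      base_code(s[i2]) != 4) ? MATCH : -5;
              ++step;
              if (cur > bestd) { bestd = cur; besti = step; }
              if (bestd - cur > xdrop) break;
              ++i2; ++j2;
            }
            for (int t = 0; t < besti; ++t)
              if (base_code(s[r1 + t]) != base_code(g.seq[(size_t)(g1 + t)])) nm++;
            score += bestd; r1 += besti; g1 += besti;
          }
          int hlen = r1 - r0;
          if (hlen >= min_len && (double)(hlen - nm) / hlen >= min_identity)
            hits.push_back({r0, r1, g0, g1, score, nm, strand});
          a = b;
        }
      }
    }
    // merge duplicate hits (same strand, similar diagonal, overlapping on read)
    std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
      return x.score > y.score;
    });
    std::vector<Hit> kept;
    for (auto& h : hits) {
      bool dup = false;
      for (auto& kh : kept) {
        if (kh.strand == h.strand &&
            std::llabs((kh.gs - kh.rs) - (h.gs - h.rs)) <= 8 &&
            std::max(kh.rs, h.rs) < std::min(kh.re, h.re)) { dup = true; break; }
      }
      if (!dup) kept.push_back(h);
    }
    // ambiguity: another kept hit covering >=50% of the same read interval
    // within the score margin
    for (size_t x = 0; x < kept.size(); ++x) {
      for (size_t y = 0; y < kept.size(); ++y) {
        if (x == y) continue;
        int ov = std::min(kept[x].re, kept[y].re) - std::max(kept[x].rs, kept[y].rs);
        int mlen = std::min(kept[x].re - kept[x].rs, kept[y].re - kept[y].rs);
        if (ov * 2 >= mlen && kept[y].score >= kept[x].score - margin)
          kept[x].amb = true;
      }
    }
    for (auto& h : kept) {
      int ci = g.chrom_of((size_t)h.gs);
      o_read.push_back(r + 1);
      o_strand.push_back(h.strand == 0 ? "+" : "-");
      o_rs.push_back(h.rs + 1);
      o_re.push_back(h.re);
      o_chrom.push_back(ci + 1);
      o_gs.push_back((int)(h.gs - g.offset[ci]) + 1);
      o_ge.push_back((int)(h.ge - g.offset[ci]));
      o_score.push_back(h.score);
      o_nm.push_back(h.nm);
      o_amb.push_back(h.amb ? 1 : 0);
    }
  }
  return DataFrame::create(
      _["read"] = wrap(o_read), _["strand"] = wrap(o_strand),
      _["read_start"] = wrap(o_rs), _["read_end"] = wrap(o_re),
      _["chrom"] = wrap(o_chrom), _["ref_start"] = wrap(o_gs),
      _["ref_end"] = wrap(o_ge), _["score"] = wrap(o_score),
      _["nm"] = wrap(o_nm), _["ambiguous"] = wrap(o_amb),
      _["stringsAsFactors"] = false);
}
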