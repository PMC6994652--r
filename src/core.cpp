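// Core sequence machinery: k-mer seed/extend read matcher, pileup
// accumulator and de Bruijn unitig assembler. These are desk-scale
// stand-ins with exactly specified behaviour (deterministic tie-breaks,
// ungapped extension, single-indel dual-anchor mode); they are not
// re-implementations of production aligners/assemblers.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <map>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static inline char bits2base(int b) { return "ACGT"[b & 3]; }
static inline char comp(char c) {
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
  for (auto& c : r) c = comp(c);
  return r;
}

// ---------------------------------------------------------------- index

struct SeedHit { int contig; int pos; };  // pos 0-based

typedef std::unordered_map<uint64_t, std::vector<SeedHit> > KmerIndex;

static void index_genome(const std::vector<std::string>& seqs, int k,
                         KmerIndex& idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    if ((int)s.size() < k) continue;
    uint64_t code = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        idx[code].push_back(SeedHit{ (int)ci, (int)(i - k + 1) });
      }
    }
  }
}

static inline bool encode_kmer(const std::string& s, int off, int k,
                               uint64_t& code) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[off + i]);
    if (b < 0) return false;
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

static int count_mismatches(const std::string& read, const std::string& ref,
                            int start, int stop_after) {
  int nm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char a = read[i], b = ref[start + i];
    if (a != b || base2bits(a) < 0) {
      if (++nm > stop_after) return nm;
    }
  }
  return nm;
}

// ---- banded global alignment with affine gaps (cost minimization) ----
// costs: match 0, mismatch 2, gap open 6 (includes first base), extend 2.
// Aligns the whole read against ref[start .. start+len+delta-1]; used in
// gapped mode so clustered edits (several indels/SNPs within one read)
// are all recovered. Band half-width `bw` around the shifting diagonal.
struct DPResult {
  bool ok = false;
  int nm = 0, gapbases = 0, cost = 0, refspan = 0;
  std::string cigar;
};

static const int MM_COST = 2, GAP_OPEN = 6, GAP_EXT = 2;
static const int DP_INF = 1 << 28;

// Aligns the whole read against ref[start .. start+m-1], band j-i in
// [lo, hi]. With free_end the alignment may stop at any ref column at
// i = n (semi-global: one read end anchored by the caller's seed, the
// other free); otherwise both ends are pinned.
static DPResult banded_align(const std::string& read, const std::string& ref,
                             int start, int m, int lo, int hi, int maxmm,
                             bool free_end) {
  DPResult out;
  int n = (int)read.size();
  int W = hi - lo + 1;
  // layered band matrices: 0 = M (diag), 1 = D (ref gap), 2 = I (read gap)
  std::vector<int> cost(3 * (n + 1) * W, DP_INF);
  std::vector<unsigned char> from(3 * (n + 1) * W, 255);
  auto at = [&](int layer, int i, int j) -> int {
    int off = j - i - lo;
    if (off < 0 || off >= W) return -1;
    return (layer * (n + 1) + i) * W + off;
  };
  { int c0 = at(0, 0, 0); cost[c0] = 0; }
  for (int j = 1; j <= m && j <= hi; ++j) {       // leading ref gap (D)
    int c = at(1, 0, j);
    if (c >= 0) { cost[c] = GAP_OPEN + GAP_EXT * (j - 1); from[c] = 1; }
  }
  for (int i = 1; i <= n; ++i) {
    int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      if (j == 0) {                                // leading read gap (I)
        int c = at(2, i, 0);
        if (c >= 0) {
          cost[c] = GAP_OPEN + GAP_EXT * (i - 1);
          from[c] = 2;
        }
        continue;
      }
      // M: diagonal
      int cm = at(0, i, j);
      if (cm >= 0) {
        char rb = ref[start + j - 1], qb = read[i - 1];
        int sub = (rb == qb && base2bits(qb) >= 0) ? 0 : MM_COST;
        int bestc = DP_INF; unsigned char bf = 255;
        for (int l = 0; l < 3; ++l) {
          int p = at(l, i - 1, j - 1);
          if (p >= 0 && cost[p] + sub < bestc) {
            bestc = cost[p] + sub; bf = (unsigned char)l;
          }
        }
        if (bf != 255) { cost[cm] = bestc; from[cm] = bf; }
      }
      // D: consume ref only
      int cd = at(1, i, j);
      if (cd >= 0) {
        int bestc = DP_INF; unsigned char bf = 255;
        int p = at(1, i, j - 1);
        if (p >= 0 && cost[p] + GAP_EXT < bestc) {
          bestc = cost[p] + GAP_EXT; bf = 1;
        }
        for (int l = 0; l < 3; l += 2) {
          int q = at(l, i, j - 1);
          if (q >= 0 && cost[q] + GAP_OPEN < bestc) {
            bestc = cost[q] + GAP_OPEN; bf = (unsigned char)l;
          }
        }
        if (bf != 255) { cost[cd] = bestc; from[cd] = bf; }
      }
      // I: consume read only
      int ci = at(2, i, j);
      if (ci >= 0) {
        int bestc = DP_INF; unsigned char bf = 255;
        int p = at(2, i - 1, j);
        if (p >= 0 && cost[p] + GAP_EXT < bestc) {
          bestc = cost[p] + GAP_EXT; bf = 2;
        }
        for (int l = 0; l < 2; ++l) {
          int q = at(l, i - 1, j);
          if (q >= 0 && cost[q] + GAP_OPEN < bestc) {
            bestc = cost[q] + GAP_OPEN; bf = (unsigned char)l;
          }
        }
        if (bf != 255) { cost[ci] = bestc; from[ci] = bf; }
      }
    }
  }
  int endl = -1, endc = DP_INF, endj = m;
  if (free_end) {
    int jmin = std::max(0, n + lo), jmax = std::min(m, n + hi);
    for (int j = jmin; j <= jmax; ++j)
      for (int l = 0; l < 3; ++l) {
        int p = at(l, n, j);
        if (p >= 0 && cost[p] < endc) { endc = cost[p]; endl = l; endj = j; }
      }
  } else {
    for (int l = 0; l < 3; ++l) {
      int p = at(l, n, m);
      if (p >= 0 && cost[p] < endc) { endc = cost[p]; endl = l; }
    }
  }
  if (endl < 0 || endc >= DP_INF) return out;
  // traceback
  std::string ops;
  int i = n, j = endj, l = endl;
  while (i > 0 || j > 0) {
    int p = at(l, i, j);
    if (p < 0 || from[p] == 255) return out;  // should not happen
    int prev = from[p];
    if (l == 0) { ops.push_back('M'); --i; --j; }
    else if (l == 1) { ops.push_back('D'); --j; }
    else { ops.push_back('I'); --i; }
    l = prev;
    if (i == 0 && j == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  // compact to CIGAR, count mismatches and gap bases
  std::string cg;
  int qp = 0, rp = start, nm = 0, gaps = 0;
  size_t a = 0;
  while (a < ops.size()) {
    size_t b = a;
    while (b < ops.size() && ops[b] == ops[a]) ++b;
    int run = (int)(b - a);
    cg += std::to_string(run);
    cg.push_back(ops[a]);
    if (ops[a] == 'M') {
      for (int t = 0; t < run; ++t, ++qp, ++rp)
        if (read[qp] != ref[rp] || base2bits(read[qp]) < 0) ++nm;
    } else if (ops[a] == 'D') { rp += run; gaps += run; }
    else { qp += run; gaps += run; }
    a = b;
  }
  if (nm > maxmm) return out;
  out.ok = true; out.nm = nm; out.gapbases = gaps; out.cost = endc;
  out.refspan = endj; out.cigar = cg;
  return out;
}

// reverse the run order of a CIGAR string (alignment read right-to-left)
static std::string reverse_cigar(const std::string& cg) {
  std::vector<std::string> toks;
  size_t i = 0;
  while (i < cg.size()) {
    size_t j = i;
    while (j < cg.size() && isdigit(cg[j])) ++j;
    toks.push_back(cg.substr(i, j - i + 1));
    i = j + 1;
  }
  std::string out;
  for (auto it = toks.rbegin(); it != toks.rend(); ++it) out += *it;
  return out;
}

struct AlnOut {
  bool mapped = false;
  int contig = -1, pos = -1;   // pos 0-based
  bool minus = false;
  int nm = 0, refspan = 0, gapbases = 0, cost = 0;
  std::string cigar;           // empty = all-M (ungapped)
};

// Candidate loci from seeds spread across the read.
static void gather_candidates(const std::string& s, int k,
                              const KmerIndex& idx,
                              std::vector<SeedHit>& cand) {
  int len = (int)s.size();
  std::vector<int> offsets;
  for (int o = 0; o + k <= len; o += k) offsets.push_back(o);
  if (!offsets.empty() && offsets.back() != len - k) offsets.push_back(len - k);
  for (int o : offsets) {
    uint64_t code;
    if (!encode_kmer(s, o, k, code)) continue;
    KmerIndex::const_iterator it = idx.find(code);
    if (it == idx.end()) continue;
    for (const SeedHit& h : it->second) {
      cand.push_back(SeedHit{ h.contig, h.pos - o });
      if (cand.size() > 4096) return;  // repeat blow-up guard
    }
  }
}

static bool better(const AlnOut& a, int nm, int contig, int pos, bool minus) {
  if (!a.mapped) return true;
  if (nm != a.nm) return nm < a.nm;
  if (contig != a.contig) return contig < a.contig;
  if (pos != a.pos) return pos < a.pos;
  return !minus && a.minus;  // plus strand preferred on exact tie
}

static AlnOut align_one(const std::string& fwd,
                        const std::vector<std::string>& refs,
                        const KmerIndex& idx, int k, int maxmm,
                        bool gapped, int max_indel) {
  AlnOut best;
  int len = (int)fwd.size();
  std::string rev = revcomp(fwd);
  const std::string* strands[2] = { &fwd, &rev };

  for (int st = 0; st < 2; ++st) {
    const std::string& s = *strands[st];
    std::vector<SeedHit> cand;
    gather_candidates(s, k, idx, cand);
    std::sort(cand.begin(), cand.end(), [](const SeedHit& a, const SeedHit& b) {
      return a.contig != b.contig ? a.contig < b.contig : a.pos < b.pos;
    });
    cand.erase(std::unique(cand.begin(), cand.end(),
                           [](const SeedHit& a, const SeedHit& b) {
                             return a.contig == b.contig && a.pos == b.pos;
                           }),
               cand.end());
    for (const SeedHit& c : cand) {
      if (c.pos < 0 || c.pos + len > (int)refs[c.contig].size()) continue;
      int cap = best.mapped ? std::min(maxmm, best.nm) : maxmm;
      int nm = count_mismatches(s, refs[c.contig], c.pos, cap);
      if (nm <= maxmm && better(best, nm, c.contig, c.pos, st == 1)) {
        best.mapped = true; best.contig = c.contig; best.pos = c.pos;
        best.minus = (st == 1); best.nm = nm; best.refspan = len;
        best.gapbases = 0; best.cost = nm * MM_COST; best.cigar.clear();
      }
    }
  }
  if (best.mapped || !gapped || len < 2 * k) return best;

  // gapped rescue: anchor an exact k-mer seed at one read end and run a
  // banded affine-gap semi-global alignment towards the other (free)
  // end. Trying both end seeds covers an indel anywhere in the read, and
  // the DP recovers clustered edits (several SNPs/indels per read). The
  // band accommodates two same-sign maximum-size indels in one read.
  // Candidates are compared by alignment cost, then (contig, position,
  // strand).
  int bw = 2 * max_indel;
  auto consider = [&](int contig, int pos0, bool minus, const DPResult& r) {
    if (!r.ok || r.gapbases == 0) return;
    bool take = !best.mapped || r.cost < best.cost ||
      (r.cost == best.cost &&
       (contig < best.contig ||
        (contig == best.contig &&
         (pos0 < best.pos || (pos0 == best.pos && !minus && best.minus)))));
    if (take) {
      best.mapped = true; best.contig = contig; best.pos = pos0;
      best.minus = minus; best.nm = r.nm; best.refspan = r.refspan;
      best.gapbases = r.gapbases; best.cost = r.cost;
      best.cigar = r.cigar;
    }
  };
  for (int st = 0; st < 2; ++st) {
    const std::string& s = *strands[st];
    bool minus = (st == 1);
    int e = len - k;
    uint64_t c1, c2;
    // start-anchored, free right end
    if (encode_kmer(s, 0, k, c1)) {
      KmerIndex::const_iterator i1 = idx.find(c1);
      if (i1 != idx.end()) {
        int tried = 0;
        for (const SeedHit& h1 : i1->second) {
          if (++tried > 16) break;
          const std::string& ref = refs[h1.contig];
          int m = std::min(len + bw, (int)ref.size() - h1.pos);
          if (m < len - bw) continue;
          DPResult r = banded_align(s, ref, h1.pos, m, -bw, bw, maxmm,
                                    true);
          consider(h1.contig, h1.pos, minus, r);
        }
      }
    }
    // end-anchored, free left end (run on reversed strings)
    if (encode_kmer(s, e, k, c2)) {
      KmerIndex::const_iterator i2 = idx.find(c2);
      if (i2 != idx.end()) {
        int tried = 0;
        for (const SeedHit& h2 : i2->second) {
          if (++tried > 16) break;
          const std::string& ref = refs[h2.contig];
          int wend = h2.pos + k - 1;           // ref index of read end
          int wstart = std::max(0, wend - (len + bw) + 1);
          int m = wend - wstart + 1;
          if (m < len - bw) continue;
          std::string revread(s.rbegin(), s.rend());
          std::string win = ref.substr(wstart, m);
          std::reverse(win.begin(), win.end());
          DPResult r = banded_align(revread, win, 0, m, -bw, bw, maxmm,
                                    true);
          if (r.ok && r.gapbases > 0) {
            r.cigar = reverse_cigar(r.cigar);
            consider(h2.contig, wend - r.refspan + 1, minus, r);
          }
        }
      }
    }
  }
  return best;
}

// prebuilt seed index shareable across align calls on one genome
struct GenomeIndex {
  std::vector<std::string> refs;
  KmerIndex idx;
  int k;
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector ref_seqs, int k) {
  GenomeIndex* gi = new GenomeIndex();
  gi->k = k;
  gi->refs.resize(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i)
    gi->refs[i] = as<std::string>(ref_seqs[i]);
  index_genome(gi->refs, k, gi->idx);
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(SEXP index, CharacterVector read_ids,
               CharacterVector read_seqs, CharacterVector read_quals,
               double max_mismatch_frac, bool gapped, int max_indel) {
  XPtr<GenomeIndex> gi(index);
  const std::vector<std::string>& refs = gi->refs;
  const KmerIndex& idx = gi->idx;
  int k = gi->k;

  int n = read_seqs.size();
  IntegerVector contig(n), pos(n), nm(n), alen(n), score(n);
  LogicalVector mapped(n);
  CharacterVector strand(n), cigar(n), oseq(n), oqual(n);
  bool have_qual = read_quals.size() == n;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(read_seqs[i]);
    std::string q = have_qual ? as<std::string>(read_quals[i]) : std::string();
    int len = (int)s.size();
    int maxmm = (int)std::floor(max_mismatch_frac * len);
    AlnOut a;
    if (len >= k) a = align_one(s, refs, idx, k, maxmm, gapped, max_indel);
    if (!a.mapped) {
      mapped[i] = false;
      contig[i] = NA_INTEGER; pos[i] = NA_INTEGER; nm[i] = NA_INTEGER;
      alen[i] = NA_INTEGER; score[i] = NA_INTEGER;
      strand[i] = NA_STRING; cigar[i] = NA_STRING;
      oseq[i] = s; oqual[i] = q;
      continue;
    }
    mapped[i] = true;
    contig[i] = a.contig + 1;
    pos[i] = a.pos + 1;
    strand[i] = a.minus ? "-" : "+";
    std::string os = a.minus ? revcomp(s) : s;
    std::string oq = q;
    if (a.minus) std::reverse(oq.begin(), oq.end());
    oseq[i] = os; oqual[i] = oq;
    nm[i] = a.nm;
    alen[i] = a.refspan;
    score[i] = len - a.nm - a.gapbases;
    cigar[i] = a.cigar.empty() ? std::to_string(len) + "M" : a.cigar;
  }
  return List::create(
    _["read_id"] = read_ids, _["mapped"] = mapped, _["contig_idx"] = contig,
    _["pos"] = pos, _["strand"] = strand, _["cigar"] = cigar,
    _["mismatches"] = nm, _["aligned_length"] = alen, _["score"] = score,
    _["seq"] = oseq, _["qual"] = oqual);
}

// ---------------------------------------------------------------- pileup

struct IndelKey {
  int contig, pos;            // pos 1-based anchor
  std::string ref, alt;
  bool operator<(const IndelKey& o) const {
    if (contig != o.contig) return contig < o.contig;
    if (pos != o.pos) return pos < o.pos;
    if (ref != o.ref) return ref < o.ref;
    return alt < o.alt;
  }
};

// left-align an anchored indel against its reference sequence, so all
// reads supporting one event aggregate under a single key regardless of
// where their alignments placed it within a repeat run
static void left_align_indel(const std::string& ref, int& pos1,
                             std::string& refa, std::string& alta) {
  // pos1 is 1-based; refa/alta carry the anchor base
  while (pos1 > 1) {
    size_t rl = refa.size(), al = alta.size();
    if (rl == 0 || al == 0) break;
    if (refa[rl - 1] != alta[al - 1]) break;
    if (rl == 1 && al == 1) break;
    char prev = ref[pos1 - 2];
    refa = std::string(1, prev) + refa.substr(0, rl - 1);
    alta = std::string(1, prev) + alta.substr(0, al - 1);
    --pos1;
  }
}

// [[Rcpp::export(name = ".cpp_pileup")]]
List cpp_pileup(CharacterVector ref_seqs, IntegerVector contig_idx,
                IntegerVector pos, CharacterVector cigar, CharacterVector seq,
                CharacterVector qual, int default_qual, int indel_flank) {
  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  std::vector<std::vector<std::array<int, 4> > > cnt(nref);
  std::vector<std::vector<std::array<double, 4> > > qsum(nref);
  // wspan[c][p]: after prefix-summing, the number of alignments spanning
  // [p - indel_flank, p + indel_flank] -- the denominator for indel
  // zygosity (only reads with enough flank could have reported the indel)
  // del_cov[c][p]: reads whose alignment deletes reference base p; they
  // count toward column depth (the pileup's '*' observations) so that
  // misaligned tails inside a homozygous deletion cannot look unanimous
  std::vector<std::vector<int> > del_cov(nref);
  // alignment spans per contig, for exact windowed indel depth
  std::vector<std::vector<std::pair<long, long> > > spans(nref);
  for (int i = 0; i < nref; ++i) {
    refs[i] = as<std::string>(ref_seqs[i]);
    cnt[i].assign(refs[i].size(), std::array<int, 4>{ {0, 0, 0, 0} });
    qsum[i].assign(refs[i].size(), std::array<double, 4>{ {0, 0, 0, 0} });
    del_cov[i].assign(refs[i].size(), 0);
  }
  std::map<IndelKey, std::pair<int, double> > indels;

  int n = contig_idx.size();
  for (int i = 0; i < n; ++i) {
    if (IntegerVector::is_na(contig_idx[i]) || IntegerVector::is_na(pos[i]))
      continue;
    int ci = contig_idx[i] - 1;
    if (ci < 0 || ci >= nref) stop("pileup: contig index out of range");
    const std::string& ref = refs[ci];
    std::string s = as<std::string>(seq[i]);
    std::string q = as<std::string>(qual[i]);
    std::string cg = as<std::string>(cigar[i]);
    size_t rp = (size_t)(pos[i] - 1);   // ref cursor, 0-based
    size_t qp = 0;                      // read cursor
    double lastq = default_qual;
    size_t ci2 = 0;
    // indel events of this read, flushed only if the read spans the
    // event by >= indel_flank on both sides (matching the wspan
    // denominator, so indel zygosity is support/spanning-reads)
    struct Pending { IndelKey key; double q; long a0, a1; };
    std::vector<Pending> pending;
    while (ci2 < cg.size()) {
      long num = 0;
      while (ci2 < cg.size() && isdigit(cg[ci2])) num = num * 10 + (cg[ci2++] - '0');
      if (ci2 >= cg.size()) stop("pileup: malformed CIGAR '%s'", cg.c_str());
      char op = cg[ci2++];
      switch (op) {
      case 'M': case '=': case 'X':
        for (long j = 0; j < num; ++j, ++rp, ++qp) {
          if (rp >= ref.size() || qp >= s.size())
            stop("pileup: alignment overruns contig at position %d", (int)rp + 1);
          int b = base2bits(s[qp]);
          double bq = qp < q.size() ? (double)(q[qp] - 33) : (double)default_qual;
          lastq = bq;
          if (b >= 0) { cnt[ci][rp][b]++; qsum[ci][rp][b] += bq; }
        }
        break;
      case 'I': {
        if (rp == 0 || qp + num > s.size()) { qp += num; break; }
        size_t anchor = rp - 1;
        std::string refa(1, ref[anchor]);
        std::string alta = refa + s.substr(qp, num);
        double bq = qp < q.size() ? (double)(q[qp] - 33) : (double)default_qual;
        bool clean = true;
        for (char c : alta) if (base2bits(c) < 0) clean = false;
        if (clean) {
          int p1 = (int)anchor + 1;
          left_align_indel(ref, p1, refa, alta);
          pending.push_back(Pending{ IndelKey{ ci, p1, refa, alta }, bq,
                                     (long)anchor, (long)anchor });
        }
        qp += num;
        break;
      }
      case 'D': case 'N': {
        if (op == 'D')
          for (long j = 0; j < num && rp + j < ref.size(); ++j)
            del_cov[ci][rp + j]++;
        if (op == 'D' && rp > 0 && rp + num <= ref.size()) {
          size_t anchor = rp - 1;
          std::string refa = ref.substr(anchor, num + 1);
          std::string alta(1, ref[anchor]);
          bool clean = true;
          for (char c : refa) if (base2bits(c) < 0) clean = false;
          if (clean) {
            int p1 = (int)anchor + 1;
            left_align_indel(ref, p1, refa, alta);
            pending.push_back(Pending{ IndelKey{ ci, p1, refa, alta },
                                       lastq, (long)anchor,
                                       (long)(anchor + num) });
          }
        }
        rp += num;
        break;
      }
      case 'S': qp += num; break;
      case 'H': case 'P': break;
      default: stop("pileup: unsupported CIGAR op '%c'", op);
      }
    }
    // record the alignment span for windowed indel depth
    long s0 = pos[i] - 1, e0 = (long)rp - 1;
    spans[ci].push_back(std::make_pair(s0, e0));
    for (const Pending& pd : pending) {
      if (pd.a0 - indel_flank >= s0 && pd.a1 + indel_flank <= e0) {
        auto& e2 = indels[pd.key];
        e2.first++; e2.second += pd.q;
      }
    }
  }
  // exact count of alignments spanning [A, B] per indel candidate:
  // sweep candidates by A while inserting alignment ends into a Fenwick
  // tree for spans with start <= A, then count ends >= B
  std::map<IndelKey, int> indel_depth;
  for (int ci = 0; ci < nref; ++ci) {
    std::vector<const IndelKey*> cands;
    for (const auto& kv : indels)
      if (kv.first.contig == ci) cands.push_back(&kv.first);
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end(),
              [&](const IndelKey* x, const IndelKey* y) {
                return x->pos < y->pos;
              });
    std::sort(spans[ci].begin(), spans[ci].end());
    long nlen = (long)refs[ci].size() + 2;
    std::vector<int> fen(nlen + 1, 0);
    auto fen_add = [&](long p) {
      for (long x = p + 1; x <= nlen; x += x & (-x)) fen[x]++;
    };
    auto fen_le = [&](long p) {   // count of inserted ends <= p
      int s = 0;
      for (long x = p + 1; x > 0; x -= x & (-x)) s += fen[x];
      return s;
    };
    size_t sp = 0; int inserted = 0;
    for (const IndelKey* kk : cands) {
      long A = (long)kk->pos - 1 - indel_flank;
      long B = (long)kk->pos - 1 + (long)kk->ref.size() - 1 + indel_flank;
      while (sp < spans[ci].size() && spans[ci][sp].first <= A) {
        long e2 = spans[ci][sp].second;
        if (e2 < 0) e2 = 0;
        if (e2 > nlen - 1) e2 = nlen - 1;
        fen_add(e2); ++inserted; ++sp;
      }
      int d = inserted;
      if (B >= 1) d -= fen_le(B - 1);
      indel_depth[*kk] = d;
    }
  }

  // emit candidates sorted by (contig, pos, ref, alt)
  std::vector<int> o_contig, o_pos, o_depth, o_support;
  std::vector<std::string> o_ref, o_alt, o_kind;
  std::vector<double> o_zyg, o_qual;
  for (int ci = 0; ci < nref; ++ci) {
    const std::string& ref = refs[ci];
    for (size_t p = 0; p < ref.size(); ++p) {
      int rb = base2bits(ref[p]);
      int depth = cnt[ci][p][0] + cnt[ci][p][1] + cnt[ci][p][2] +
                  cnt[ci][p][3] + del_cov[ci][p];
      if (depth == 0) continue;
      for (int b = 0; b < 4; ++b) {
        if (b == rb || cnt[ci][p][b] == 0) continue;
        o_contig.push_back(ci + 1);
        o_pos.push_back((int)p + 1);
        o_ref.push_back(std::string(1, rb >= 0 ? bits2base(rb) : ref[p]));
        o_alt.push_back(std::string(1, bits2base(b)));
        o_kind.push_back("SNP");
        o_depth.push_back(depth);
        o_support.push_back(cnt[ci][p][b]);
        o_zyg.push_back((double)cnt[ci][p][b] / depth);
        o_qual.push_back(qsum[ci][p][b] / cnt[ci][p][b]);
      }
    }
  }
  for (const auto& kv : indels) {
    const IndelKey& key = kv.first;
    int depth = indel_depth[key];
    if (depth < kv.second.first) depth = kv.second.first;
    o_contig.push_back(key.contig + 1);
    o_pos.push_back(key.pos);
    o_ref.push_back(key.ref);
    o_alt.push_back(key.alt);
    o_kind.push_back(key.ref.size() > key.alt.size() ? "DEL" : "INS");
    o_depth.push_back(depth);
    o_support.push_back(kv.second.first);
    o_zyg.push_back((double)kv.second.first / depth);
    o_qual.push_back(kv.second.second / kv.second.first);
  }
  return List::create(
    _["contig_idx"] = wrap(o_contig), _["pos"] = wrap(o_pos),
    _["ref"] = wrap(o_ref), _["alt"] = wrap(o_alt), _["kind"] = wrap(o_kind),
    _["depth"] = wrap(o_depth), _["alt_support"] = wrap(o_support),
    _["zygosity"] = wrap(o_zyg), _["quality"] = wrap(o_qual));
}

// ------------------------------------------------------------- assembler

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}
static inline uint64_t canon(uint64_t code, int k) {
  uint64_t rc = rc_code(code, k);
  return code < rc ? code : rc;
}
static std::string decode(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bits2base(code & 3); code >>= 2; }
  return s;
}

// [[Rcpp::export(name = ".cpp_assemble")]]
CharacterVector cpp_assemble(CharacterVector reads, int k, int min_len) {
  if (k < 5 || k > 31) stop("assembler k must be in [5, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_set<uint64_t> kmers;
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    uint64_t code = 0; int valid = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) kmers.insert(canon(code, k));
    }
  }
  if (kmers.empty()) return CharacterVector(0);

  std::vector<uint64_t> sorted(kmers.begin(), kmers.end());
  std::sort(sorted.begin(), sorted.end());
  std::unordered_set<uint64_t> visited;

  auto succs = [&](uint64_t code, std::vector<uint64_t>& out) {
    out.clear();
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nx = ((code << 2) | b) & mask;
      if (kmers.count(canon(nx, k))) out.push_back(nx);
    }
  };
  auto preds = [&](uint64_t code, std::vector<uint64_t>& out) {
    out.clear();
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t pv = (b << (2 * (k - 1))) | (code >> 2);
      if (kmers.count(canon(pv, k))) out.push_back(pv);
    }
  };

  std::vector<std::string> unitigs;
  std::vector<uint64_t> nb, nb2;
  for (uint64_t start : sorted) {
    if (visited.count(start)) continue;
    visited.insert(start);
    std::string path = decode(start, k);
    // extend right
    uint64_t cur = start;
    for (;;) {
      succs(cur, nb);
      if (nb.size() != 1) break;
      uint64_t nx = nb[0];
      uint64_t cx = canon(nx, k);
      if (visited.count(cx)) break;
      preds(nx, nb2);
      if (nb2.size() != 1) break;
      path.push_back(bits2base(nx & 3));
      visited.insert(cx);
      cur = nx;
    }
    // extend left
    cur = start;
    for (;;) {
      preds(cur, nb);
      if (nb.size() != 1) break;
      uint64_t pv = nb[0];
      uint64_t cx = canon(pv, k);
      if (visited.count(cx)) break;
      succs(pv, nb2);
      if (nb2.size() != 1) break;
      path.insert(path.begin(), bits2base((pv >> (2 * (k - 1))) & 3));
      visited.insert(cx);
      cur = pv;
    }
    if ((int)path.size() >= min_len) {
      std::string rc = revcomp(path);
      unitigs.push_back(path < rc ? path : rc);
    }
  }
  std::sort(unitigs.begin(), unitigs.end(), [](const std::string& a,
                                               const std::string& b) {
    return a.size() != b.size() ? a.size() > b.size() : a < b;
  });
  return wrap(unitigs);
}
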