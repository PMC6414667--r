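// Seed-and-extend local nucleotide aligner.
//
// Exact k-mer seeds against an indexed reference set, followed by full
// affine-gap Smith-Waterman restricted to a reference window around the
// seeded diagonal(s).  Scoring convention: match/mismatch from parameters,
// a gap of length L costs gap_open + L * gap_extend (the first gap column
// pays both the opening and one extension), matching the convention of
// classical local-alignment implementations so that an exhaustive DP over
// the full matrix is a valid oracle.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > map; // kmer -> (ref, pos)
};

static void index_refs(const std::vector<std::string>& refs, int k, SeedIndex& idx) {
  idx.k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < k) continue;
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        idx.map[code].push_back(std::make_pair((int)r, (int)(i - k + 1)));
      }
    }
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
    case 'A': case 'a': out[i] = 'T'; break;
    case 'C': case 'c': out[i] = 'G'; break;
    case 'G': case 'g': out[i] = 'C'; break;
    case 'T': case 't': out[i] = 'A'; break;
    default: out[i] = 'N';
    }
  }
  return out;
}

struct AlnResult {
  int score;          // best local score; <= 0 means no alignment
  int matches;        // identical columns
  int cols;           // alignment columns (matches + mismatches + gaps)
  int ref_start, ref_end;   // 0-based half-open, window coordinates
  int read_start, read_end; // 0-based half-open on the oriented read
};

// Full affine-gap Smith-Waterman of read (rows) vs ref window (cols),
// with traceback.  Matrices are flat vectors reused across calls.
class SWAligner {
public:
  SWAligner(int match, int mismatch, int gap_open, int gap_extend)
    : ma(match), mi(mismatch), go(gap_open), ge(gap_extend) {}

  AlnResult align(const std::string& read, const std::string& ref) {
    const int m = (int)read.size(), n = (int)ref.size();
    const int W = n + 1;
    const int NEG = -1000000000;
    H.assign((size_t)(m + 1) * W, 0);
    E.assign((size_t)(m + 1) * W, NEG);
    F.assign((size_t)(m + 1) * W, NEG);
    rcode.resize(n);
    for (int j = 0; j < n; ++j) rcode[j] = (signed char)base_code(ref[j]);
    int best = 0, bi = 0, bj = 0;
    const int goe = go + ge;
    for (int i = 1; i <= m; ++i) {
      const int rb = base_code(read[i - 1]);
      const int* Hp = &H[(size_t)(i - 1) * W];
      const int* Fp = &F[(size_t)(i - 1) * W];
      int* Hc = &H[(size_t)i * W];
      int* Ec = &E[(size_t)i * W];
      int* Fc = &F[(size_t)i * W];
      for (int j = 1; j <= n; ++j) {
        const int sub = (rb >= 0 && rcode[j - 1] == rb) ? ma : mi;
        const int e = std::max(Hc[j - 1] - goe, Ec[j - 1] - ge);
        const int f = std::max(Hp[j] - goe, Fp[j] - ge);
        int h = std::max(std::max(Hp[j - 1] + sub, std::max(e, f)), 0);
        Ec[j] = e; Fc[j] = f; Hc[j] = h;
        if (h >= best && h > 0) { best = h; bi = i; bj = j; }
      }
    }
    AlnResult res;
    res.score = best;
    res.matches = 0; res.cols = 0;
    res.ref_start = res.ref_end = 0; res.read_start = res.read_end = 0;
    if (best <= 0) return res;
    // traceback
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (gap in read), 2 = F (gap in ref)
    while (true) {
      if (state == 0) {
        int h = H[(size_t)i * W + j];
        if (h == 0) break;
        // prefer the diagonal on ties so co-optimal paths favour
        // substitution columns over gap columns
        const int sub = (base_code(read[i - 1]) >= 0 &&
                         read[i - 1] == ref[j - 1]) ? ma : mi;
        if (i >= 1 && j >= 1 && h == H[(size_t)(i - 1) * W + j - 1] + sub) {
          res.cols++;
          if (sub == ma) res.matches++;
          --i; --j;
          continue;
        }
        if (h == E[(size_t)i * W + j]) { state = 1; continue; }
        if (h == F[(size_t)i * W + j]) { state = 2; continue; }
        res.cols++;
        if (sub == ma) res.matches++;
        --i; --j;
      } else if (state == 1) {
        // E[i][j] came from E[i][j-1]-ge (stay) or H[i][j-1]-go-ge (close)
        int e = E[(size_t)i * W + j];
        res.cols++;
        bool stay = (j >= 2) && (e == E[(size_t)i * W + j - 1] - ge);
        --j;
        if (!stay) state = 0;
      } else {
        int f = F[(size_t)i * W + j];
        res.cols++;
        bool stay = (i >= 2) && (f == F[(size_t)(i - 1) * W + j] - ge);
        --i;
        if (!stay) state = 0;
      }
    }
    res.read_start = i; res.read_end = bi;
    res.ref_start = j;  res.ref_end = bj;
    return res;
  }

private:
  int ma, mi, go, ge;
  std::vector<int> H, E, F;
  std::vector<signed char> rcode;
};

struct Candidate {
  int ref;
  int win_start;
  std::string window; // unused placeholder
  int win_len;
};

struct BestHit {
  bool found = false;
  int ref = -1;
  double score = -1;
  int matches = 0, cols = 0;
  int ref_start = 0, ref_end = 0;
  int read_start = 0, read_end = 0;
  char strand = '+';
};

// Align one oriented read against the index; fill per-ref best into `per_ref`.
static void align_oriented(const std::string& read, const SeedIndex& idx,
                           const std::vector<std::string>& refs,
                           SWAligner& sw, char strand, int band, int pad,
                           std::vector<BestHit>& per_ref) {
  const int k = idx.k;
  const int m = (int)read.size();
  if (m < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  // collect (ref, diag) seed hits
  std::vector<std::pair<int,int> > seeds; // (ref, diag)
  uint64_t code = 0; int valid = 0;
  for (int i = 0; i < m; ++i) {
    int b = base_code(read[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      auto it = idx.map.find(code);
      if (it == idx.map.end()) continue;
      const int qpos = i - k + 1;
      for (size_t h = 0; h < it->second.size(); ++h) {
        seeds.push_back(std::make_pair(it->second[h].first,
                                       it->second[h].second - qpos));
      }
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end());
  seeds.erase(std::unique(seeds.begin(), seeds.end()), seeds.end());
  // group diagonals per ref; close a group on a diagonal jump > band or span > 100
  size_t s = 0;
  while (s < seeds.size()) {
    int ref = seeds[s].first;
    size_t e = s;
    int d0 = seeds[s].second;
    while (e + 1 < seeds.size() && seeds[e + 1].first == ref &&
           seeds[e + 1].second - seeds[e].second <= band &&
           seeds[e + 1].second - d0 <= 100) ++e;
    int dmin = seeds[s].second, dmax = seeds[e].second;
    const std::string& R = refs[ref];
    int ws = std::max(0, dmin - pad);
    int we = std::min((int)R.size(), dmax + m + pad);
    if (we > ws) {
      AlnResult a = sw.align(read, R.substr(ws, we - ws));
      if (a.score > 0) {
        BestHit& bh = per_ref[ref];
        if (!bh.found || a.score > bh.score) {
          bh.found = true; bh.ref = ref; bh.score = a.score;
          bh.matches = a.matches; bh.cols = a.cols;
          bh.ref_start = ws + a.ref_start; bh.ref_end = ws + a.ref_end;
          bh.read_start = a.read_start; bh.read_end = a.read_end;
          bh.strand = strand;
        }
      }
    }
    s = e + 1;
  }
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector read_ids,
                     CharacterVector refs, CharacterVector ref_ids,
                     int k, double min_identity, int min_len,
                     bool best_hit_only,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band, int pad) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);
  SeedIndex idx;
  index_refs(R, k, idx);
  SWAligner sw(match, mismatch, gap_open, gap_extend);

  std::vector<std::string> out_read, out_ref;
  std::vector<int> out_rs, out_re, out_qs, out_qe, out_len, out_matches;
  std::vector<double> out_pid, out_score;
  std::vector<std::string> out_strand;
  int n_short = 0;

  for (int q = 0; q < reads.size(); ++q) {
    std::string rd = as<std::string>(reads[q]);
    if ((int)rd.size() < k) { ++n_short; continue; }
    std::vector<BestHit> per_ref(nref);
    align_oriented(rd, idx, R, sw, '+', band, pad, per_ref);
    std::string rc = revcomp(rd);
    std::vector<BestHit> per_ref_rc(nref);
    align_oriented(rc, idx, R, sw, '-', band, pad, per_ref_rc);
    for (int r = 0; r < nref; ++r) {
      if (per_ref_rc[r].found &&
          (!per_ref[r].found || per_ref_rc[r].score > per_ref[r].score)) {
        per_ref[r] = per_ref_rc[r];
      }
    }
    // filter per-ref hits
    std::vector<int> keep;
    for (int r = 0; r < nref; ++r) {
      if (!per_ref[r].found) continue;
      const BestHit& b = per_ref[r];
      double pid = 100.0 * b.matches / b.cols;
      if (b.cols > min_len && pid >= min_identity) keep.push_back(r);
    }
    if (keep.empty()) continue;
    if (best_hit_only) {
      // highest score; ties by lexicographically smallest ref_id
      int bestr = keep[0];
      for (size_t ii = 1; ii < keep.size(); ++ii) {
        int r = keep[ii];
        if (per_ref[r].score > per_ref[bestr].score ||
            (per_ref[r].score == per_ref[bestr].score &&
             as<std::string>(ref_ids[r]) < as<std::string>(ref_ids[bestr])))
          bestr = r;
      }
      keep.assign(1, bestr);
    }
    for (size_t ii = 0; ii < keep.size(); ++ii) {
      const BestHit& b = per_ref[keep[ii]];
      out_read.push_back(as<std::string>(read_ids[q]));
      out_ref.push_back(as<std::string>(ref_ids[keep[ii]]));
      out_rs.push_back(b.ref_start);
      out_re.push_back(b.ref_end);
      out_qs.push_back(b.read_start);
      out_qe.push_back(b.read_end);
      out_len.push_back(b.cols);
      out_matches.push_back(b.matches);
      out_pid.push_back(100.0 * b.matches / b.cols);
      out_score.push_back(b.score);
      out_strand.push_back(std::string(1, b.strand));
    }
  }

  DataFrame hits = DataFrame::create(
    _["read_id"] = wrap(out_read),
    _["ref_id"] = wrap(out_ref),
    _["ref_start"] = wrap(out_rs),
    _["ref_end"] = wrap(out_re),
    _["read_start"] = wrap(out_qs),
    _["read_end"] = wrap(out_qe),
    _["aligned_length"] = wrap(out_len),
    _["matches"] = wrap(out_matches),
    _["percent_identity"] = wrap(out_pid),
    _["score"] = wrap(out_score),
    _["strand"] = wrap(out_strand),
    _["stringsAsFactors"] = false);
  return List::create(_["hits"] = hits, _["n_too_short"] = n_short);
}

// Exhaustive affine-gap local DP on one pair (no seeding, no window):
// used only as an in-package convenience for small instances.
// [[Rcpp::export]]
List cpp_sw_full(std::string read, std::string ref,
                 int match, int mismatch, int gap_open, int gap_extend) {
  SWAligner sw(match, mismatch, gap_open, gap_extend);
  AlnResult a = sw.align(read, ref);
  return List::create(_["score"] = a.score, _["matches"] = a.matches,
                      _["cols"] = a.cols,
                      _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
                      _["read_start"] = a.read_start, _["read_end"] = a.read_end);
}
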