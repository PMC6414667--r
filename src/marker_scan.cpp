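// Six-frame translation and ungapped position-specific scoring matrix
// (PSSM) scan for marker-gene read classification, with batch
// nearest-reference assignment at the profile placement columns.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Codon table indexed by 16*b1 + 4*b2 + b3 with A=0, C=1, G=2, T=3.
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMI"  // AAA..ATT
  "QHQHPPPPRRRRLLLL"  // CAA..CTT
  "EDEDAAAAGGGGVVVV"  // GAA..GTT
  "*Y*YSSSS*CWCLFLF"; // TAA..TTT

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Amino-acid row order of the PSSM: alphabetical one-letter codes.
static inline int aa_index(char a) {
  static const std::string order = "ACDEFGHIKLMNPQRSTVWY";
  size_t p = order.find(a);
  return (p == std::string::npos) ? -1 : (int)p;
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

static std::string translate_frame(const std::string& s, int off) {
  std::string aa;
  aa.reserve(s.size() / 3 + 1);
  for (size_t i = off; i + 2 < s.size(); i += 3) {
    int b1 = base_code(s[i]), b2 = base_code(s[i + 1]), b3 = base_code(s[i + 2]);
    if (b1 < 0 || b2 < 0 || b3 < 0) { aa.push_back('X'); continue; }
    aa.push_back(CODON_TABLE[16 * b1 + 4 * b2 + b3]);
  }
  return aa;
}

// [[Rcpp::export]]
CharacterVector cpp_translate_six(std::string seq) {
  CharacterVector out(6);
  std::string rc = revcomp(seq);
  for (int f = 0; f < 3; ++f) out[f] = translate_frame(seq, f);
  for (int f = 0; f < 3; ++f) out[3 + f] = translate_frame(rc, f);
  return out;
}

struct ScanBest {
  double score = R_NegInf;
  int frame = NA_INTEGER;   // 1..6 (4..6 are reverse-complement frames)
  int offset = NA_INTEGER;  // 0-based profile column of segment start
  std::string segment;
};

// Best ungapped placement of every stop-free segment (>= min_seg aa) of all
// six frames onto the profile columns.  `P` is the profile row-major
// (20 rows of C doubles); `zero` is an all-zero row used for unknown
// residues (X), which contribute 0.
static ScanBest scan_read(const std::string& read, const double* P,
                          const double* zero, int C, int min_seg) {
  ScanBest best;
  std::string rc = revcomp(read);
  std::vector<double> S;
  for (int f = 0; f < 6; ++f) {
    const std::string aa = translate_frame(f < 3 ? read : rc, f % 3);
    size_t start = 0;
    for (size_t i = 0; i <= aa.size(); ++i) {
      if (i == aa.size() || aa[i] == '*') {
        const int len = (int)(i - start);
        if (len >= min_seg && len <= C) {
          const int n_off = C - len + 1;
          S.assign(n_off, 0.0);
          // accumulate per residue row over all offsets (contiguous in
          // the profile row, so the loop vectorizes)
          for (int p = 0; p < len; ++p) {
            int idx = aa_index(aa[start + p]);
            const double* row = ((idx >= 0) ? P + (size_t)idx * C : zero) + p;
            double* Sp = S.data();
            for (int off = 0; off < n_off; ++off) Sp[off] += row[off];
          }
          for (int off = 0; off < n_off; ++off) {
            if (S[off] > best.score) {
              best.score = S[off]; best.frame = f + 1; best.offset = off;
              best.segment = aa.substr(start, len);
            }
          }
        }
        start = i + 1;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_marker_scan(CharacterVector reads, NumericMatrix pssm, int min_seg) {
  const int n = reads.size();
  const int C = pssm.ncol(), A = pssm.nrow();
  std::vector<double> P((size_t)A * C);
  for (int a = 0; a < A; ++a)
    for (int c = 0; c < C; ++c) P[(size_t)a * C + c] = pssm(a, c);
  std::vector<double> zero(C, 0.0);
  NumericVector score(n);
  IntegerVector frame(n), offset(n), seg_len(n);
  CharacterVector segment(n);
  for (int i = 0; i < n; ++i) {
    ScanBest b = scan_read(as<std::string>(reads[i]), P.data(), zero.data(),
                           C, min_seg);
    score[i] = b.score;
    frame[i] = b.frame;
    offset[i] = b.offset;
    seg_len[i] = b.segment.empty() ? NA_INTEGER : (int)b.segment.size();
    segment[i] = b.segment;
  }
  return List::create(_["score"] = score, _["frame"] = frame,
                      _["offset"] = offset, _["seg_len"] = seg_len,
                      _["segment"] = segment);
}

// Batch nearest-reference assignment.  `refs` are reference proteins
// restricted to the profile columns (all the same length C, '-' for gaps);
// references must be supplied sorted by id so that the first maximum
// realizes the lexicographic tie-break.
// [[Rcpp::export]]
List cpp_assign_nearest(CharacterVector segments, IntegerVector offsets,
                        CharacterVector refs) {
  const int n = segments.size();
  const int R = refs.size();
  std::vector<std::string> rf(R);
  for (int r = 0; r < R; ++r) rf[r] = as<std::string>(refs[r]);
  IntegerVector best_ref(n);
  NumericVector identity(n);
  for (int i = 0; i < n; ++i) {
    std::string seg = as<std::string>(segments[i]);
    int off = offsets[i];
    if (seg.empty() || off == NA_INTEGER) {
      best_ref[i] = NA_INTEGER; identity[i] = NA_REAL; continue;
    }
    const int m = (int)seg.size();
    int br = -1; double bid = -1; int bcov = -1;
    for (int r = 0; r < R; ++r) {
      int matches = 0, nongap = 0;
      for (int p = 0; p < m; ++p) {
        char rc = rf[r][off + p];
        if (rc != '-') ++nongap;
        if (rc == seg[p]) ++matches;
      }
      double id = (double)matches / m;
      if (id > bid || (id == bid && nongap > bcov)) {
        bid = id; bcov = nongap; br = r;
      }
    }
    best_ref[i] = br + 1;
    identity[i] = 100.0 * bid;
  }
  return List::create(_["ref"] = best_ref, _["identity"] = identity);
}
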