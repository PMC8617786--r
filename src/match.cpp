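#include <Rcpp.h>
using namespace Rcpp;

// 4-bit encoding of IUPAC nucleotide codes (A=1, C=2, G=4, T=8).
static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': return 8;
    case 'R': return 1 | 4;
    case 'Y': return 2 | 8;
    case 'S': return 2 | 4;
    case 'W': return 1 | 8;
    case 'K': return 4 | 8;
    case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;
    case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;
    case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;
  }
}

// A window base matches a primer base iff the window base is a concrete
// nucleotide contained in the primer base's IUPAC expansion. Ambiguity codes
// in the window (including N) never match: the expansion is over {A,C,G,T}.
static inline bool base_match(char w, char p) {
  const int bw = iupac_bits(w);
  if (bw != 1 && bw != 2 && bw != 4 && bw != 8) return false;
  return (bw & iupac_bits(p)) != 0;
}

// [[Rcpp::export]]
int cpp_mismatch_count(const std::string& primer, const std::string& window) {
  if (primer.size() != window.size())
    stop("primer and window must have equal length (%d vs %d)",
         (int)primer.size(), (int)window.size());
  int mm = 0;
  for (size_t i = 0; i < primer.size(); ++i)
    if (!base_match(window[i], primer[i])) ++mm;
  return mm;
}

// Slide `pattern` (IUPAC) along the plus strand of `subject`. A hit requires
// total mismatches <= max_mm and zero mismatches inside the anchor region
// (the 3' end of the underlying primer: the last anchor_len pattern bases
// when anchor_at_end, else the first anchor_len — the latter is used when the
// pattern is the reverse complement of a reverse primer).
// [[Rcpp::export]]
DataFrame cpp_find_sites(const std::string& subject, const std::string& pattern,
                         int max_mm, bool anchor_at_end, int anchor_len) {
  const int n = subject.size(), m = pattern.size();
  std::vector<int> starts;
  std::vector<int> mms;
  if (m > 0 && m <= n) {
    const int a0 = anchor_at_end ? std::max(0, m - anchor_len) : 0;
    const int a1 = anchor_at_end ? m : std::min(m, anchor_len);
    for (int s = 0; s + m <= n; ++s) {
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (!base_match(subject[s + k], pattern[k])) {
          if (k >= a0 && k < a1) { ok = false; break; }
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { starts.push_back(s); mms.push_back(mm); }
    }
  }
  return DataFrame::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}

// Merge read pairs by the maximal-scoring ungapped overlap between R1 and the
// reverse complement of R2 (b = revcomp(R2), qb = reversed R2 qualities).
// Offsets place b at position off >= 0 of a; score = matching bases in the
// overlap; only offsets with overlap >= min_overlap and mismatch fraction <=
// max_mm_frac are eligible. Disagreements resolve to the higher-quality base,
// ties to R1.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector a, CharacterVector qa,
                     CharacterVector b, CharacterVector qb,
                     int min_overlap, double max_mm_frac) {
  const int n = a.size();
  if (qa.size() != n || b.size() != n || qb.size() != n)
    stop("all four vectors must have equal length");
  CharacterVector merged(n);
  CharacterVector reason(n);
  for (int i = 0; i < n; ++i) {
    const std::string sa = as<std::string>(a[i]);
    const std::string sqa = as<std::string>(qa[i]);
    const std::string sb = as<std::string>(b[i]);
    const std::string sqb = as<std::string>(qb[i]);
    const int la = sa.size(), lb = sb.size();
    int best_off = -1, best_score = -1;
    for (int off = 0; off + min_overlap <= la; ++off) {
      const int ov = std::min(la - off, lb);
      if (ov < min_overlap) break;
      if (ov <= best_score) break;  // overlap shrinks with off: cannot improve
      int mm = 0;
      for (int k = 0; k < ov; ++k)
        if (sa[off + k] != sb[k]) ++mm;
      const int score = ov - mm;
      if ((double)mm <= max_mm_frac * ov && score > best_score) {
        best_score = score;
        best_off = off;
      }
    }
    if (best_off < 0) {
      merged[i] = NA_STRING;
      reason[i] = "no-overlap";
      continue;
    }
    const int off = best_off;
    const int ov = std::min(la - off, lb);
    std::string out = sa.substr(0, off);
    out.reserve(std::max(la, off + lb));
    for (int k = 0; k < ov; ++k) {
      if (sa[off + k] == sb[k] || sqa[off + k] >= sqb[k])
        out.push_back(sa[off + k]);
      else
        out.push_back(sb[k]);
    }
    if (off + lb > la)
      out += sb.substr(la - off);
    else if (la > off + lb)
      out += sa.substr(off + lb);
    merged[i] = out;
    reason[i] = NA_STRING;
  }
  return List::create(_["merged"] = merged, _["reason"] = reason);
}

// Mismatches of `pattern` (IUPAC) against a fixed end of each sequence:
// prefix (at_start = true) or suffix. Returns NA when the sequence is shorter
// than the pattern. Used by primer trimming on dereplicated merged reads.
// [[Rcpp::export]]
IntegerVector cpp_end_mismatch(CharacterVector seqs, const std::string& pattern,
                               bool at_start) {
  const int n = seqs.size(), m = pattern.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < m) { out[i] = NA_INTEGER; continue; }
    const int s0 = at_start ? 0 : (int)s.size() - m;
    int mm = 0;
    for (int k = 0; k < m; ++k)
      if (!base_match(s[s0 + k], pattern[k])) ++mm;
    out[i] = mm;
  }
  return out;
}
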