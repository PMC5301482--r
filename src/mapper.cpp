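#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Hamming mismatches between read and genome window, early-exiting once the
// count exceeds `cap`. 'N' on either side matches nothing.
static inline int hamming_capped(const char* g, const char* r, int len,
                                 int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    char a = g[i], b = r[i];
    if (a != b || a == 'N' || b == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return out;
}

// Exhaustive ungapped placement of each read: every offset x both
// orientations. Returns the unique placement with minimal mismatch count
// if that minimum is <= max_mismatch; ties -> unmapped.
// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, std::string genome,
                        int max_mismatch) {
  int n = reads.size();
  int glen = (int)genome.size();
  const char* g = genome.c_str();
  LogicalVector mapped(n);
  IntegerVector pos(n), nmm(n);
  CharacterVector strand(n), gseq(n);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int len = (int)fwd.size();
    if (len > glen) stop("read longer than genome");
    std::string rev = revcomp(fwd);
    int best = max_mismatch + 1;  // anything > this is irrelevant
    int best_pos = -1, best_orient = 0, ties = 0;
    int nplace = glen - len + 1;
    for (int orient = 0; orient < 2; ++orient) {
      const char* r = (orient == 0) ? fwd.c_str() : rev.c_str();
      for (int off = 0; off < nplace; ++off) {
        // cap = best: a count equal to best is a tie we must detect
        int mm = hamming_capped(g + off, r, len, best);
        if (mm < best) {
          best = mm; best_pos = off; best_orient = orient; ties = 1;
        } else if (mm == best && best <= max_mismatch) {
          ++ties;
        }
      }
    }
    if (best <= max_mismatch && ties == 1) {
      mapped[i] = true;
      pos[i] = best_pos + 1;  // 1-based
      nmm[i] = best;
      strand[i] = (best_orient == 0) ? "F" : "R";
      gseq[i] = (best_orient == 0) ? fwd : rev;
    } else {
      mapped[i] = false;
      pos[i] = NA_INTEGER; nmm[i] = NA_INTEGER;
      strand[i] = NA_STRING;
      gseq[i] = fwd;
    }
  }
  return DataFrame::create(_["mapped"] = mapped, _["position"] = pos,
                           _["strand_group"] = strand, _["seq"] = gseq,
                           _["n_mismatch"] = nmm,
                           _["stringsAsFactors"] = false);
}

// Per-strand pileup over ungapped alignments: counts of genome-space bases
// A/C/G/T at each covered position. 'N' contributes nothing.
// [[Rcpp::export]]
List pileup_cpp(IntegerVector position, CharacterVector strand_group,
                CharacterVector seq, int genome_length) {
  // two strands x 4 bases x genome_length
  std::vector<std::vector<int>> cnt(8, std::vector<int>(genome_length, 0));
  int n = position.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seq[i]);
    int p0 = position[i] - 1;
    if (p0 < 0 || p0 + (int)s.size() > genome_length)
      stop("alignment exceeds genome bounds");
    bool rev = (as<std::string>(strand_group[i]) == "R");
    int base_off = rev ? 4 : 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      int b;
      switch (s[j]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        case 'T': b = 3; break;
        default: continue;  // N: no evidence
      }
      ++cnt[base_off + b][p0 + j];
    }
  }
  // emit sparse rows (covered positions only), strand-major
  std::vector<int> out_pos; std::vector<std::string> out_str;
  std::vector<int> oa, oc, og, ot;
  for (int sgi = 0; sgi < 2; ++sgi) {
    int off = sgi * 4;
    for (int p = 0; p < genome_length; ++p) {
      int a = cnt[off][p], c = cnt[off + 1][p], gg = cnt[off + 2][p],
          t = cnt[off + 3][p];
      if (a + c + gg + t > 0) {
        out_pos.push_back(p + 1);
        out_str.push_back(sgi == 0 ? "F" : "R");
        oa.push_back(a); oc.push_back(c); og.push_back(gg); ot.push_back(t);
      }
    }
  }
  return List::create(_["position"] = wrap(out_pos),
                      _["strand_group"] = wrap(out_str),
                      _["A"] = wrap(oa), _["C"] = wrap(oc),
                      _["G"] = wrap(og), _["T"] = wrap(ot));
}
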