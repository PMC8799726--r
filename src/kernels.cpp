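#include <Rcpp.h>
using namespace Rcpp;

// FLASH-style overlap merge of one read pair.
// r2 must already be reverse-complemented (and q2 reversed) so both reads
// are on the same strand. Candidate layouts are indexed by the offset of
// r2's start relative to r1's start, from -(len2 - min_overlap) (outie /
// r2 upstream) to len1 - min_overlap (innie / partial 3' overlap),
// covering full containment in between. The best layout minimises
// mismatches / overlap_length, ties broken by longer overlap.
//
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2, CharacterVector q2,
                     int min_overlap, double max_mismatch_ratio) {
  int n = r1.size();
  CharacterVector seq(n), qual(n);
  IntegerVector overlap(n);
  NumericVector ratio(n);
  LogicalVector merged(n);

  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2[i]);
    std::string u1 = as<std::string>(q1[i]);
    std::string u2 = as<std::string>(q2[i]);
    int l1 = s1.size(), l2 = s2.size();
    int best_off = 0, best_len = -1, best_mm = 0;
    double best_ratio = 2.0;
    if (l1 >= min_overlap && l2 >= min_overlap) {
      for (int off = -(l2 - min_overlap); off <= l1 - min_overlap; ++off) {
        int start = std::max(0, off);          // overlap start on r1 axis
        int end = std::min(l1, off + l2);      // overlap end on r1 axis
        int olen = end - start;
        if (olen < min_overlap) continue;
        // abort counting once the layout cannot beat the current best
        int cap = (int)std::floor(best_ratio * olen);
        if (cap > olen) cap = olen;
        int mm = 0;
        for (int p = start; p < end; ++p) {
          if (s1[p] != s2[p - off]) {
            if (++mm > cap) break;
          }
        }
        if (mm > cap) continue;
        double r = (double)mm / (double)olen;
        if (r < best_ratio - 1e-12 ||
            (std::abs(r - best_ratio) <= 1e-12 && olen > best_len)) {
          best_ratio = r;
          best_len = olen;
          best_mm = mm;
          best_off = off;
        }
      }
    }
    if (best_len >= min_overlap && best_ratio <= max_mismatch_ratio + 1e-12) {
      int off = best_off;
      int start = std::max(0, off);
      int end = std::min(l1, off + l2);
      std::string cons, consq;
      cons.reserve(l1 + l2);
      consq.reserve(l1 + l2);
      if (off > 0) {            // r1 leads
        cons.append(s1, 0, off);
        consq.append(u1, 0, off);
      } else if (off < 0) {     // r2 leads (outie)
        cons.append(s2, 0, -off);
        consq.append(u2, 0, -off);
      }
      for (int p = start; p < end; ++p) {
        char b1 = s1[p], b2 = s2[p - off];
        char c1 = u1[p], c2 = u2[p - off];
        if (b1 == b2) {
          cons.push_back(b1);
          consq.push_back(std::max(c1, c2));
        } else if (c1 > c2) {
          cons.push_back(b1);
          consq.push_back(c1);
        } else if (c2 > c1) {
          cons.push_back(b2);
          consq.push_back(c2);
        } else {                // equal qualities: keep read1's base, floor quality
          cons.push_back(b1);
          consq.push_back('#'); // Phred 2
        }
      }
      if (off + l2 > l1) {      // r2 extends past r1
        cons.append(s2, l1 - off, l2 - (l1 - off));
        consq.append(u2, l1 - off, l2 - (l1 - off));
      } else if (off + l2 < l1) { // r1 extends past r2
        cons.append(s1, off + l2, l1 - (off + l2));
        consq.append(u1, off + l2, l1 - (off + l2));
      }
      seq[i] = cons;
      qual[i] = consq;
      overlap[i] = best_len;
      ratio[i] = best_ratio;
      merged[i] = true;
    } else {
      seq[i] = NA_STRING;
      qual[i] = NA_STRING;
      overlap[i] = NA_INTEGER;
      ratio[i] = NA_REAL;
      merged[i] = false;
    }
  }
  return List::create(_["sequence"] = seq, _["quality"] = qual,
                      _["overlap_length"] = overlap,
                      _["mismatch_ratio"] = ratio, _["merged"] = merged);
}

// 3' quality trimming by the running-sum method: subtract the cutoff from
// each quality, form partial sums from the 3' end, and cut at the position
// where the partial sum is minimal (only if that minimum is negative).
// Returns the number of bases to keep per read.
//
// [[Rcpp::export]]
IntegerVector quality_trim_keep_cpp(CharacterVector qual, int cutoff) {
  int n = qual.size();
  IntegerVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(qual[i]);
    int len = q.size();
    long run = 0, best = 0;
    int cut = len; // keep everything by default
    for (int p = len - 1; p >= 0; --p) {
      run += ((int)q[p] - 33) - cutoff;
      if (run < best) { best = run; cut = p; }
    }
    keep[i] = (best < 0) ? cut : len;
  }
  return keep;
}

// Apply pre-drawn substitution errors: for read i, n_errors[i] positions
// are drawn uniformly (R RNG, so seeded runs are reproducible) and the
// base replaced by one of the three other bases.
//
// [[Rcpp::export]]
CharacterVector inject_substitutions_cpp(CharacterVector seqs,
                                         IntegerVector n_errors) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = s.size();
    int ne = n_errors[i];
    for (int e = 0; e < ne; ++e) {
      int pos = (int)std::floor(unif_rand() * len);
      if (pos >= len) pos = len - 1;
      char cur = s[pos];
      char sub;
      do {
        sub = BASES[(int)std::floor(unif_rand() * 4) % 4];
      } while (sub == cur);
      s[pos] = sub;
    }
    out[i] = s;
  }
  return out;
}
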