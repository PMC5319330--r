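#include <Rcpp.h>
using namespace Rcpp;

// Ungapped scan of a bit-encoded read against a bit-encoded reference frame.
// Each element is a 4-bit base set (A=1, C=2, G=4, T=8); a position matches
// when the two sets intersect, so IUPAC ambiguity codes and bisulfite
// conversion frames (reference C also accepting T, or G also accepting A)
// are handled by the encoding, not the loop. Returns
// c(best_offset_0based, best_mismatches, n_placements_at_best); offset -1
// when nothing is within max_mismatch.
// [[Rcpp::export]]
IntegerVector scan_read(IntegerVector read, IntegerVector ref,
                        int max_mismatch) {
  const int n = read.size(), L = ref.size();
  int best = max_mismatch + 1, best_off = -1, ties = 0;
  for (int o = 0; o + n <= L; ++o) {
    int mm = 0;
    bool worse = false;
    for (int i = 0; i < n; ++i) {
      if ((read[i] & ref[o + i]) == 0) {
        if (++mm > best) { worse = true; break; }
      }
    }
    if (worse) continue;
    if (mm < best) { best = mm; best_off = o; ties = 1; }
    else if (mm == best) ++ties;
  }
  if (best > max_mismatch) return IntegerVector::create(-1, -1, 0);
  return IntegerVector::create(best_off, best, ties);
}
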