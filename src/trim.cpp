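#include <Rcpp.h>
using namespace Rcpp;

// One read's 3'-end trimming automaton over integer quality scores.
//
// Scans from the 3' end (index len-1) toward the 5' end. Bases scoring
// below qh are discarded until a base scoring >= qh is found; that base
// becomes the candidate 3' end and is kept tentatively. Scanning continues
// inward, counting consecutive high-quality bases; up to nl consecutive
// low-quality bases are tolerated (they reset the high-quality counter but
// are kept tentatively). When nh consecutive high-quality bases have been
// seen the trim point is fixed at the candidate end. If nl is overrun, all
// tentatively kept bases are dropped and the scan restarts inward of the
// offending low-quality run. A candidate that would leave fewer than
// minlen bases, or a scan that reaches the 5' end without completing an
// nh run, yields 0 (nothing kept).
static int trim_one(const int *q, const int len, const int qh,
                    const int nh, const int nl, const int minlen) {
  int p = len - 1;
  for (;;) {
    while (p >= 0 && q[p] < qh) --p;    // discard the 3' low-quality tail
    if (p < 0 || p + 1 < minlen) return 0;
    const int e = p;                    // candidate 3' end (0-based)
    int hq_run = 1, lq_run = 0;
    if (hq_run >= nh) return e + 1;
    bool overrun = false;
    for (--p; p >= 0; --p) {
      if (q[p] >= qh) {
        lq_run = 0;
        if (++hq_run >= nh) return e + 1;
      } else {
        hq_run = 0;
        if (++lq_run > nl) { overrun = true; --p; break; }
      }
    }
    if (!overrun) return 0;             // hit the 5' end: no nh run found
  }
}

// Batched trimming over a ragged array: scores holds all reads
// concatenated 5'->3', lens the per-read lengths. Returns the 1-based
// inclusive kept end per read (0 = nothing kept).
// [[Rcpp::export(name = ".trim_ends_cpp")]]
IntegerVector trim_ends_cpp(IntegerVector scores, IntegerVector lens,
                            int hq_threshold, int hq_run, int lq_tolerance,
                            int min_length) {
  const int n = lens.size();
  const int *q = INTEGER(scores);
  double total = 0;
  for (int i = 0; i < n; ++i) total += lens[i];
  if (total != (double)scores.size())
    stop("sum(lens) does not match length(scores)");
  IntegerVector ends(n);
  R_xlen_t off = 0;
  for (int i = 0; i < n; ++i) {
    ends[i] = trim_one(q + off, lens[i], hq_threshold, hq_run,
                       lq_tolerance, min_length);
    off += lens[i];
  }
  return ends;
}
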