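---
title: "Content-dependent quality trimming: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content-dependent quality trimming: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualtrim)
```

## Why content-dependent trimming

Illumina base-call quality decays along the read: the error probability
rises roughly exponentially from the 5′ to the 3′ end. For de novo
assembly this matters twice over — erroneous k-mers inflate the de Bruijn
graph, and discarding whole reads to avoid them wastes coverage. Two
fixed-recipe alternatives both lose information: hard-trimming every read
to a fixed length throws away good tails of good reads, while
filter-on-mean approaches keep decayed tails whenever the 5′ half is good
enough to carry the average. The approach implemented here is *content
dependent*: how much of each read survives is decided by the local
arrangement of high- and low-quality bases in that read, and an isolated
low-quality base inside high-quality context is kept rather than used as
an excuse to discard the read.

A deliberate non-goal is error *correction*: base calls and their quality
scores pass through unmodified (only 3′ bases are removed, never 5′
bases, and never bases in the middle). Adapter removal and quality-score
recalibration are likewise out of scope; run dedicated tools for those
before or after this one.

## The two-stage filter

### Stage 1: the 3′ trimming automaton

The scan starts at the 3′ end with two counters (consecutive high-quality
run, consecutive low-quality run) and proceeds toward the 5′ end:

1. Bases scoring below the high-quality threshold `hq_threshold`
   (*Q~H~*) are removed until a base at or above it is found. That base
   becomes the **candidate 3′ end** and is kept tentatively.
2. Scanning inward, each high-quality base extends the high-quality run;
   each low-quality base resets it and extends the low-quality run. Up to
   `lq_tolerance` (*n~L~*) consecutive low-quality bases are tolerated
   and kept tentatively.
3. When the high-quality run reaches `hq_run` (*n~H~*), trimming
   terminates: the read is cut at the candidate end, retaining every
   tentatively kept base, including tolerated low-quality ones.
4. When the low-quality run exceeds `lq_tolerance`, all tentatively kept
   bases are dropped and the scan restarts inward of the offending run
   (step 1, on the remaining prefix).

If no candidate at or above `min_length` (*L*) can terminate this way —
including a scan that reaches the 5′ end with the run incomplete — the
read keeps nothing and is rejected as too short. Consequently every kept
read is a prefix of the input, ends in a base scoring at least *Q~H~*,
and has at least *L* bases. The automaton never needs the error
probabilities themselves: all decisions compare integer scores with
integer thresholds.

### Stage 2: approval

A trimmed read is approved only if (a) no base scores below the floor
`lq_floor` (*Q~L~*) and (b) *strictly more* than `hq_fraction` (*f*) of
its bases score at or above *Q~H~*, the fraction being computed over the
trimmed length. The floor is checked first; a read failing both is
reported as failing the floor.

### Paired-end routing

Both mates are trimmed independently. Pairs with two approved mates go to
the synchronized paired outputs; pairs with exactly one go to a single
unpaired file (mate 1 and mate 2 survivors interleaved in input-pair
order); pairs with none count as removed. Mates are paired by ordinal
position in the two files — the Illumina file convention — not by
read-name parsing, which would require dialect knowledge of name
suffixes. The run counters satisfy two identities by construction:
`reads_scanned = reads_removed + reads_kept_paired + reads_kept_unpaired`
and `reads_kept_paired = 2 * pairs_kept`.

### Duplicate pairs

PCR/optical duplicate pairs are removed *before* trimming (duplicates
should be judged on the raw fragments, and trimming first could make
distinct fragments collide). The key is the uppercased concatenation of
the first `k` = 50 bases of each mate; the first pair per key wins, later
ones are dropped. No reverse-complement or mate-swap canonicalization is
applied, qualities and names are ignored, and reads shorter than `k`
contribute their full sequence. One key per unique pair is held in a hash
table, which is the scaling limit of this filter (fine for tens of
millions of pairs on a workstation; not for arbitrarily large streams).

## Parameters

| parameter      | symbol  | default | units  | why this default |
|----------------|---------|---------|--------|------------------|
| `hq_threshold` | *Q~H~*  | 25      | score  | ≈ 0.3% error on the log-odds scale; raising it to 30 typically discards most reads of a lane, lowering to 20 keeps barely more reads at ~3× the error rate (~0.01) |
| `lq_floor`     | *Q~L~*  | 10      | score  | ≈ 9% error; a single such base is enough doubt to drop the read |
| `hq_run`       | *n~H~*  | 5       | bases  | five clean bases per tolerated dip implies ≥ ~83% high-quality content, consistent with `hq_fraction` |
| `lq_tolerance` | *n~L~*  | 1       | bases  | keeps isolated dips, rejects dip runs |
| `min_length`   | *L*     | 50      | bases  | shorter reads contribute little to assembly |
| `hq_fraction`  | *f*     | 0.8     | —      | read-level guard matching `hq_run`/`lq_tolerance` |
| `encoding`     | —       | sanger  | —      | modern FASTQ; `illumina` and `solexa` for legacy data |

`hq_run` and `lq_tolerance` interact with `hq_fraction`: tolerating one
low-quality base per five high-quality ones already guarantees about 83%
high-quality content, so `hq_fraction` = 0.8 rarely bites on its own with
the default automaton settings. Tune them together.

Quality dialects are never guessed from the data. Offsets 33 and 64
produce overlapping byte ranges, and a wrong guess silently shifts every
score by 31; the user states the dialect (`sanger`, `illumina`,
`solexa`).

## Numerical and boundary choices

Where the verbal description of such a filter is ambiguous, this package
fixes the semantics as follows (these choices are frozen and tested):

* "High-quality" means score **≥** *Q~H~*, both in the automaton and in
  the approval fraction; "below the floor" means score **<** *Q~L~*
  (a base at exactly *Q~L~* survives). The fraction test is strict:
  exactly *f* is rejected.
* A tolerated low-quality base **resets** the consecutive high-quality
  counter; termination requires *n~H~* *uninterrupted* high-quality
  bases.
* On restart after an overrun, the scan resumes inward of the offending
  run; bases between the failed candidate and that run are permanently
  discarded.
* A read whose scan would pass below *L* unterminated is rejected rather
  than hard-cut at *L*: a hard cut would break the guarantee that kept
  reads end in a high-quality base.
* The approval fraction's denominator is the **trimmed** length.
* Positions are 1-based; the trim point is the inclusive index of the
  last kept base; 0 means nothing kept.
* Error probabilities are reported on the scale of the configured
  dialect: Phred `p = 10^(-Q/10)` for `sanger`/`illumina`, log-odds
  `p = 1/(1+10^(Q/10))` for `solexa`. The log-odds values are the ones
  conventionally quoted for the default thresholds (0.0032 at Q25,
  0.0909 at Q10); the two scales agree to within 10⁻⁴ above Q30.

The automaton itself is compiled code (a per-base C++ scan); everything
around it is vectorized R.

## The synthetic read generator

`generate_pairs()` emulates a paired-end Illumina library *at the level
this tool observes*: per-base quality scores with a positional trend, and
exact duplicate pairs.

* The positional trend interpolates the error probability geometrically
  from `p(q_start)` to `p(q_end)` (`decay = "exponential_error"`),
  mirroring the exponential 5′→3′ error growth of real reads. On the
  Phred scale this is exactly a linear score decline, so the `"linear"`
  mode coincides there; on the log-odds scale they differ at low quality.
* Per-base jitter is additive Gaussian noise on the score (`noise_sd`),
  rounded to integers and clipped to the encodable range — a score
  marginal, not a full error model.
* Base sequences are uniform random over A/C/G/T: no reference genome,
  adapters, indels, or score-correlated miscalls. The trimmer never
  inspects base identity (the duplicate filter's prefix aside, for which
  random sequences suffice), so this is the right fidelity for testing
  *this* package — and it means passing tests say nothing about, e.g.,
  adapter contamination handling on real data.
* `floor(n * dup_rate)` pairs are exact copies (sequence and qualities)
  of earlier pairs, at positions drawn uniformly; the injected count is
  recorded as ground truth.

The defaults (100 bp, Q38 falling to Q10, jitter SD 3) imitate a
late-cycle-degraded Illumina GAII run. Everything is deterministic under
a fixed seed.

## How the implementation is verified

* **Analytic conversions.** The score→probability values quoted above
  are recomputed and checked at their printed precision.
* **Declarative oracle, exhaustively.** The automaton's trim point has an
  equivalent declarative characterization: the 3′-most high-quality
  position from which an inward scan completes *n~H~* consecutive
  high-quality bases before hitting *n~L~* + 1 consecutive low-quality
  ones. The test suite implements this characterization independently in
  plain R and compares it with the automaton on **every** quality string
  of length 1–12 over the score alphabet {5, 20, 30} (threshold 25), for
  *n~H~* ∈ {2, 3} and *n~L~* ∈ {0, 1, 2} — about 800,000 strings per
  parameter setting. Since the characterization depends on scores only
  through the ≥-threshold comparison, it is evaluated once per
  high/low pattern and fanned out, which is exact.
* **Invariant suites.** Prefix/terminal-quality/length-floor guarantees,
  trimming idempotence, monotonicity in *n~L~*, the closed form at
  *n~L~* = 0, routing conservation, mate synchronization, counter
  identities, duplicate-filter idempotence and key uniqueness, and FASTQ
  round-trips for both offsets, all on randomized inputs under fixed
  seeds.
* **End-to-end.** A 10,000-pair library (Q38→Q8, 20% duplicates) is
  generated, deduplicated (the removed count must equal the injected
  truth exactly) and trimmed (every kept read must end ≥ *Q~H~* at
  length ≥ *L*). Per-position mean scores are compared with the
  generating profile at the three-standard-error level. Two details make
  this comparison statistically honest: the means are computed over the
  *unique* pairs (injected duplicates are copies, not independent draws,
  and would understate the standard error), and with 100 positions × 2
  mates checked at 3 SE, the chance-expected number of excursions
  (≈ 0.27 per 100 under the null) is allowed — up to two per mate, with
  a hard cap at 4.5 SE that would catch any real bias.

These problem sizes (exhaustive to length 12, 10⁴ pairs end-to-end) keep
the whole suite under a minute while exercising every code path the
larger regime would.

## Known limitations

* The duplicate filter holds one key per unique pair in memory and
  treats a pair and its mate-swapped or reverse-complemented twin as
  distinct.
* Unpaired survivors from different runs are never re-paired; read names
  are never rewritten.
* Multi-line (wrapped) FASTQ, interleaved FASTQ, FASTA and SAM/BAM input
  are not supported.
* Single-end duplicate removal is not offered (a 50 bp single-read
  prefix is a much weaker fragment identity than a pair of them).
* The tool is single-threaded by design; throughput is I/O-bound at
  typical desk scale.
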