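# qualtrim

Content-dependent quality trimming of Illumina FASTQ reads before de novo
assembly or mapping.

Base-call error probability in Illumina reads grows roughly exponentially
from the 5′ to the 3′ end of a read, and those errors inflate de Bruijn
graphs and break contigs. `qualtrim` removes untrustworthy 3′ read tails
while deliberately *keeping* isolated low-quality bases that sit inside
otherwise high-quality sequence — a single mid-read dip carries far less
risk than a decayed tail, and discarding the whole read for it wastes
coverage. The package is aimed at anyone preprocessing paired-end or
single-end Illumina libraries: it trims, filters, keeps mate files
synchronized, rescues half-surviving pairs as single-end reads, and can
remove PCR-duplicate pairs.

## The algorithm

Each read is processed in two stages, controlled by six parameters
(defaults in parentheses):

**Stage 1 — 3′ trimming automaton.** Scanning from the 3′ end, bases with
quality score below the high-quality threshold *Q<sub>H</sub>* (25) are
removed. The first base with score ≥ *Q<sub>H</sub>* becomes the candidate
3′ end and is kept tentatively. Scanning continues inward: up to
*n<sub>L</sub>* (1) consecutive low-quality bases are tolerated (kept
tentatively, resetting the high-quality run counter); once
*n<sub>H</sub>* (5) consecutive high-quality bases have been seen, the
read is cut at the candidate end and all tentatively kept bases are
retained. If *n<sub>L</sub>* is overrun, the tentative bases are dropped
and the scan restarts further inward. A read that cannot terminate this
way above the minimum length *L* (50) is discarded, so every kept read
ends in a base scoring ≥ *Q<sub>H</sub>* and has length ≥ *L*.

**Stage 2 — approval.** A trimmed read is kept only if more than a
fraction *f* (80%) of its bases score ≥ *Q<sub>H</sub>* and no base scores
below the floor *Q<sub>L</sub>* (10).

For paired input, pairs with both mates approved go to the paired output
files; pairs with exactly one approved mate send that mate to an unpaired
(single-end) file. Sanger (offset 33), Illumina (offset 64) and early
Solexa (offset 64, log-odds scale `p = 1/(1+10^(Q/10))`) quality dialects
are supported; on the log-odds scale the defaults *Q<sub>H</sub>* = 25 and
*Q<sub>L</sub>* = 10 correspond to error probabilities of about 0.0032
and 0.0909.

## Worked example

Simulate a small paired-end library with decaying 3′ quality and 10%
duplicate pairs, then deduplicate and trim it:

```r
library(qualtrim)

sim <- generate_pairs(500, quality_profile(), dup_rate = 0.1, seed = 7,
                      prefix = "sim")
stats <- process_pairs("sim_1.fastq", "sim_2.fastq", "out",
                       trim_config(), dedup = TRUE)
```

The run logs (and writes to `out.stats`):

```
reads_scanned	900
reads_removed	679
reads_kept_paired	60
reads_kept_unpaired	161
pairs_scanned	450
pairs_kept	30
duplicates_removed	50
```

All 50 injected duplicate pairs were removed before trimming; of the 450
remaining pairs (900 reads), 30 pairs survived with both mates intact
(written to `out_trim1.fastq`/`out_trim2.fastq`, still synchronized), 161
reads survived alone (`out_trim_unpaired.fastq`, usable as single-end
input), and 679 reads failed the quality demands. The default profile
decays from Q38 to Q10 over 100 bp, so most reads lose their 3′ half and
many drop below the 50 bp floor — the expected behaviour for so steep a
decay.

The same run from a shell:

```sh
qualtrim simulate --prefix sim --n 500 --duprate 0.1 --seed 7
qualtrim paired sim_1.fastq sim_2.fastq --prefix out --dedup
```

(`qualtrim` is installed under `exec/` in the package directory; see
`qualtrim --help` for the `--hq`, `--lq`, `--mh`, `--ml`, `--minlen`,
`--frac` and `--format` flags.)

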