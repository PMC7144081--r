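---
title: "Reference-free quality control for long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free quality control for long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(overqc)
```

## The problem

Long-read platforms (PacBio, Oxford Nanopore) deliver reads of thousands to
tens of thousands of bases at per-base error rates of several percent, and
increasingly without meaningful Phred scores. Classical short-read QC
either leans on those Phred scores or on alignment to a reference genome;
for a de-novo project neither may exist. Yet every long-read library
contains some fraction of *non-sense reads* — reads that overlap no other
molecule in the same library, produced by pore artifacts, chemistry
failures or extreme basecalling error. Because genomic DNA is fragmented
randomly, a genuine read at reasonable depth *must* overlap other reads;
a read that overlaps (almost) nothing carries no usable signal. The
fraction of such reads is a compact, reference-free indicator of library
health, and `overqc` estimates it together with per-read error rates,
adapter boundaries and the usual descriptive statistics.

## The estimator pipeline

1. **Sketching.** Every read is reduced to its (w,k)-minimizers: in each
   window of `w = 10` consecutive k-mers (`k = 15`) the k-mer with the
   smallest canonical hash is kept. Canonical hashing (the hash of the
   lexicographically/numerically smaller of a k-mer and its reverse
   complement, mixed through a fixed 64-bit finalizer and truncated to 53
   bits so hashes are exact doubles) makes sketches strand-invariant and
   platform-independent. K-mers containing `N` are skipped. `k = 15` and
   `w = 10` follow common long-read overlap practice: 15-mers are long
   enough that two unrelated 10 kb reads share almost none, short enough
   to survive ~10% error; `w = 10` keeps roughly 2/(w+1) = 18% of k-mers.
2. **Indexing.** A hash -> (read, position, strand) postings table over
   the whole dataset. Hashes occurring in more reads than the 99.9th
   percentile of the per-hash occurrence distribution (and never fewer
   than 100 reads) are masked: high-frequency minimizers are repeat
   signatures and generate spurious matches.
3. **Overlap detection.** For each sampled read, hits are grouped per
   (target read, relative strand) and chained into the longest collinear
   run; both coordinates must increase (target decreasing for `-`
   chains) and no positional gap may exceed `max_gap = 2000` bases. The
   chain is O(n^2) per group — a deliberate desk-scale simplification
   with the same contract as production chainers.
4. **Filtering.** An overlap is accepted iff (a) it has at least
   `min_shared = 4` chained shared minimizers, (b) its dovetail-implied
   span is at least `min_span = 500` bases, and (c) it is *proper*: on
   each side it reaches within `terminal_slack = 1000` bases of an end of
   one of the two reads (dovetail/containment). Purely internal matches
   are the signature of repeats, not of genuine fragment overlap.
   The span test uses the implied span (chain span plus, per side, the
   smaller of the two reads' overhangs) because a minimizer chain
   systematically stops about one thinned-minimizer spacing short of the
   true overlap end; filtering on the bare chain span would discard
   genuine overlaps barely above `min_span`. Reported coordinates remain
   the chain bounds, 0-based and half-open on each read's forward strand.
5. **Classification.** A sampled read with `nonsense_max_partners = 2`
   or fewer distinct overlapping partners is flagged as a non-sense read.
   The dataset noise fraction is the flagged fraction of the sample, with
   a 95% Wilson score interval (chosen over Wald for its small-count and
   boundary behavior; the upstream method prints no interval at all).

Sampling uses single-pass reservoir sampling (default 5000 reads of at
least 1000 bases, seed 7), so the pipeline is deterministic for a fixed
seed and input order and its cost is bounded by the sample size, not the
dataset.

## Per-read error rates from k-mer survival

For each accepted overlap of a read, let `f` be the fraction of the
read's minimizers inside the overlap window that survived as chained
shared minimizers. A k-mer survives only if it is error-free in *both*
reads, so `f` estimates `(1-e)^(2k)` when both reads err at rate `e`.
Attributing error symmetrically gives the per-overlap estimate
`e = 1 - f^(1/(2k))`; a read's error rate is the median over its
accepted overlaps, times a calibration constant `c` that absorbs
minimizer-sampling bias (errors in the partner read also perturb
*which* k-mers are selected as minimizers). Parameter recovery on
simulated reads of known substitution rate (300 kb genome, 20x, rates
0.05/0.10/0.15) showed the raw estimator recovers the truth to within
about 0.015 at every level, so `c` is fixed at 1.0; the knob is kept
because other sketch geometries (smaller `w`, homopolymer compression)
would need it.

Reads with no accepted overlap have no estimate (`NA`) in the per-read
table. For the QV-versus-error association analysis
(`qv_error_association()`) such reads are right-censored at the
estimator's detection ceiling `1 - (1/(m+1))^(1/(2k))` (`m` = the read's
minimizer count), i.e. treated as "at least this erroneous": a read
whose sketch shares nothing with any other read behaves as maximally
erroneous, which is exactly the signature of high-QV artifact reads.

## Adapter boundaries

Un-trimmed terminal adapters are non-genomic, so accepted overlaps begin
only after them and the uncovered prefix lengths of well-supported reads
(>= 3 partners) pile up at the adapter length. The boundary is the median
uncovered prefix (suffix), reported only when at least 50 reads
contribute and the raw median exceeds the noise floor `w + k + 5` bases —
below that, plain minimizer spacing explains the uncovered ends. One
correction is applied: the first *shared* minimizer sits, in median,
`log(2) * (w+1) / (2 * (1-e)^k)` bases past the true boundary (selected
minimizers are `(w+1)/2` bases apart and only `(1-e)^k` of k-mers are
error-free), so that lag — computed from the dataset's own estimated
error rate — is subtracted. At 10% error the lag is about 19 bases;
without the correction a 45-base adapter is reported near 66.

## The synthetic-data generator

`simulate_dataset()` draws reads from a random i.i.d. genome (default
1 Mb at 45% GC) with lognormal lengths (mean ~8 kb, sdlog 0.35, minimum
500), uniform start positions, equiprobable strands, and per-base
mismatch/insertion/deletion errors (default 5%/2.5%/2.5%, a PacBio-like
10% total). Non-sense reads are injected as i.i.d. random sequence —
the purest testable form of "overlaps nothing" — with an optional
high-error genomic variant (35% error) and an optional short-fragment
length mode (lognormal mean ~1 kb) that reproduces the failed-library
signature: depressed standardized coverage in the short length bins and
excess short-fragment mass. Contaminant spikes draw short fragments
(mean ~4.5 kb) from one window (default 50 kb) of a second, GC-divergent
genome (default 200 kb at 65% GC), which produces a secondary GC mode
that disappears when contaminant-truth reads are removed. Base qualities
encode each read's true error rate as `round(-10*log10(e))` with ±1
jitter; injected noise reads instead get a constant decoy QV (default
10), emulating high-quality non-informative reads, so the QV-vs-error
analysis has known truth in both directions.

What the generator does *not* emulate: platform-specific error profiles
(homopolymer compression, burst indels), chimeric reads, coverage biases,
real repeat structure, or signal-level artifacts. Passing tests therefore
demonstrate estimator correctness under the stated statistical model, not
performance on any particular instrument's quirks; the repeat-masking and
properness filters in particular face far milder conditions on an i.i.d.
genome than on a real one.

## Validation conditions and numerical choices

The package's acceptance checks (mirrored in `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) run at these problem sizes, chosen as
the smallest scales at which the estimated quantities stabilize:

* Noise-fraction recovery: 1 Mb genome, 25x, injected fractions
  0/0.1/0.2/0.3, tolerance ±0.03, strict monotonicity; clean floor
  <= 0.02.
* Error-rate recovery: 300 kb, 20x, substitution rates 0.05/0.10/0.15,
  tolerance ±0.03, monotone.
* Adapter: 300 kb, 15x, a 45-base adapter at both ends, tolerance
  ±(w+5) bases; adapter-free control must report 0.
* Overlap-engine sensitivity: <= 50 reads of ~1.6 kb at 5% substitution
  per read (~10% pairwise divergence), compared against a brute-force
  shared-canonical-k-mer oracle restricted to the true overlap interval;
  sensitivity >= 95%, and zero accepted overlaps among independent random
  reads over 100 seeded trials. The divergence condition is stated
  pairwise because at ~19% pairwise divergence a 500-base overlap
  carries an expected 2 shared minimizers under this sketch geometry —
  below any usable acceptance threshold — so no 4-minimizer engine can
  reach 95% sensitivity there.

Degenerate inputs are defined, not errors, wherever a value exists:
sequences shorter than `k` sketch to nothing; a zero-variance coverage
sample standardizes to all zeros with a warning; an all-`N` read has `NA`
GC; a read shorter than one complexity window is a single window; fewer
than 50 adapter-contributing reads yield "undetermined" rather than a
number. Ties in minimizer selection go to the leftmost k-mer; ties in
overlap deduplication go to larger `n_shared`, then larger span, then
target id. The per-read median (not mean) over overlap error estimates
resists the occasional mis-chained overlap.

## Conventions

Per-read QV is the arithmetic mean of a read's Phred values, matching
the field's reporting convention for "average read quality"; the
alternative (Phred of the mean error probability) is dominated by the
worst bases and is deliberately not used. Sequence complexity is mean
Shannon entropy over 64-base tiles with a 1-bit low-complexity threshold
(the entropy of a perfect two-letter repeat); DUST-style scores would
serve equally and differ only in scaling. "Coverage" is used in two
senses, kept separate throughout: the *partner count* drives the
non-sense classification, while *mean depth* (summed accepted overlap
spans over read length) drives the standardized-coverage plot, z-scored
with the sample (n-1) standard deviation across all sampled reads and
drawn with reference lines at ±3 SD.

## Known limitations

* The noise-fraction estimator is downward-blind to noise reads shorter
  than `min_read_len` (they are never sampled); the short-fragment mass
  in the length histogram is the complementary signal.
* At per-read error rates near 15%, accepted overlaps per read drop
  sharply (expected shared minimizers per full overlap approach
  `min_shared`), so partner counts — and with them the noise fraction —
  begin to inflate; beyond ~15% the classifier and the error estimator
  degrade together.
* The desk-scale chainer is quadratic per hit group; the package is
  built for samples of thousands of reads, not full production flowcells.
* Adapter detection reports a single boundary per side (the median); it
  will not resolve mixtures of trimmed and un-trimmed reads.
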