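---
title: "Quantifying organellar tRNA end-processing with trnaproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organellar tRNA end-processing with trnaproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaproc)
```

## The measurement model

Organellar tRNAs are matured from precursors by removal of a 5' leader
(RNase P) and a 3' trailer (RNase Z). In a size-fractionated small-RNA
library, mature tRNAs produce reads confined to the annotated gene body,
while unprocessed precursors produce reads that extend into the flanking
sequence. `trnaproc` turns aligned reads into a per-tRNA maturation readout
in three steps.

**Counting.** Each tRNA gene contributes three count bins per sample: the
mature interval and two fixed flank windows of 50 nt immediately up- and
downstream (strand-aware: the leader is the biological 5' side). A read is
assigned to a bin when the fraction of the *read* covered by the bin is at
least `f_mature = 0.3` for the mature region or `f_flank = 0.1` for a flank —
the `-f` convention of BEDtools `intersect`, with ties (`>=`) counting. The
asymmetric thresholds reflect the geometry: a precursor read of ~80 nt
carries at most a few tens of leader nucleotides, so a low flank threshold is
needed to see precursors at all, while the higher mature threshold keeps
stray flank-only fragments out of the mature bin. One read may legitimately
increment both a mature and a flank counter — precursor reads spanning the
cleavage site are exactly the signal of interest — and a read overlapping two
distinct genes increments both, since no exclusivity rule is imposed.

**The PER statistic.** For mature count $m$ and flank count $f$,

$$\mathrm{PER} = \log_2 (m / f),$$

computed per sample and per end (5' or 3'). High PER means efficient
processing. PER is *undefined* when either count is zero; we deliberately use
no pseudocounts, so "not detected" propagates as a dash instead of a
fabricated extreme value. Between two samples the contrast is summarised as
$M = \mathrm{PER}_{con} - \mathrm{PER}_{ref}$ and
$A = (\mathrm{PER}_{con} + \mathrm{PER}_{ref})/2$; because PERs are already
log ratios (and can be negative), M and A are taken on the values directly,
whereas accumulation MA plots first take $\log_2$ of the (positive) RPKM
values.

**Testing.** Each locus with defined PERs in both samples yields a 2×2 table
$[[m_{ref}, f_{ref}], [m_{con}, f_{con}]]$ tested with Fisher's exact test,
followed by Benjamini–Hochberg adjustment over the defined tests.

## Structural rules of organellar annotations

Three quirks of plastid/mitochondrial genomes are handled explicitly rather
than left to the aligner:

* **Inverted-repeat duplicates.** Plastid genomes carry a large inverted
  repeat; tRNAs inside it exist as exact forward/reverse-complement pairs
  that are indistinguishable to a mapper. Their counts are combined and
  assigned to the forward-strand instance; the other copy is dropped from all
  per-locus reporting. A pair without exactly one forward member is a
  configuration error.
* **Tandem identical copies.** Some mitochondrial tRNAs occur twice with
  identical gene *and* 50-nt flank sequence. Counts are combined into the
  instance listed first on the genome (smallest start coordinate).
* **Intron-containing plastid tRNAs.** Reads from spliced tRNAs map across
  gaps with algorithmic ambiguity, so intron-bearing plastid loci are
  excluded from PER computation entirely.

Duplicate groups are *declared* in the annotation schema (a group-id and kind
column) rather than auto-detected from sequence, because detection would
smuggle in a sequence-identity policy that the analysis itself does not need;
the synthetic generator writes these columns, and real annotations are small
enough to curate. Nucleus-encoded tRNAs are accepted and carried through
accumulation analysis but excluded from PER reporting unless
`include_nuclear = TRUE`.

Internally all coordinates are 0-based half-open (BED convention); GTF input
is converted on load. Flanks are clipped at contig ends by default — matching
linearised reference sequences — with `circular = TRUE` available to wrap
windows around the origin of a circular organellar contig (a wrapped window
becomes two parts whose overlaps are summed per read). Flank windows are kept
at a fixed ±50 nt regardless of neighbouring genes; no trimming against
adjacent annotations is attempted, so in dense regions a flank can overlap a
neighbouring gene's reads (visible as high flank counts, e.g. where a tRNA
sits immediately downstream of another gene).

## Choices where the analysis was genuinely open

* **Fisher sidedness.** The package default is the one-sided alternative
  `"greater"` on the table above, i.e. a test specifically for *relative
  precursor excess in the contrast sample* (odds ratio > 1). This is the
  question a processing-enzyme knock-down asks, and it is the convention
  under which the package's fixture tables are internally consistent. The
  two-sided point-probability test and the opposite one-sided test are
  available via `alternative =`.
* **BH family.** The family over which adjustment is performed is a policy,
  not a fact of the data: `run_pipeline()` defaults to pooling all defined 5'
  and 3' tests of one run into a single family (`bh_family = "run"`), and the
  run log records the family size and membership so the choice is always
  auditable. `"per_end"` adjusts each end separately; a standalone
  `per_test()` call adjusts within its own table.
* **Multi-mapped reads.** tRNA genes are repetitive, so counting assumes
  alignments produced *without* a uniqueness filter, and every reported
  placement counts once. `multimap_weight = TRUE` optionally down-weights
  placements by 1/placements; it is off by default because fractional counts
  would break the exactness of the Fisher test.
* **Strand.** Counting is strand-blind by default (the BEDtools `-f`
  intersection does not require strand match); `stranded = TRUE` restricts to
  same-strand hits.
* **Printing.** Result tables carry full-precision values plus "printed"
  columns rounded half-away-from-zero to 2 decimals, so comparisons against
  published-style tables are explicit; `validate_against_fixture()` compares
  at a configurable absolute tolerance (default 0.005 = 2-decimal precision)
  and flags value, definedness (number vs dash) and key mismatches
  separately.

## The synthetic data generator

`build_genome()` creates two contigs ("pt", "mt") with non-overlapping tRNA
loci of 70–90 nt, at least ~300 nt apart, plus on demand: inverted-repeat
pairs (exact reverse-complement copies, flanks included), tandem duplicates
(identical copies with identical 50-nt flanks) and intron-flagged plastid
loci. `sim_truth()` fixes the generative parameters: per-locus expected
molecule counts (Poisson), per-sample processing probabilities `p5`/`p3`, and
extension lengths `leader_len`/`trailer_len` (default 20 nt each). Each
molecule is independently 5'-processed with probability `p5` and 3'-processed
with `p3`; an unprocessed end extends the molecule beyond the mature locus.
Every molecule yields one read spanning it from the biological 5' end,
truncated to a length drawn uniformly from `read_length_range` (default
70–150 nt, bracketing the ~80 nt reads of a size-fractionated library). The
knock-down sample multiplies `p5` by `knockdown_factor` (default 0.5, i.e.
unprocessed-5' fractions of 0.2 vs 0.6 at `p5 = 0.8`).

`expected_per()` gives the closed-form expectation of the counted PER under
this model — enumerating the four processing states and the read-length
distribution and applying the same overlap thresholds as the counting stage —
which is what simulation tests recover against.

Defaults were chosen once as a realistic organellar regime: hundreds to
thousands of molecules per locus (organellar tRNAs are abundant), 20-nt
unprocessed extensions (well above the 0.1×read-length flank threshold so
precursors are detectable), and Poisson molecule counts with uniform
read-length jitter as the simplest structure consistent with count-based
exact testing.

What the generator deliberately does **not** model: sequencing error, adapter
or ligation bias, PCR duplicates, base qualities, and — most importantly —
the modification-induced reverse-transcription dropout that makes some real
tRNA species severely underrepresented. A per-locus `capture_efficiency`
multiplier can mimic the *magnitude* of underrepresentation, but passing
simulation tests shows correctness of the counting and inference machinery,
not robustness to these biochemical artefacts.

## Numerical notes

* Fisher p values come from `stats::fisher.test` (conditional exact test;
  two-sided uses the point-probability rule). Tests verify it against an
  independent hypergeometric enumeration on all 2×2 tables with margins ≤ 12
  to 1e-12 relative error; large printed counts (~10^6) stay well within the
  support sizes the implementation handles exactly.
* BH adjustment is `stats::p.adjust` over the defined tests only; undefined
  entries never inflate the family size.
* Empty margins (a sample with zero reads in both bins) yield NA rather than
  an error; `compute_per` likewise returns NA, never ±Inf.
* Overlap thresholds are compared with `>=`, so a read exactly at 0.3/0.1
  counts.
* Everything downstream of the RNG-seeded simulator is deterministic:
  rerunning a pipeline configuration reproduces byte-identical output tables.

## Problem sizes used by the test suite

The packaged checks run on deliberately small instances: oracle equivalence
on 200 random instances of ≤ 50 reads × ≤ 10 loci against a brute-force
double loop; exact-test enumeration over all 2×2 tables with margins ≤ 12;
parameter recovery on 4 loci × 5,000 molecules × 20 simulation seeds
(recovered mean PER difference within 3 standard errors of the analytic
expectation); and a null calibration with identical samples over a family of
20 loci, where the Fisher rejection rate at α = 0.05 must sit inside its 99%
binomial band (the discrete test is conservative, so rejections are rare).

## Limitations

* The pipeline consumes *alignments*; trimming, QC and mapping policy
  (including how a mapper distributes multi-reads) are upstream decisions
  that materially affect flank counts.
* PER compares read counts, not molecule counts; reverse-transcription
  blocks at modified nucleosides can deflate mature counts in a
  species-specific way, which cancels *within* a locus between samples only
  if the modification status is unchanged by the perturbation.
* The ±50 nt flank window is a proxy for the true leader/trailer, whose
  lengths vary by locus; very short leaders dilute the flank signal.
* Adjusted p values depend on the declared BH family; comparisons across
  analyses must hold the family policy fixed (it is logged for this reason).
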