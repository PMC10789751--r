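---
title: "Methods: readthrough detection, matched statistics, and the synthetic truth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: readthrough detection, matched statistics, and the synthetic truth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the detection
model and its assumptions, the statistical machinery, the synthetic-data
model that provides ground truth, and the numerical and design choices made
where the underlying procedure left room.

## The detection model

Transcription readthrough produces a continuous stretch of coverage
immediately downstream of a gene's transcription termination site (TTS),
decaying with distance. The caller models a tail as a run of consecutive,
non-overlapping windows, starting exactly at the TTS and extending in the
transcription direction, each of which clears a coverage floor:

* `window_bp = 500` — window size; tail lengths are therefore resolved to
  one window (the recovered length of a planted tail is within 500 bp of
  truth, one window short when the remainder fails, one long when a partial
  plateau still lifts the next window over the floor).
* `min_window_fpkm = 0.15` — the per-window FPKM floor. Reads over a region
  are estimated from depth as `sum(depth)/read_length`, which keeps FPKM
  semantics without needing alignments; this is exact for uniformly spread
  reads and slightly biased at region edges otherwise.
* `min_tail_bp = 2000` — minimum tail length for an RT call.
* `max_tail_bp = 100000` — scan cap. Observed tails reach ~60 kb; the cap
  only prevents unbounded scans across gene deserts.

"Rolling window" is implemented as consecutive *non-overlapping* windows
(step = window size). This matches the screening behavior of
downstream-of-gene detection tools, makes the tail length an exact multiple
of the window size, and keeps the calling decision local: a single failing
window ends the tail. A final window truncated by the chromosome edge is
evaluated over its actual length.

Assumptions worth stating: coverage is unstranded (hence the UND filter);
the TTS is the downstream boundary of the gene-level span (union over
isoforms) rather than of a dominant isoform; and the scan does not stop when
it enters a same-strand expressed gene — that situation is reported as a
read-in flag instead, because stopping would silently truncate genuine
tails.

### UND filtering and consensus

Any RT call whose tail overlaps (>= 1 bp) *any* annotated opposite-strand
gene is reclassified UND: in an unstranded library that coverage is
indistinguishable from antisense transcription. All annotated genes are
used, not only expressed ones — a conservative choice, since a lowly
expressed antisense gene still confounds the signal. Across a tissue's
samples, a gene is UND if UND in any sample (ambiguity is a property of the
locus, not of sampling), RT if called RT in more than half the samples
(configurable), and NRT otherwise.

## Matched statistics

RT genes are fewer and differently expressed than NRT genes, so raw group
comparisons confound readthrough with expression. Every group statistic
therefore runs on expression-matched subsamples: draw `n` RT genes uniformly
without replacement, pair each with the unused NRT gene nearest in
`log2(FPKM + 1)` (linear matching over-weights high expressors; the log
scale is the package's choice where the procedure is silent), consume NRT
partners without replacement within a subsample, reset across permutations.
Ties resolve to the lexicographically smallest gene id, including across
runs of exactly equal expression, so results are reproducible to the byte
given the seed.

Comparisons use the two-sided Mann-Whitney test (exact for both groups at
most 20 and no ties, normal approximation with tie correction otherwise)
and Cohen's d with the pooled (n−1)-weighted standard deviation. The null
calibration checks in the tests confirm ~5% rejection at p < 0.05 when
outcomes are independent of group.

### Hexamer volcano

Each 6-mer in the TTS ± 500 bp flanks is scored as the log2 ratio of pooled
occurrence counts between the matched RT and NRT sides, with a pseudocount
of 1 (the bare ratio is undefined at zero counts). Significance is a
two-sided Welch t-test between the two per-permutation count vectors
("Student's t-test" with the conservative unequal-variance form), BH
corrected; volcano calls require FDR <= 0.001 and |score| >= 0.58. Counts
are pooled across permutations rather than averaged — the scores are
identical up to the pseudocount, and pooling keeps the score on the printed
count scale.

One property of this statistic matters for calibration: the pooled score
carries *finite-pool composition noise* of roughly
`sqrt(1/c_RT + 1/c_NRT)/ln 2` where `c` is the per-hexamer pool count. The
permutation t-test measures resampling noise, which shrinks with the number
of permutations, so with small pools the test will confidently flag
composition differences that are just pool-sampling accidents. With ~1000 bp
flanks, per-hexamer counts are ~0.24 per sequence; keeping 3 sigma of the
composition noise below the 0.58 score threshold requires pools of several
hundred sequences. The package's calibration checks therefore use 800 vs
1600 null sequences (per-hexamer pool counts in the hundreds, as in a
genome-scale gene set); at that size the volcano calls essentially nothing
under the null and recovers a planted 50% depletion of `CCGCGC` with a
score near −1.

### Intron retention

Introns are the complement of the merged exonic intervals within each gene
span, minus any exon of any other annotated gene (so a nested gene's exons
punch holes in its host's introns); pieces are indexed in transcription
order. Retention is quantified per intron as
`RPKM = (reads + 1) / ((length/1000) * (total_reads/1e6))` — the pseudocount
keeps values positive and comparable across introns with zero counts — on
the first two and last two introns of each gene. Introns of genes with fewer
than four introns carry two position labels (a single intron is both first
and last). The RT-vs-NRT contrast per position class uses matched values
pooled over permutations, flagged at Mann-Whitney p < 0.05 **and**
Cohen's d > 0.3; the conjunction matters because the pooled sample sizes are
large enough that p alone would flag trivial differences. The package's
planted-retention checks restrict this contrast to genes with at least four
introns, where the four classes are disjoint; shorter genes place one intron
in two classes, which genuinely mixes a last-intron effect into the other
classes rather than falsifying it.

### Genomic and epigenomic context

Chromosome enrichment is a per-chromosome two-sided Fisher exact test of
group membership against the expressed background, BH corrected, direction
by the sample odds ratio at FDR < 0.05. The background excludes the group by
default ("RT vs expressed" is ambiguous on this point; the inclusive variant
is a flag). Gene density assigns each gene to the chromosome or 1-Mb window
containing its 5' end. Downstream distance follows the
`bedtools closest -D a -iu -io -s` convention: nearest same-strand expressed
gene strictly downstream, overlaps ignored, distance = gap.

The epigenomic regions are 2-kb windows upstream (`TTSminus`) and downstream
(`TTSplus`) of the TTS and ±2 kb around the tail end (`RTend`); RT genes
with tails under 2500 bp are dropped from all three classes to limit
overlap between `TTSplus` and `RTend`. Chromatin-state fold enrichment over
a genome segmentation is the state's density inside the regions relative to
its genome-wide density.

### miRNA sponges

A seed pattern is the DNA reverse complement of mature miRNA positions 2–9;
sites are exact, possibly overlapping matches on the sense-strand sequence
of a tail or last exon (no G:U wobble, no 7mer variants — the minimal model
the seed-extraction defines). A sponge is an RT gene with at least 20 sites
for one miRNA in its tail. The tail-vs-last-exon contrast first averages
counts and densities per gene across miRNAs (and tissues), then compares
the per-gene vectors.

## The synthetic truth model

The generator's defaults are the package's reference study conditions: 500
genes on 4 chromosomes, both strands equally, geometric intron counts (mean
4), 3 samples, library size 2e7 at read length 100, log-normal gene
expression (meanlog 1.5, sdlog 0.8, ~3% of genes below the expressed
threshold), 40% of genes planted with tails uniform over 2–60 kb (the
observed tail range) at window FPKM 0.3–3, and 10% of planted-RT genes given
a single-exon antisense neighbor inside the tail to exercise the UND filter.

Deliberate design choices:

* **Intergenic gaps of 125–145 kb** so that two facing 60-kb tails can never
  merge; planted truth then maps one-to-one onto calls. Margins of 70 kb at
  chromosome ends let edge tails fit.
* **Tail plateaus at exactly the planted window FPKM**, constant across
  samples. Threshold recovery is then exact rather than probabilistic: a
  planted FPKM of 0.15 passes the `>=` rule, 0.149 does not.
* **Planted-RT hosts floored at FPKM 2**: readthrough is defined on
  expressed genes, so planting a tail on a gene that the expression filter
  would drop creates undefined truth.
* **Antisense neighbors are excluded from detector precision/recall
  scoring.** They are ambiguous by construction — their own downstream scan
  runs back across the host tail into the host gene, and the UND filter
  (correctly) removes them.
* **Truth status** is RT only when the planted tail meets both calling
  thresholds; sub-threshold tails are planted as NRT truth so threshold
  recovery is tested from both sides.
* **Hexamer depletion by binomial thinning** (each occurrence destroyed with
  probability 1 − factor): per-window integer targets would over-deplete
  windows holding a single occurrence. Planted miRNA sites are verified by
  re-scanning the edited region and regenerating on spurious collisions, so
  the recorded site count is exact.
* Coverage is a depth model (plateaus plus optional Poisson read noise,
  default off), not a read-level simulation: the detector consumes depth, so
  read-level realism adds nothing the tests could check.

What the generator does **not** emulate: positional decay of tail coverage,
expression covariance across genes and samples, mappability and GC coverage
bias, isoform-level termination differences, and stranded libraries. Passing
tests therefore demonstrate correctness of the calling and statistics on
their stated model, not robustness to alignment artifacts on real data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; GTF (1-based closed)
  converts at the boundary.
* `rt_ratio(0, 0)` is 0; Cohen's d with zero pooled SD is 0; identical
  groups give p = 1 rather than an error; zero-variance columns in the
  Welch test give p = 1 (equal means) or 0 (unequal).
* Read counts from depth round half-up.
* Aging fold changes use `(median + 1e-6)/(median + 1e-6)` so zero-median
  proportions are defined.
* Weighted coverage accumulation can produce values like −1e-15; the
  generator clamps them to zero.
* Seeds: every generator and every matching configuration takes an explicit
  integer seed and restores the caller's RNG state, so identical seeds give
  byte-identical outputs (GTF data lines, bedGraphs, truth tables,
  subsample tables).

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations for a
single CPU: threshold-recovery panel of 200 genes (tails 100 bp–10 kb,
window FPKM 0.01–1.0); end-to-end panel of 500 genes x 3 samples; null
Mann-Whitney calibration over 1000 runs; hexamer calibration with 800/1600
null sequences and 200 permutations of matched subsamples (the study-scale
1000 permutations with n = 500 remain the package defaults); retention
recovery on 300 genes with a planted 2x last-intron multiplier; aging
recovery with 20 samples per group and a planted 3x shift in 50 of 200
genes.

## Known limitations

Single-tissue orchestration in `run_pipeline()` (multi-tissue matrices are
assembled with `build_rt_ratio_matrix()` from per-tissue runs); no
isoform-aware TTS; exact seed matching only; no stranded-library mode beyond
skipping the UND filter; the intron table treats all annotated overlapping
exons as masking, regardless of biotype.
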