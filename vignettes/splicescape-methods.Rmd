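---
title: "Methods: splicing events, novel transcripts, and two-pool expression statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing events, novel transcripts, and two-pool expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

`splicescape` implements the downstream computational stages of a
two-condition, pooled-library RNA-seq comparison — the design used when
biological material is so scarce (for example single preimplantation
embryos) that each condition is sequenced as one pooled library with no
replicates.  This vignette explains the models behind each stage, the
tunable parameters, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## Coordinate conventions and data model

All coordinates in the package API are BED-style 0-based half-open
`[start, end)`.  GTF input and output (1-based closed) is converted at the
file boundary by `read_gtf()` / `write_gtf()`, which delegate parsing to
`rtracklayer`.  A transcript is an ordered exon chain on one chromosome and
strand; exons must be separated by at least 1 bp of intron, and violations
are rejected rather than repaired because they indicate a corrupt upstream
assembly.  Unstranded (`.`) transcripts are oriented as `+` — a
deterministic fallback is preferable to a failure, and the choice is
surfaced by a warning where orientation matters.

## Classifying simple alternative-splicing events

Only genes with two or more isoforms sharing a **single transcription start
site** (exact 5'-coordinate equality; no fuzz window, so selection is
reproducible) are classified.  Restricting to a shared TSS removes
alternative-first-exon structures by construction, which is why the simple
taxonomy has six categories rather than eight: exon skipping, alternative
5' splice site, alternative 3' splice site, intron retention, mutually
exclusive exons, and alternative last exon.

`classify_pair()` compares the exonic base coverage of the two chains.
Each maximal region where coverage differs (or linked pair of regions, for
mutually exclusive and alternative-last-exon structures) is matched against
one template:

* **exon skipping** — a run of whole internal exons of one isoform sitting
  inside a single intron of the other, with matching outer splice sites;
* **intron retention** — one isoform's single exon spans exactly the
  other's exon–intron–exon triple;
* **alternative 5'/3' splice site** — the two isoforms' introns agree at
  one boundary and differ at the other; donor versus acceptor assignment is
  strand-aware;
* **mutually exclusive exons** — one internal exon per isoform, disjoint,
  with both flanking splice sites shared;
* **alternative last exon** — disjoint terminal exons downstream of a
  shared final donor site.

A pair with exactly one matched local difference yields that simple event;
more than one difference, or a difference matching no template, yields a
single `complex` event.  For genes with three or more isoforms,
`classify_gene()` takes the union over all unordered pairs and
de-duplicates by `(category, locus)`, so an event observed in several pairs
is counted once; how pairwise events should be aggregated into per-gene
counts is genuinely open, and this rule is stated in the report metadata.

Because the classifier is strand-aware, mirroring all coordinates *and*
flipping the strand preserves every category (the transcript-relative
order of boundaries is unchanged); mirroring *without* a strand flip is
the transformation that exchanges donor-side and acceptor-side shifts.
The test-suite verifies the classifier against an independent whole-chain
oracle that re-derives each category by reconstruction (remove a run of
internal exons, fill an intron, shift one boundary, swap one exon),
exhaustively over an 8-point boundary grid and on 10,000 seeded pairs from
a 12-point grid.

## Novel transcribed units

Assembled transcripts whose span overlaps no annotated gene span are
clustered by single-linkage exonic overlap into candidate units (strand is
ignored by default, with a `stranded` override; both the intergenic
distance and the EST comparison are strand-ignored for the same reason —
external evidence rarely has reliable strand for unannotated loci).  Units
containing no multi-exonic transcript are dropped.  Acceptance requires,
verbatim in boundary semantics:

| criterion | rule |
|---|---|
| distance | ≥ 1000 bp from the nearest gene span (inclusive) |
| length | merged exonic length ≥ 250 bp (inclusive) |
| coverage | mean fragment coverage ≥ 5 (inclusive) |
| repeats | < 50% of exonic bases repeat-masked (strict) |
| junctions | every intron supported by ≥ 2 junction alignments (inclusive) |

All five criteria are applied in `filter_novel_tus()`, and every rejected
unit lists every violated criterion — keeping the full rejection accounting
in one place.  "Gene boundaries" means the genomic span of each annotated
gene (first exon start to last exon end), the conservative reading.
External EST support (≥ 5 ESTs jointly covering strictly more than 50% of
exonic bases) is scored separately from acceptance, as supporting evidence
rather than a filter.  Coverage is consumed as a precomputed per-transcript
mean — read alignment is out of scope — and a unit's coverage is the
exonic-length-weighted mean over its members.

## Quantification

FPKM is `count * 1e9 / (length * library_size)` with effective length the
sum of exon lengths (fragment-length correction belongs to the upstream
assembler).  Upper-quartile normalization computes, per sample, the 75th
percentile — linear interpolation between order statistics, R's default
quantile type 7 — of the counts of features nonzero in that sample, and
rescales by the geometric mean of the factors so the table keeps its
overall scale.  Gene-level condition abundances sum isoform FPKMs (FPKM is
additive over isoforms) after normalization; normalization matters in this
design because a handful of strongly differential genes otherwise shifts
the composition of one library and biases every null gene's apparent fold
change.  A gene is called expressed at FPKM ≥ 0.5 by default (the
threshold is configurable and logged; exclusivity calls are threshold
calls, since "expressed in exactly one condition" is otherwise undefined at
finite depth).  Oriented fold changes are binned right-closed into
(1,5], (5,10], (10,15], (15,20], (20,∞).

## Differential expression and differential isoform usage

With one pooled library per condition there is no replicate variance to
estimate, so the expression test conditions on the total count of a gene:
under the null, the condition-A count is binomial with proportion
`size_A / (size_A + size_B)`.  Effective sizes may be upper-quartile
scaled (the pipeline does this).  The reported statistic is a log2 fold
change with a depth-scaled pseudocount `0.5 / min(size)`.

Differential isoform usage is measured by the Jensen–Shannon distance —
the square root of the Jensen–Shannon divergence with base-2 logarithms —
between the two conditions' isoform-proportion vectors; it is a bounded
metric, 0 for identical usage and 1 for disjoint isoform support.  Instead
of an asymptotic variance model, the null is a multinomial parametric
bootstrap: both conditions' counts are pooled into one proportion vector
and `n_boot` pairs of multinomial samples are drawn at the observed
per-condition depths.  The p-value uses the add-one convention
`(1 + #[null ≥ observed]) / (n_boot + 1)`, which cannot be zero and is
deterministic given the seed (per-gene seeds are derived from the master
seed and the gene's rank in sorted order, so results do not depend on
input order).  Multiple testing uses Benjamini–Hochberg throughout, with
FDR < 0.05 for expression and splicing and FDR < 0.01 for enrichment as
defaults.

## Length-bias-corrected enrichment

Long genes yield more fragments and are easier to call differentially
expressed, so a category of long genes is spuriously enriched under the
central hypergeometric model.  `fit_pwf()` estimates each gene's
length-driven DE propensity by isotonic regression of the DE indicator on
gene length: ties are aggregated first (the weight must be a function of
length alone), neighbouring lengths are pre-binned to roughly 100 genes,
and a weighted pool-adjacent-violators fit is applied.  The pre-binning
step matters: an unbinned isotonic fit develops spikes at the extreme
lengths under the null, inflating the weight spread.  Isotonic regression
was chosen over a monotone spline because it is parameter-free, exactly
monotone, and mean-preserving (the fitted weights average to the observed
DE fraction).

Each category is then tested under a Wallenius noncentral hypergeometric
null with a single odds parameter, the ratio of mean weights inside versus
outside the category.  The upper tail is evaluated exactly by the
sequential-draw recursion (draw `n` genes one at a time without
replacement, category genes weighted by the odds), which is O(n·m1) and
exact for the DE-set sizes this package targets (up to a few thousand).
At odds 1 the distribution reduces to the central hypergeometric, which
the tests verify against `phyper` to 1e-9.  Only over-representation is
tested by default, matching how enriched-pathway results are reported.
The gene→category map is tested as given — GO ancestor propagation is out
of scope and noted in the output metadata.

## qPCR validation statistics

Reference-gene stability follows the geNorm logic: for candidates *j*, *k*
the pairwise variation `V(j,k)` is the standard deviation (sample SD, n−1
denominator, the reference method's convention) across samples of
`Ct_k − Ct_j` (equivalently of the log2 expression ratio, since expression
is `2^−Ct`), and `M_j` is the mean of `V(j,k)` over the other candidates.
M is invariant to per-sample loading shifts, which cancel in the ratios.
The candidate with the smallest M becomes the internal control; ties break
lexicographically with a warning.  Relative expression uses `2^−ΔΔCt` with
ΔCt averaged within condition before differencing (per-sample folds are
also emitted, since averaging before or after is a genuine choice).

## The synthetic-data generator

`sim_config()` / `simulate_scenario()` emulate the full input bundle on one
linear pseudo-chromosome, with all randomness flowing from one seed through
named per-file substreams (byte-identical reruns).  Genes are spaced
≥ 5000 bp apart so the 1000 bp intergenic rule is never ambiguous.  Default
study conditions: 20 two-isoform genes per event category (each pair
differing by exactly one planted event), 20 true novel units satisfying all
five criteria, 25 decoys each violating exactly one, one pooled library per
condition, a planted fold-change spectrum {3, 7, 12, 17, 25} in both
directions spanning every reporting bin, and a usage-shift effect that
moves isoform proportions from `(p, 1−p)` to the renormalized
`(p + shift·(1−p), 1−p)`.

Counts are multinomial at the configured library depth — the pooled
single-library design has no replicate variance to emulate, so no
overdispersion is added.  Baseline gene expression is log-normal (sdlog
0.3).  For the calibration and power analyses the tested problem sizes are
504 two-isoform genes at roughly 1e4 fragments per gene under the null and
1e5 per gene for the power run (library depth scales with the number of
features so that per-gene depth, the quantity that drives the test, is at
the stated level).

The qPCR generator plants one stable control (noise sd 0.05 cycles around
the per-sample loading trace) and two unstable candidates with iid shifts
(sd 0.5 cycles) *plus opposite condition-level regulation* (±0.75 cycles).
The condition effect is essential, not decorative: with iid shifts alone,
`sd(u1−u2) / sd(u1−stable) = √2` independent of the noise scale, and at 10
samples that separation leaves the stable gene losing the M ranking in
roughly 10% of replicates.  A treatment-responsive candidate — the classic
failure mode geNorm screens for — separates the M values decisively.

What the generator does **not** emulate: positional read bias and 3'
amplification bias, sequencing error, overdispersion across biological
replicates, multi-chromosome genomes, overlapping or nested genes, and
incomplete transcript assembly.  Passing tests therefore demonstrate the
correctness of the algorithms under clean planted truth, not robustness to
assembler artifacts on real libraries.

## Problem sizes and numerical choices

The test-suite and the acceptance script use: the default 6×20 scenario
for recovery; 504 genes × 999 bootstrap resamples for calibration and
power; 2000 genes × 400 null categories (size 150, sampled with
probability proportional to length, DE propensity logistic in log-length
with slope 0.8 per SD) for the enrichment calibration contrast; 200 seeded
replicates for geNorm recovery.  Probability-vector inputs to
`js_distance` must sum to 1 within 1e-9; `0·log 0` is taken as 0; the
Wallenius recursion guards impossible urn states explicitly.  All
thresholds and every seed appear in the pipeline's `report.json`, and
rerunning `run_all()` with the same configuration reproduces the report
byte for byte.
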