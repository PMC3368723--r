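# splicescape

Downstream statistics for two-condition, pooled-library RNA-seq
comparisons — the design used when biological material is too scarce for
replicates, such as comparing pools of in vivo– and in vitro–derived
preimplantation embryos.  Given a reference annotation, an assembled
transcriptome, fragment-count tables and supporting evidence files,
`splicescape` provides:

* **Novel transcribed-unit discovery** — intergenic multi-exonic units
  screened against five criteria (distance ≥ 1000 bp from gene boundaries,
  exonic length ≥ 250 bp, mean coverage ≥ 5, repeat overlap < 50%,
  junction support ≥ 2), with EST support (≥ 5 ESTs covering > 50%)
  scored separately.
* **Alternative-splicing classification** — isoform pairs of single-TSS
  multi-isoform genes labelled as one of six simple event categories
  (exon skipping, alternative 5′/3′ splice site, intron retention,
  mutually exclusive exons, alternative last exon) or `complex`.
* **Differential isoform usage** — the Jensen–Shannon distance
  √(½KL(p‖m) + ½KL(q‖m)), m = (p+q)/2, between conditions'
  isoform-proportion vectors, tested by a pooled multinomial bootstrap;
  Benjamini–Hochberg FDR control.
* **Expression** — FPKM (`count·10⁹ / (length·library_size)`),
  upper-quartile normalization, exclusive-expression calls, fold-change
  binning, and a no-replicate binomial test of condition counts.
* **Length-bias-corrected enrichment** — an isotonic probability
  weighting function of DE propensity versus gene length, and exact
  Wallenius noncentral hypergeometric category tests (reducing to
  one-sided Fisher at uniform weights).
* **qPCR validation statistics** — geNorm stability values
  M_j = mean_k SD(Ct_k − Ct_j) for reference-gene selection, and 2^−ΔΔCt
  relative expression.
* **A seeded synthetic-data generator** that plants ground truth for every
  stage (event categories, true/decoy novel units, usage shifts, fold
  changes, a stable qPCR control) and writes the full input bundle.

## Worked example

Simulate a small scenario (3 event genes per category, 5 true novel units,
10 decoys) and run the full pipeline:

```r
library(splicescape)
cfg <- sim_config(seed = 5, events_per_category = 3, n_novel_tu = 5,
                  n_decoy_tu = 10, depth = 2e5)
simulate_scenario(cfg, "scenario")
rc <- run_config(
  reference_gtf = "scenario/reference.gtf",
  assembled_gtf = "scenario/assembled.gtf",
  counts_tsv    = "scenario/counts.tsv",
  repeats_bed   = "scenario/repeats.bed",
  ests_bed      = "scenario/ests.bed",
  junctions_tsv = "scenario/junctions.tsv",
  coverage_tsv  = "scenario/coverage.tsv",
  gene2cat_tsv  = "scenario/go.tsv",
  lengths_tsv   = "scenario/lengths.tsv",
  ct_tsv        = "scenario/ct.tsv",
  ct_candidates = c("CTRLSTABLE", "CTRLU1", "CTRLU2"),
  ct_targets    = paste0("TGT", 1:4),
  n_boot = 199, seed = 7)
rep <- run_all(rc, "out")
rep$splicing$event_summary
#>             category n_events n_genes
#> 1      exon_skipping        3       3
#> 2         alt_5prime        3       3
#> 3         alt_3prime        3       3
#> 4   intron_retention        3       3
#> 5 mutually_exclusive        3       3
#> 6      alt_last_exon        3       3
#> 7            complex        0       0
rep$expression$fold_change_bins
#>   <=5 5-10 10-15 15-20 >20
#> A   1    1     1     1   1
#> B   1    1     1     1   1
round(rep$qpcr$folds$fold, 2)
#> [1] 8.19 2.07 0.49 1.03
```

All 15 candidate units are recovered: the 5 planted true units are
accepted, each of the 10 decoys is rejected for exactly its planted
criterion; the 10 planted fold changes land one per bin per direction; the
geNorm stage selects the planted stable control and the 2^−ΔΔCt estimates
(8.19, 2.07, 0.49, 1.03) recover the planted folds (8, 2, 0.5, 1).
`out/report.json` collects every count, threshold and seed, and is
byte-identical across reruns of the same configuration.

A thin command-line wrapper is installed with the package
(`system.file("scripts/splicescape.R", package = "splicescape")`) with
subcommands `validate`, `simulate` and `run`.

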