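# shared fixture builders

tx <- function(id, starts, ends, strand = "+", gene = "G1", chrom = "chr1")
  transcript_model(id, gene, chrom, starts, ends, strand)

# exon chains from sorted grid points: (p1,p2),(p3,p4),...
chain_from_points <- function(pts) {
  k <- length(pts) / 2
  cbind(start = pts[2 * seq_len(k) - 1], end = pts[2 * seq_len(k)])
}

# all exon chains over `grid` whose first exon starts at grid[1], <= 4 exons
all_chains_from_grid <- function(grid) {
  rest <- grid[-1]
  out <- list()
  for (k in 1:4) {
    need <- 2 * k - 1
    if (need > length(rest)) break
    combs <- combn(rest, need)
    for (j in seq_len(ncol(combs)))
      out[[length(out) + 1L]] <- chain_from_points(c(grid[1], combs[, j]))
  }
  out
}

small_scenario <- function(seed = 5, depth = 2e5) {
  cfg <- sim_config(seed = seed, events_per_category = 3L, n_novel_tu = 5L,
                    n_decoy_tu = 10L, depth = depth)
  d <- withr::local_tempdir(.local_envir = parent.frame())
  simulate_scenario(cfg, d)
  list(cfg = cfg, dir = d)
}

scenario_run_config <- function(d, n_boot = 199L, seed = 7L) {
  run_config(
    reference_gtf = file.path(d, "reference.gtf"),
    assembled_gtf = file.path(d, "assembled.gtf"),
    counts_tsv = file.path(d, "counts.tsv"),
    repeats_bed = file.path(d, "repeats.bed"),
    ests_bed = file.path(d, "ests.bed"),
    junctions_tsv = file.path(d, "junctions.tsv"),
    coverage_tsv = file.path(d, "coverage.tsv"),
    gene2cat_tsv = file.path(d, "go.tsv"),
    lengths_tsv = file.path(d, "lengths.tsv"),
    ct_tsv = file.path(d, "ct.tsv"),
    ct_candidates = c("CTRLSTABLE", "CTRLU1", "CTRLU2"),
    ct_targets = paste0("TGT", 1:4),
    n_boot = n_boot, seed = seed)
}
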