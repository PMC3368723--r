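test_that("the same seed reproduces every generated file byte-for-byte", {
  cfg <- sim_config(seed = 77, events_per_category = 2L, n_novel_tu = 3L,
                    n_decoy_tu = 5L, depth = 5e4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_scenario(cfg, d1)
  simulate_scenario(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("planted annotation has one two-isoform gene per category per slot", {
  cfg <- sim_config(seed = 3, events_per_category = 1L, n_novel_tu = 0L,
                    n_decoy_tu = 0L, n_genes = 6L)
  an <- generate_annotation(cfg)
  genes <- select_single_tss_genes(group_genes(an$assembled))
  expect_length(genes, 6L)
  ev <- do.call(rbind, lapply(genes, classify_gene))
  expect_setequal(ev$category, EVENT_CATEGORIES[1:6])
  # with no novel units, every assembled transcript belongs to a reference gene
  expect_setequal(unique(vapply(an$assembled, function(t) t$gene_id, "")),
                  vapply(an$reference, function(t) t$gene_id, ""))
})

test_that("abundance columns sum exactly to the library depth", {
  cfg <- sim_config(seed = 8, events_per_category = 2L, n_novel_tu = 2L,
                    n_decoy_tu = 0L, depth = 12345, n_samples_per_condition = 2L)
  an <- generate_annotation(cfg)
  cnt <- suppressWarnings(generate_abundances(cfg, an))
  expect_equal(unname(colSums(cnt$counts)), rep(12345, 4))
  expect_equal(cnt$condition, c("A", "A", "B", "B"))
})

test_that("a zero-effect configuration leaves conditions exchangeable in expectation", {
  cfg <- sim_config(seed = 14, events_per_category = 2L, n_novel_tu = 0L,
                    n_decoy_tu = 0L, usage_shift = 0,
                    de_fold_changes = numeric(0), depth = 5e5)
  an <- generate_annotation(cfg)
  cnt <- suppressWarnings(generate_abundances(cfg, an))
  ca <- cnt$counts[, 1]; cb <- cnt$counts[, 2]
  # per-feature proportions match within multinomial noise (~4 sd)
  p <- (ca + cb) / sum(ca + cb)
  se <- sqrt(p * (1 - p) * 2 / sum(ca))
  expect_true(all(abs(ca / sum(ca) - cb / sum(cb)) < 4 * se + 1e-9))
})

test_that("a planted fold change is recovered from condition count ratios", {
  cfg <- sim_config(seed = 4, n_genes = 1000L, events_per_category = 2L,
                    n_novel_tu = 0L, n_decoy_tu = 0L, usage_shift = 0,
                    de_fold_changes = c(20), depth = 1e6)
  an <- generate_annotation(cfg)
  cnt <- suppressWarnings(generate_abundances(cfg, an))
  g <- names(an$truth$de_fold_changes)
  i <- which(cnt$gene_id == g)
  ratio <- sum(cnt$counts[i, 2]) / sum(cnt$counts[i, 1])
  expect_equal(ratio, 20, tolerance = 0.05)
})

test_that("evidence files encode each decoy's single planted violation", {
  cfg <- sim_config(seed = 6, events_per_category = 2L, n_novel_tu = 4L,
                    n_decoy_tu = 10L)
  an <- generate_annotation(cfg)
  ev <- generate_evidence(cfg, an)
  cov_decoys <- names(an$truth$decoy_failure_reason)[
    an$truth$decoy_failure_reason == "coverage"]
  expect_true(all(ev$coverage$mean_coverage[
    ev$coverage$transcript_id %in% cov_decoys] < 5))
  other <- setdiff(ev$coverage$transcript_id, cov_decoys)
  expect_true(all(ev$coverage$mean_coverage[
    ev$coverage$transcript_id %in% other] >= 5))
  # every true unit's introns have support >= 2
  true_tx <- an$truth$true_novel_tu_ids
  asm_ids <- vapply(an$assembled, function(t) t$transcript_id, "")
  for (id in true_tx) {
    intr <- derive_introns(an$assembled[[which(asm_ids == id)]])
    for (r in seq_len(nrow(intr))) {
      hit <- ev$junctions$donor_end == intr[r, "start"] &
        ev$junctions$acceptor_start == intr[r, "end"]
      expect_true(any(ev$junctions$support_count[hit] >= 2))
    }
  }
})

test_that("noise-free Ct arithmetic: an 8-fold target gives mean ddCt of -3", {
  cfg <- sim_config(seed = 10, target_ct_folds = c(8, 2, 0.5, 1))
  ctt <- generate_ct_table(cfg, sd_stable = 0, sd_unstable = 0, sd_target = 0)
  r <- ddct_fold_change(ctt, "TGT1", "CTRLSTABLE", "A", "B")
  expect_equal(r$ddct, -3)
  expect_equal(r$fold, 8)
  # the stable control co-varies perfectly with loading: M contribution 0
  # against a hypothetical copy, i.e. its Ct minus loading trace is constant
  expect_lt(sd(ctt$ct["CTRLSTABLE", ] - ctt$ct["TGT4", ]), 1e-12)
})
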