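# a minimal hand-built landscape: one reference gene on chr1 at [1000, 2000)
ref_gene <- function() list(tx("r1", c(1000, 1600), c(1400, 2000), gene = "REF"))

unit_with <- function(dist = 2000, len = 300, cov = 6.1, rep_frac = 0.1, junc = 3) {
  u <- list(unit_id = "u1", chrom = "chr1", strand = "+",
            transcripts = list(), exonic_span = cbind(start = 0, end = len),
            total_length = len, n_exons = 2L,
            introns = cbind(start = 10, end = 20),
            distance_to_nearest_gene = dist, mean_coverage = cov,
            repeat_fraction = rep_frac, min_junction_support = junc,
            est_count = 0L, est_coverage_fraction = 0, supported = FALSE)
  u
}

test_that("acceptance applies the five criteria with verbatim boundary semantics", {
  ok <- filter_novel_tus(list(unit_with()))
  expect_true(ok$table$accepted)
  expect_equal(ok$table$rejection_reasons, "")

  # boundaries: >=1000 inclusive, >=250 inclusive, >=5 inclusive, <0.5
  # strict, >=2 inclusive
  expect_true(filter_novel_tus(list(unit_with(dist = 1000)))$table$accepted)
  expect_false(filter_novel_tus(list(unit_with(dist = 999)))$table$accepted)
  expect_true(filter_novel_tus(list(unit_with(len = 250)))$table$accepted)
  expect_false(filter_novel_tus(list(unit_with(cov = 4.99)))$table$accepted)
  expect_equal(filter_novel_tus(list(unit_with(cov = 4.99)))$table$rejection_reasons,
               "coverage")
  expect_false(filter_novel_tus(list(unit_with(rep_frac = 0.5)))$table$accepted)
  expect_equal(filter_novel_tus(list(unit_with(rep_frac = 0.5)))$table$rejection_reasons,
               "repeat_fraction")
  expect_true(filter_novel_tus(list(unit_with(rep_frac = 0.499)))$table$accepted)
  expect_false(filter_novel_tus(list(unit_with(junc = 1)))$table$accepted)

  multi <- filter_novel_tus(list(unit_with(dist = 10, cov = 1)))
  expect_equal(multi$table$rejection_reasons, "distance,coverage")

  bad <- unit_with(); bad$mean_coverage <- NA_real_
  expect_error(filter_novel_tus(list(bad)), "mean_coverage")
})

test_that("acceptance is monotone in each criterion", {
  base <- unit_with(dist = 1500, len = 300, cov = 6, rep_frac = 0.3, junc = 2)
  expect_true(filter_novel_tus(list(base))$table$accepted)
  better <- list(
    unit_with(dist = 1e6, len = 300, cov = 6, rep_frac = 0.3, junc = 2),
    unit_with(dist = 1500, len = 300, cov = 100, rep_frac = 0.3, junc = 2),
    unit_with(dist = 1500, len = 300, cov = 6, rep_frac = 0, junc = 2),
    unit_with(dist = 1500, len = 300, cov = 6, rep_frac = 0.3, junc = 50))
  for (u in better) expect_true(filter_novel_tus(list(u))$table$accepted)
})

test_that("candidate clustering keeps intergenic multi-exonic units only", {
  asm <- c(ref_gene(), list(
    tx("far", c(5000, 5500), c(5200, 5700)),       # 3000 bp away: candidate
    tx("near", c(2500, 2700), c(2600, 2800)),      # 500 bp away: candidate, fails distance
    tx("single", 9000, 9400),                      # single exon: dropped
    tx("overlap", c(1500, 2500), c(1700, 2600))))  # overlaps the gene: dropped
  cand <- candidate_units(asm, ref_gene())
  ids <- unlist(lapply(cand, function(u)
    vapply(u$transcripts, function(t) t$transcript_id, "")))
  expect_setequal(ids, c("far", "near"))
  d <- vapply(cand, `[[`, numeric(1), "distance_to_nearest_gene")
  expect_setequal(d, c(3000, 500))
})

test_that("overlapping transcripts cluster into one unit regardless of order", {
  t1 <- tx("t1", c(5000, 5500), c(5200, 5700))
  t2 <- tx("t2", c(5100, 5500), c(5200, 5800))
  t3 <- tx("t3", c(9000, 9300), c(9100, 9400))
  for (perm in list(list(t1, t2, t3), list(t3, t2, t1), list(t2, t3, t1))) {
    cand <- candidate_units(c(ref_gene(), perm), ref_gene())
    expect_length(cand, 2L)
    sizes <- sort(unname(vapply(cand, function(u) length(u$transcripts), 1L)))
    expect_equal(sizes, c(1L, 2L))
    expect_equal(vapply(cand, `[[`, "", "unit_id"),
                 sort(vapply(cand, `[[`, "", "unit_id")))
  }
})

test_that("evidence annotation computes repeat fraction, junction support, coverage", {
  cand <- candidate_units(c(ref_gene(), list(tx("far", c(5000, 5500), c(5200, 5700)))),
                          ref_gene())
  repeats <- data.frame(chrom = "chr1", start = 5000, end = 5100)  # 100 of 400 bases
  junctions <- data.frame(chrom = "chr1", donor_end = 5200,
                          acceptor_start = 5500, strand = "+", support_count = 2)
  coverage <- data.frame(transcript_id = "far", mean_coverage = 7.5)
  u <- annotate_evidence(cand, repeats, junctions, coverage)[[1]]
  expect_equal(u$repeat_fraction, 0.25)
  expect_equal(u$min_junction_support, 2)
  expect_equal(u$mean_coverage, 7.5)

  # an intron absent from the junction table has support 0
  u0 <- annotate_evidence(cand, repeats, junctions[0, ], coverage)[[1]]
  expect_equal(u0$min_junction_support, 0)

  expect_error(annotate_evidence(cand, repeats, junctions,
                                 data.frame(transcript_id = "other",
                                            mean_coverage = 1)),
               "coverage missing")
})

test_that("EST support needs >= 5 ESTs and strictly > 50% joint coverage", {
  cand <- candidate_units(c(ref_gene(), list(tx("far", c(5000, 5500), c(5200, 5700)))),
                          ref_gene())
  mk_ests <- function(n, s, e) {
    df <- data.frame(chrom = rep("chr1", n), start = s, end = e,
                     name = paste0("e", seq_len(n)), strand = "+")
    df$blocks <- lapply(seq_len(n), function(i) cbind(start = s, end = e))
    df
  }
  # unit exonic bases: [5000,5200) + [5500,5700) = 400; [5000,5200)+[5500,5540) = 240/400 = 60%
  five_60 <- mk_ests(5, 5000, 5540)
  u <- est_support(cand, five_60)[[1]]
  expect_equal(u$est_count, 5L)
  expect_equal(u$est_coverage_fraction, 0.6)
  expect_true(u$supported)

  four_100 <- mk_ests(4, 5000, 5700)
  expect_false(est_support(cand, four_100)[[1]]$supported)

  six_50 <- mk_ests(6, 5000, 5200)   # exactly 50%
  u50 <- est_support(cand, six_50)[[1]]
  expect_equal(u50$est_coverage_fraction, 0.5)
  expect_false(u50$supported)
})
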