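test_that("GTF coordinates convert to 0-based half-open and round-trip", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    f)
  txs <- read_gtf(f)
  expect_length(txs, 1L)
  expect_equal(unname(txs[[1]]$exons[, "start"]), c(0, 200))
  expect_equal(unname(txs[[1]]$exons[, "end"]), c(100, 300))

  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(txs, f2)
  txs2 <- read_gtf(f2)
  expect_equal(txs2[[1]]$exons, txs[[1]]$exons)
  expect_equal(txs2[[1]]$transcript_id, "t1")
  expect_equal(txs2[[1]]$gene_id, "g1")
})

test_that("empty GTF gives an empty list; shared gene_id keeps two models", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f)
  expect_equal(read_gtf(f), list())

  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t51\t150\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'),
    f2)
  txs <- read_gtf(f2)
  expect_length(txs, 2L)
  expect_equal(vapply(txs, function(t) t$gene_id, ""), c("g1", "g1"))
  expect_equal(sort(vapply(txs, function(t) t$transcript_id, "")), c("t1", "t2"))
})

test_that("overlapping or adjacent exons are rejected, not repaired", {
  expect_error(tx("t", c(0, 50), c(60, 100)), "overlapping or adjacent")
  expect_error(tx("t", c(0, 100), c(100, 200)), "overlapping or adjacent")
  expect_error(tx("t", 10, 10), "end <= start")
})

test_that("derive_introns returns the gaps between consecutive exons", {
  expect_equal(unname(derive_introns(tx("t", c(0, 200), c(100, 300)))),
               cbind(100, 200), ignore_attr = TRUE)
  expect_equal(nrow(derive_introns(tx("t", 0, 100))), 0L)
  got <- derive_introns(tx("t", c(0, 20, 40), c(10, 30, 50)))
  expect_equal(unname(got[, "start"]), c(10, 30))
  expect_equal(unname(got[, "end"]), c(20, 40))
})

test_that("tss_position is strand-aware and reflection-antisymmetric", {
  expect_equal(tss_position(tx("t", c(0, 200), c(100, 300), "+")), 0)
  expect_equal(tss_position(tx("t", c(0, 200), c(100, 300), "-")), 300)
  expect_equal(tss_position(tx("t", 5, 50, "+")), 5)
  # reflecting about C and flipping strand maps tss to C - tss
  C <- 1000
  for (i in 1:20) {
    set.seed(i)
    pts <- sort(sample(0:400, 2 * sample(1:4, 1)))
    ch <- chain_from_points(pts)
    t_plus <- tx("t", ch[, "start"], ch[, "end"], "+")
    t_minus <- tx("t", C - ch[, "end"], C - ch[, "start"], "-")
    expect_equal(tss_position(t_minus), C - tss_position(t_plus))
  }
})

test_that("exon lengths plus intron lengths equal the genomic span", {
  for (i in 1:30) {
    set.seed(100 + i)
    pts <- sort(sample(0:500, 2 * sample(1:4, 1)))
    ch <- chain_from_points(pts)
    t <- tx("t", ch[, "start"], ch[, "end"])
    intr <- derive_introns(t)
    span <- unname(t$exons[nrow(t$exons), "end"] - t$exons[1, "start"])
    expect_equal(sum(t$exons[, "end"] - t$exons[, "start"]) +
                   sum(intr[, "end"] - intr[, "start"]), span)
  }
})

test_that("read_bed handles BED3 and expands BED12 blocks", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", f)
  b <- read_bed(f)
  expect_equal(b$start, 0)
  expect_equal(b$end, 100)
  expect_equal(unname(b$blocks[[1]]), cbind(0, 100), ignore_attr = TRUE)

  f12 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t210\test1\t0\t+\t10\t210\t0\t2\t50,50,\t0,150,", f12)
  b12 <- read_bed(f12)
  blk <- b12$blocks[[1]]
  expect_equal(unname(blk[, "start"]), c(10, 160))
  expect_equal(unname(blk[, "end"]), c(60, 210))

  fe <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), fe)
  expect_equal(nrow(read_bed(fe)), 0L)
})
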