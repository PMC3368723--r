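cat_of <- function(a, b) {
  ev <- classify_pair(a, b)
  if (nrow(ev) == 0L) "none" else ev$category
}

test_that("single-TSS multi-isoform selection uses exact coordinate equality", {
  g <- list(
    two_same = list(tx("a", c(0, 200), c(100, 300)), tx("b", 0, 300)),
    single = list(tx("c", 0, 100)),
    off_by_one = list(tx("d", c(1, 200), c(100, 300)), tx("e", 0, 300)))
  kept <- select_single_tss_genes(g)
  expect_equal(names(kept), "two_same")
})

test_that("each simple event category is recognized with its locus", {
  ev <- classify_pair(tx("a", c(0, 200, 400), c(100, 300, 500)),
                      tx("b", c(0, 400), c(100, 500)))
  expect_equal(ev$category, "exon_skipping")
  expect_equal(c(ev$locus_start, ev$locus_end), c(200, 300))

  ev <- classify_pair(tx("a", c(0, 200), c(100, 300)), tx("b", 0, 300))
  expect_equal(ev$category, "intron_retention")
  expect_equal(c(ev$locus_start, ev$locus_end), c(100, 200))

  ev <- classify_pair(tx("a", c(0, 200), c(100, 300)),
                      tx("b", c(0, 200), c(120, 300)))
  expect_equal(ev$category, "alt_5prime")
  expect_equal(c(ev$locus_start, ev$locus_end), c(100, 120))

  expect_equal(cat_of(tx("a", c(0, 200, 600), c(100, 300, 700)),
                      tx("b", c(0, 400, 600), c(100, 500, 700))),
               "mutually_exclusive")
  expect_equal(cat_of(tx("a", c(0, 200), c(100, 300)),
                      tx("b", c(0, 400), c(100, 500))),
               "alt_last_exon")
  expect_equal(cat_of(tx("a", c(0, 200, 400), c(100, 300, 500)),
                      tx("b", c(0, 400), c(120, 500))),
               "complex")
  expect_equal(cat_of(tx("a", c(0, 200), c(100, 300)),
                      tx("b", c(0, 200), c(100, 300))),
               "none")
})

test_that("classification is symmetric in the two isoforms", {
  pairs <- list(
    list(tx("a", c(0, 200, 400), c(100, 300, 500)), tx("b", c(0, 400), c(100, 500))),
    list(tx("a", c(0, 200), c(100, 300)), tx("b", 0, 300)),
    list(tx("a", c(0, 200), c(100, 300)), tx("b", c(0, 200), c(120, 300))),
    list(tx("a", c(0, 200), c(100, 300)), tx("b", c(0, 400), c(100, 500))))
  for (p in pairs) {
    e1 <- classify_pair(p[[1]], p[[2]])
    e2 <- classify_pair(p[[2]], p[[1]])
    expect_equal(e1$category, e2$category)
    expect_equal(e1$locus_start, e2$locus_start)
    expect_equal(e1$locus_end, e2$locus_end)
  }
})

test_that("coordinate translation shifts loci and preserves categories", {
  a <- tx("a", c(0, 200, 400), c(100, 300, 500))
  b <- tx("b", c(0, 400), c(100, 500))
  for (shift in c(17, 1000)) {
    a2 <- tx("a", a$exons[, 1] + shift, a$exons[, 2] + shift)
    b2 <- tx("b", b$exons[, 1] + shift, b$exons[, 2] + shift)
    e <- classify_pair(a2, b2)
    expect_equal(e$category, "exon_skipping")
    expect_equal(e$locus_start, 200 + shift)
  }
})

test_that("mirroring with a strand flip preserves categories; without a flip it swaps alt 5'/3'", {
  mirror <- function(t, C, strand) tx(t$transcript_id, C - t$exons[, "end"],
                                      C - t$exons[, "start"], strand)
  # strand-aware: mirror + flip keeps transcript-relative order, so every
  # category is preserved
  cases <- list(
    list(tx("a", c(0, 200, 400), c(100, 300, 500)), tx("b", c(0, 400), c(100, 500)), "exon_skipping"),
    list(tx("a", c(0, 200), c(100, 300)), tx("b", 0, 300), "intron_retention"),
    list(tx("a", c(0, 200), c(100, 300)), tx("b", c(0, 200), c(120, 300)), "alt_5prime"),
    list(tx("a", c(0, 200), c(100, 300)), tx("b", c(0, 400), c(100, 500)), "alt_last_exon"))
  for (cs in cases) {
    am <- mirror(cs[[1]], 1000, "-"); bm <- mirror(cs[[2]], 1000, "-")
    expect_equal(cat_of(am, bm), cs[[3]])
  }
  # mirror without flip swaps donor- and acceptor-side shifts (requires the
  # pair to share both ends so the mirrored pair still shares its TSS)
  a <- tx("a", c(0, 200), c(100, 300))
  b <- tx("b", c(0, 200), c(120, 300))
  expect_equal(cat_of(a, b), "alt_5prime")
  am <- mirror(a, 300, "+"); bm <- mirror(b, 300, "+")
  expect_equal(cat_of(am, bm), "alt_3prime")
})

test_that("a three-isoform gene aggregates pairwise events with de-duplication", {
  ref <- tx("ref", c(0, 200, 400, 600), c(100, 300, 500, 700))
  skip <- tx("skip", c(0, 400, 600), c(100, 500, 700))          # drops exon 2
  ret <- tx("ret", c(0, 200, 600), c(100, 500, 700))            # retains intron 3
  ev <- classify_gene(list(ref, skip, ret))
  # ref-skip: skipping; ref-ret: retention; skip-ret on its own merits is a
  # pure acceptor shift (400 -> 200), i.e. alternative 3'
  expect_setequal(ev$category, c("exon_skipping", "intron_retention", "alt_3prime"))
  expect_equal(nrow(ev), 3L)

  # duplicate isoforms yield no events
  expect_equal(nrow(classify_gene(list(ref, tx("ref2", ref$exons[, 1], ref$exons[, 2])))), 0L)

  # the same event seen in multiple pairs counts once
  ev2 <- classify_gene(list(ref, skip, tx("skip2", c(0, 400, 600), c(100, 500, 700))))
  expect_equal(sum(ev2$category == "exon_skipping"), 1L)
})

test_that("summarize_events tabulates events and distinct genes per category", {
  one_each <- do.call(rbind, lapply(seq_along(EVENT_CATEGORIES[1:6]), function(i)
    data.frame(gene_id = paste0("g", i), isoform_a = "a", isoform_b = "b",
               category = EVENT_CATEGORIES[i], chrom = "chr1",
               locus_start = 0, locus_end = 1, strand = "+")))
  s <- summarize_events(one_each)
  expect_equal(s$n_events[1:6], rep(1L, 6))
  expect_equal(s$n_genes[1:6], rep(1L, 6))
  expect_equal(s$n_events[7], 0L)

  s0 <- summarize_events(one_each[0, ])
  expect_true(all(s0$n_events == 0L))

  two_in_one_gene <- do.call(rbind, list(one_each[1, ], one_each[1, ]))
  two_in_one_gene$locus_start <- c(0, 10)
  s2 <- summarize_events(two_in_one_gene)
  expect_equal(s2$n_events[s2$category == "exon_skipping"], 2L)
  expect_equal(s2$n_genes[s2$category == "exon_skipping"], 1L)
})

test_that("classify_pair enforces its preconditions", {
  expect_error(classify_pair(tx("a", 0, 100, gene = "G1"),
                             tx("b", 0, 100, gene = "G2")), "share gene")
  expect_error(classify_pair(tx("a", 0, 100), tx("b", 10, 100)),
               "transcription start site")
})
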