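# Independent oracles.
#
# oracle_classify tests each splicing-event definition by whole-chain
# reconstruction: a template matches only if transforming one chain by the
# event (removing a run of internal exons, filling an intron, shifting one
# splice site, swapping one internal exon, swapping the terminal exon)
# reproduces the other chain exactly.  This shares no code with
# classify_pair, which works on exonic difference regions.

.chains_equal <- function(A, B) nrow(A) == nrow(B) && all(A == B)

oracle_classify <- function(A, B, strand = "+") {
  if (.chains_equal(A, B)) return("none")
  hits <- character(0)

  # exon skipping: drop a run of internal exons from X to obtain Y
  for (pair in list(list(A, B), list(B, A))) {
    X <- pair[[1]]; Y <- pair[[2]]
    n <- nrow(X)
    if (n >= 3) for (i in 2:(n - 1)) for (j in i:(n - 1)) {
      if (.chains_equal(X[-(i:j), , drop = FALSE], Y)) hits <- c(hits, "exon_skipping")
    }
  }

  # intron retention: merge exons j, j+1 of X to obtain Y
  for (pair in list(list(A, B), list(B, A))) {
    X <- pair[[1]]; Y <- pair[[2]]
    n <- nrow(X)
    if (n >= 2) for (j in 1:(n - 1)) {
      M <- X[-(j + 1), , drop = FALSE]
      M[j, "end"] <- X[j + 1, "end"]
      if (.chains_equal(M, Y)) hits <- c(hits, "intron_retention")
    }
  }

  if (nrow(A) == nrow(B)) {
    n <- nrow(A)
    diff_cells <- which(A != B)
    if (length(diff_cells) == 1L) {
      r <- ((diff_cells - 1) %% n) + 1
      col <- if (diff_cells > n) "end" else "start"
      if (col == "end" && r < n)        # internal donor boundary (genomic left of intron)
        hits <- c(hits, if (strand == "-") "alt_3prime" else "alt_5prime")
      if (col == "start" && r > 1)      # internal acceptor boundary (genomic right)
        hits <- c(hits, if (strand == "-") "alt_5prime" else "alt_3prime")
    }
    # mutually exclusive: exactly one internal row differs, exons disjoint
    rows_differ <- which(apply(A != B, 1, any))
    if (length(rows_differ) == 1L) {
      r <- rows_differ
      if (r > 1 && r < n && all(A[r, ] != B[r, ]) &&
          (A[r, "end"] <= B[r, "start"] || B[r, "end"] <= A[r, "start"]))
        hits <- c(hits, "mutually_exclusive")
    }
    # alternative last exon: all rows but the 3'-terminal one identical,
    # terminal exons disjoint
    if (strand == "-") {
      if (n >= 2 && .chains_equal(A[-1, , drop = FALSE], B[-1, , drop = FALSE]) &&
          (A[1, "end"] <= B[1, "start"] || B[1, "end"] <= A[1, "start"]))
        hits <- c(hits, "alt_last_exon")
    } else {
      if (n >= 2 && .chains_equal(A[-n, , drop = FALSE], B[-n, , drop = FALSE]) &&
          (A[n, "end"] <= B[n, "start"] || B[n, "end"] <= A[n, "start"]))
        hits <- c(hits, "alt_last_exon")
    }
  }

  hits <- unique(hits)
  if (length(hits) == 0L) return("complex")
  if (length(hits) > 1L) return(paste("ambiguous:", paste(hits, collapse = "+")))
  hits
}

# reference Benjamini-Hochberg step-up, written directly from the procedure
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}
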