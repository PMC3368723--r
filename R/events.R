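## Alternative-splicing event classification.
##
## Two isoforms of a single-TSS gene are compared by the regions where their
## exonic base coverage differs.  Each maximal difference region (or linked
## pair of regions) is matched against one of six templates; a pair with
## exactly one matched local difference yields a "simple" event, anything
## else is "complex".

#' Event category vocabulary
#'
#' The six simple alternative-splicing categories, in reporting order,
#' followed by `complex`.
#' @export
EVENT_CATEGORIES <- c("exon_skipping", "alt_5prime", "alt_3prime",
                      "intron_retention", "mutually_exclusive",
                      "alt_last_exon", "complex")

#' Select multi-isoform genes with a single transcription start site
#'
#' Keeps genes with at least two isoforms whose 5' ends coincide exactly
#' (same chromosome, strand, and TSS coordinate).  Exact coordinate equality
#' is used: no fuzz window, so the selection is reproducible.
#'
#' @param genes A named list of genes (each a list of [transcript_model()]),
#'   e.g. from [group_genes()].
#' @return The retained subset, same structure.
#' @export
select_single_tss_genes <- function(genes) {
  keep <- vapply(genes, function(txs) {
    if (length(txs) < 2L) return(FALSE)
    chrom <- vapply(txs, function(t) t$chrom, character(1))
    strand <- vapply(txs, function(t) t$strand, character(1))
    if (length(unique(chrom)) != 1L || length(unique(strand)) != 1L) return(FALSE)
    tss <- vapply(txs, tss_position, numeric(1))
    length(unique(tss)) == 1L
  }, logical(1))
  genes[keep]
}

# difference regions between two exon chains, with ownership
.diff_regions <- function(A, B) {
  da <- interval_setdiff(A, B)
  db <- interval_setdiff(B, A)
  d <- rbind(da, db)
  if (nrow(d) == 0L) return(NULL)
  owner <- c(rep("a", nrow(da)), rep("b", nrow(db)))
  o <- order(d[, 1L], d[, 2L])
  list(iv = d[o, , drop = FALSE], owner = owner[o])
}

.exon_index <- function(M, d) {
  hit <- which(M[, 1L] == d[1L] & M[, 2L] == d[2L])
  if (length(hit) == 1L) hit else NA_integer_
}

.is_internal <- function(M, idx) !is.na(idx) && idx > 1L && idx < nrow(M)

.has_intron <- function(M, s, e) {
  I <- if (nrow(M) < 2L) NULL else cbind(M[-nrow(M), 2L], M[-1L, 1L])
  !is.null(I) && any(I[, 1L] == s & I[, 2L] == e)
}

# --- templates; each returns a category string or NULL ------------------

# run of consecutive internal exons of `own` sitting inside a single intron
# of `oth` whose outer splice sites match own's flanking introns
.match_skipping <- function(ds, own, oth) {
  idx <- vapply(seq_len(nrow(ds)), function(i) .exon_index(own, ds[i, ]), integer(1))
  if (anyNA(idx)) return(NULL)
  if (!all(vapply(idx, function(k) .is_internal(own, k), logical(1)))) return(NULL)
  if (length(idx) > 1L && !all(diff(idx) == 1L)) return(NULL)
  k0 <- idx[1L]; k1 <- idx[length(idx)]
  gs <- own[k0 - 1L, 2L]   # end of exon upstream of the run
  ge <- own[k1 + 1L, 1L]   # start of exon downstream of the run
  if (!.has_intron(oth, gs, ge)) return(NULL)
  "exon_skipping"
}

# d equals one transcript's intron and the other has a single exon spanning
# that transcript's exon-intron-exon triple exactly
.match_retention <- function(d, A, B) {
  for (xy in list(list(X = A, Y = B), list(X = B, Y = A))) {
    X <- xy$X; Y <- xy$Y
    if (nrow(X) < 2L) next
    I <- cbind(X[-nrow(X), 2L], X[-1L, 1L])
    j <- which(I[, 1L] == d[1L] & I[, 2L] == d[2L])
    if (length(j) != 1L) next
    u <- X[j, 1L]; v <- X[j + 1L, 2L]
    if (!is.na(.exon_index(Y, c(u, v)))) return("intron_retention")
  }
  NULL
}

# a single shifted splice site: introns agree at one boundary, differ by d
# at the other; 5'/3' assignment is strand-aware
.match_altss <- function(d, A, B, strand) {
  if (nrow(A) < 2L || nrow(B) < 2L) return(NULL)
  IA <- cbind(A[-nrow(A), 2L], A[-1L, 1L])
  IB <- cbind(B[-nrow(B), 2L], B[-1L, 1L])
  minus <- identical(strand, "-")
  for (i in seq_len(nrow(IA))) for (j in seq_len(nrow(IB))) {
    a <- IA[i, ]; b <- IB[j, ]
    if (a[2L] == b[2L] && a[1L] != b[1L] &&
        min(a[1L], b[1L]) == d[1L] && max(a[1L], b[1L]) == d[2L]) {
      # genomic-left intron boundary shifted: donor on +, acceptor on -
      return(if (minus) "alt_3prime" else "alt_5prime")
    }
    if (a[1L] == b[1L] && a[2L] != b[2L] &&
        min(a[2L], b[2L]) == d[1L] && max(a[2L], b[2L]) == d[2L]) {
      return(if (minus) "alt_5prime" else "alt_3prime")
    }
  }
  NULL
}

# two non-overlapping internal exons, one per isoform, sharing both flanking
# splice sites
.match_mxe <- function(d1, o1, d2, A, B) {
  if (o1 == "a") { M1 <- A; M2 <- B } else { M1 <- B; M2 <- A }
  i <- .exon_index(M1, d1); j <- .exon_index(M2, d2)
  if (!.is_internal(M1, i) || !.is_internal(M2, j)) return(NULL)
  if (d1[2L] > d2[1L]) return(NULL)                       # must be disjoint
  if (M1[i - 1L, 2L] != M2[j - 1L, 2L]) return(NULL)      # shared upstream site
  if (M1[i + 1L, 1L] != M2[j + 1L, 1L]) return(NULL)      # shared downstream site
  "mutually_exclusive"
}

# non-overlapping terminal (3'-most) exons sharing the 5' splice site of the
# final intron
.match_ale <- function(d1, o1, d2, A, B, strand) {
  if (o1 == "a") { M1 <- A; M2 <- B } else { M1 <- B; M2 <- A }
  if (nrow(M1) < 2L || nrow(M2) < 2L) return(NULL)
  if (d1[2L] > d2[1L]) return(NULL)
  if (identical(strand, "-")) {
    # 3' terminal exon is the genomic-first one; last introns share their
    # genomic-right (donor) boundary
    i1 <- .exon_index(M1, d1); i2 <- .exon_index(M2, d2)
    ok <- (!is.na(i1) && i1 == 1L && !is.na(i2) && i2 == 1L &&
             M1[2L, 1L] == M2[2L, 1L])
    # one terminal exon belongs to each isoform
    if (ok && o1 != "b") ok <- ok  # ownership order free on '-'
  } else {
    i1 <- .exon_index(M1, d1); i2 <- .exon_index(M2, d2)
    ok <- (!is.na(i1) && i1 == nrow(M1) && !is.na(i2) && i2 == nrow(M2) &&
             M1[nrow(M1) - 1L, 2L] == M2[nrow(M2) - 1L, 2L])
  }
  if (isTRUE(ok)) "alt_last_exon" else NULL
}

#' Classify the splicing difference between two isoforms
#'
#' Both isoforms must belong to the same gene, lie on the same chromosome and
#' strand, and share their transcription start site.  The exonic base
#' coverage of the two chains is compared; each maximal local structural
#' difference is matched against the six simple event templates (exon
#' skipping, alternative 5' splice site, alternative 3' splice site, intron
#' retention, mutually exclusive exons, alternative last exon).  A pair with
#' more than one local difference, or with a difference matching no
#' template, yields a single `complex` event.
#'
#' @param a,b [transcript_model()] objects.
#' @return A data.frame with columns `gene_id`, `isoform_a`, `isoform_b`,
#'   `category`, `chrom`, `locus_start`, `locus_end`, `strand`; zero rows if
#'   the chains are identical.
#' @export
classify_pair <- function(a, b) {
  stopifnot(is(a, "transcript_model"), is(b, "transcript_model"))
  if (a$transcript_id == b$transcript_id && identical(a$exons, b$exons))
    return(.event_df())
  if (a$gene_id != b$gene_id || a$chrom != b$chrom || a$strand != b$strand)
    stop("classify_pair: isoforms must share gene, chromosome and strand")
  if (tss_position(a) != tss_position(b))
    stop("classify_pair: isoforms must share their transcription start site")
  A <- a$exons; B <- b$exons
  strand <- if (a$strand == ".") "+" else a$strand
  D <- .diff_regions(A, B)
  if (is.null(D)) return(.event_df())

  events <- list()
  unmatched <- FALSE
  i <- 1L
  n <- nrow(D$iv)
  while (i <= n) {
    d <- D$iv[i, ]; own <- D$owner[i]
    # try to pair with the next region (mutually exclusive / alt last exon)
    if (i < n && D$owner[i + 1L] != own) {
      d2 <- D$iv[i + 1L, ]
      cat2 <- .match_mxe(d, own, d2, A, B)
      if (is.null(cat2)) cat2 <- .match_ale(d, own, d2, A, B, strand)
      if (!is.null(cat2)) {
        events[[length(events) + 1L]] <- c(cat2, d[1L], d2[2L])
        i <- i + 2L
        next
      }
    }
    # maximal same-owner run of full internal exons -> one skipping event
    M <- if (own == "a") A else B
    if (.is_internal(M, .exon_index(M, d))) {
      j <- i
      while (j < n && D$owner[j + 1L] == own &&
             .is_internal(M, .exon_index(M, D$iv[j + 1L, ])))
        j <- j + 1L
      run <- D$iv[i:j, , drop = FALSE]
      cat1 <- .match_skipping(run, M, if (own == "a") B else A)
      if (!is.null(cat1)) {
        events[[length(events) + 1L]] <- c(cat1, run[1L, 1L], run[nrow(run), 2L])
        i <- j + 1L
        next
      }
    }
    cat1 <- .match_retention(d, A, B)
    if (is.null(cat1)) cat1 <- .match_altss(d, A, B, strand)
    if (is.null(cat1)) unmatched <- TRUE
    else events[[length(events) + 1L]] <- c(cat1, d[1L], d[2L])
    i <- i + 1L
  }

  if (unmatched || length(events) != 1L) {
    locus <- c(min(D$iv[, 1L]), max(D$iv[, 2L]))
    return(.event_df(a, b, "complex", locus[1L], locus[2L]))
  }
  ev <- events[[1L]]
  .event_df(a, b, ev[1L], as.numeric(ev[2L]), as.numeric(ev[3L]))
}

.event_df <- function(a = NULL, b = NULL, category = character(0),
                      locus_start = numeric(0), locus_end = numeric(0)) {
  if (is.null(a)) {
    return(data.frame(gene_id = character(0), isoform_a = character(0),
                      isoform_b = character(0), category = character(0),
                      chrom = character(0), locus_start = numeric(0),
                      locus_end = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(gene_id = a$gene_id, isoform_a = a$transcript_id,
             isoform_b = b$transcript_id, category = category,
             chrom = a$chrom, locus_start = locus_start,
             locus_end = locus_end, strand = a$strand,
             stringsAsFactors = FALSE)
}

#' Classify all isoform pairs of a gene
#'
#' Runs [classify_pair()] over every unordered isoform pair and de-duplicates
#' events by `(category, locus)`, so the same biological event observed in
#' several pairs is counted once.  A gene whose every pair is complex is
#' reported as a single `complex` event.
#'
#' @param txs List of [transcript_model()] of one single-TSS gene (>= 2
#'   isoforms).
#' @return Event data.frame as in [classify_pair()].
#' @export
classify_gene <- function(txs) {
  stopifnot(length(txs) >= 2L)
  prs <- combn(length(txs), 2L)
  evs <- lapply(seq_len(ncol(prs)), function(k)
    classify_pair(txs[[prs[1L, k]]], txs[[prs[2L, k]]]))
  ev <- do.call(rbind, evs)
  if (nrow(ev) == 0L) return(ev)
  if (all(ev$category == "complex")) {
    out <- ev[1L, , drop = FALSE]
    out$locus_start <- min(ev$locus_start)
    out$locus_end <- max(ev$locus_end)
    rownames(out) <- NULL
    return(out)
  }
  key <- paste(ev$category, ev$locus_start, ev$locus_end)
  out <- ev[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize classified events per category
#'
#' @param events Event data.frame (rows from [classify_gene()] across genes).
#' @return A data.frame with one row per category (fixed order: the six
#'   simple categories then `complex`) and columns `category`, `n_events`,
#'   `n_genes`.
#' @export
summarize_events <- function(events) {
  cat <- factor(events$category, levels = EVENT_CATEGORIES)
  if (anyNA(cat)) stop("unknown event category in input")
  data.frame(
    category = EVENT_CATEGORIES,
    n_events = as.integer(table(cat)),
    n_genes = vapply(EVENT_CATEGORIES, function(cc)
      length(unique(events$gene_id[events$category == cc])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
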