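## Novel transcribed-unit discovery.
##
## Assembled transcripts lying outside annotated gene spans are clustered by
## exonic overlap into candidate units and screened against five criteria:
## distance >= 1000 bp from any gene boundary, merged exonic length >= 250
## bp, mean coverage >= 5, repeat overlap < 50% of exonic bases, and every
## intron supported by >= 2 junction alignments.  External EST support
## (>= 5 ESTs jointly covering > 50% of exonic bases) is scored separately.

TU_CRITERIA <- c("distance", "length", "coverage", "repeat_fraction",
                 "junction_support")

.gene_spans <- function(reference) {
  genes <- group_genes(reference)
  do.call(rbind, lapply(names(genes), function(g) {
    sp <- vapply(genes[[g]], genomic_span, numeric(2))
    data.frame(gene_id = g, chrom = genes[[g]][[1L]]$chrom,
               start = min(sp[1L, ]), end = max(sp[2L, ]),
               stringsAsFactors = FALSE)
  }))
}

#' Cluster intergenic assembled transcripts into candidate novel units
#'
#' Assembled transcripts whose genomic span overlaps no reference gene span
#' are clustered by exonic overlap (single linkage; strand-ignored unless
#' `stranded`) into candidate units.  Only units containing at least one
#' multi-exonic transcript are retained.  The distance to the nearest
#' reference gene span is annotated (0 would mean overlap); the 1000 bp
#' distance rule itself is applied in [filter_novel_tus()] so that every
#' candidate's rejection reasons can be reported.
#'
#' @param assembled List of [transcript_model()] (the assembly).
#' @param reference List of [transcript_model()] (the annotation).
#' @param stranded Cluster and compare per strand (default `FALSE`).
#' @return A list of candidate units; each is a list with `unit_id`,
#'   `chrom`, `strand`, `transcripts`, `exonic_span` (merged matrix),
#'   `total_length`, `n_exons`, `introns`, `distance_to_nearest_gene`, and
#'   evidence fields initialised to `NA` (see [annotate_evidence()]).
#' @export
candidate_units <- function(assembled, reference, stranded = FALSE) {
  spans <- .gene_spans(reference)
  keep <- vapply(assembled, function(t) {
    sp <- genomic_span(t)
    s <- spans[spans$chrom == t$chrom, , drop = FALSE]
    !any(sp[1L] < s$end & sp[2L] > s$start)
  }, logical(1))
  txs <- assembled[keep]
  if (length(txs) == 0L) return(list())

  # single-linkage clustering by exonic overlap via union-find
  parent <- seq_along(txs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  key <- function(t) paste(t$chrom, if (stranded) t$strand else "*")
  ks <- vapply(txs, key, character(1))
  for (grp in split(seq_along(txs), ks)) {
    if (length(grp) < 2L) next
    for (ii in seq_along(grp)) for (jj in seq_len(ii - 1L)) {
      i <- grp[ii]; j <- grp[jj]
      if (nrow(interval_intersect(txs[[i]]$exons, txs[[j]]$exons)) > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_along(txs), find, integer(1))

  units <- lapply(split(seq_along(txs), roots), function(idx) {
    members <- txs[idx]
    if (!any(vapply(members, n_exons, integer(1)) >= 2L)) return(NULL)
    chrom <- members[[1L]]$chrom
    ex <- merge_intervals(do.call(rbind, lapply(members, function(t) t$exons)))
    introns <- unique(do.call(rbind, lapply(members, derive_introns)))
    s <- spans[spans$chrom == chrom, , drop = FALSE]
    dist <- if (nrow(s) == 0L) Inf else
      min(pmax(pmax(s$start - ex[nrow(ex), "end"], ex[1L, "start"] - s$end), 0))
    strands <- unique(vapply(members, function(t) t$strand, character(1)))
    list(unit_id = sprintf("TU_%s_%d_%d", chrom,
                           as.integer(ex[1L, "start"]), as.integer(ex[nrow(ex), "end"])),
         chrom = chrom,
         strand = if (length(strands) == 1L) strands else ".",
         transcripts = members,
         exonic_span = ex,
         total_length = interval_total(ex),
         n_exons = nrow(ex),
         introns = introns,
         distance_to_nearest_gene = dist,
         mean_coverage = NA_real_, repeat_fraction = NA_real_,
         min_junction_support = NA_real_,
         est_count = NA_integer_, est_coverage_fraction = NA_real_,
         supported = NA)
  })
  units <- Filter(Negate(is.null), units)
  units[order(vapply(units, `[[`, character(1), "unit_id"))]
}

#' Attach repeat, junction, and coverage evidence to candidate units
#'
#' @param units Candidate list from [candidate_units()].
#' @param repeats data.frame from [read_bed()] (repeat-masked intervals).
#' @param junctions data.frame with columns `chrom`, `donor_end`,
#'   `acceptor_start`, `support_count` (0-based half-open intron
#'   coordinates: `donor_end` is the intron start, `acceptor_start` its
#'   end); a `strand` column is ignored unless `stranded`.
#' @param coverage data.frame with columns `transcript_id`,
#'   `mean_coverage`; a unit's coverage is the exonic-length-weighted mean
#'   over its member transcripts.  Missing transcripts are an error.
#' @param stranded Match junctions per strand (default `FALSE`).
#' @return The units with `repeat_fraction`, `min_junction_support`,
#'   `mean_coverage` filled in.
#' @export
annotate_evidence <- function(units, repeats, junctions, coverage,
                              stranded = FALSE) {
  lapply(units, function(u) {
    rp <- repeats[repeats$chrom == u$chrom, , drop = FALSE]
    rmat <- if (nrow(rp)) cbind(start = rp$start, end = rp$end) else
      cbind(start = numeric(0), end = numeric(0))
    u$repeat_fraction <- interval_total(interval_intersect(u$exonic_span, rmat)) /
      u$total_length
    jn <- junctions[junctions$chrom == u$chrom, , drop = FALSE]
    if (stranded && "strand" %in% names(jn))
      jn <- jn[jn$strand == u$strand, , drop = FALSE]
    u$min_junction_support <- if (nrow(u$introns) == 0L) Inf else
      min(vapply(seq_len(nrow(u$introns)), function(i) {
        hit <- jn$donor_end == u$introns[i, "start"] &
          jn$acceptor_start == u$introns[i, "end"]
        if (any(hit)) max(jn$support_count[hit]) else 0
      }, numeric(1)))
    cv <- coverage$mean_coverage[match(
      vapply(u$transcripts, function(t) t$transcript_id, character(1)),
      coverage$transcript_id)]
    if (anyNA(cv))
      stop("annotate_evidence: coverage missing for unit ", u$unit_id)
    len <- vapply(u$transcripts, exonic_length, numeric(1))
    u$mean_coverage <- sum(cv * len) / sum(len)
    u
  })
}

#' Score EST support for candidate units
#'
#' @param units Candidate list (any stage).
#' @param ests data.frame from [read_bed()] (BED12 EST alignments; blocks
#'   are the aligned segments).
#' @param stranded Restrict to same-strand ESTs (default `FALSE`).
#' @return Units with `est_count`, `est_coverage_fraction` (fraction of the
#'   unit's exonic bases covered by the union of overlapping ESTs' blocks),
#'   and `supported` (`est_count >= 5` and coverage strictly `> 0.5`).
#' @export
est_support <- function(units, ests, stranded = FALSE) {
  lapply(units, function(u) {
    ee <- ests[ests$chrom == u$chrom, , drop = FALSE]
    if (stranded) ee <- ee[ee$strand == u$strand, , drop = FALSE]
    hits <- if (nrow(ee) == 0L) logical(0) else
      vapply(ee$blocks, function(b)
        nrow(interval_intersect(u$exonic_span, b)) > 0L, logical(1))
    u$est_count <- sum(hits)
    cov <- if (u$est_count == 0L) 0 else
      interval_total(interval_intersect(u$exonic_span,
                                        do.call(rbind, ee$blocks[hits])))
    u$est_coverage_fraction <- cov / u$total_length
    u$supported <- u$est_count >= 5L && u$est_coverage_fraction > 0.5
    u
  })
}

#' Apply the five novel-TU acceptance criteria
#'
#' A unit is accepted iff distance >= 1000 bp, length >= 250 bp, mean
#' coverage >= 5, repeat fraction strictly < 0.5, and minimum junction
#' support >= 2 (the printed inequalities, applied verbatim).
#'
#' @param units Candidates with evidence fields populated (via
#'   [annotate_evidence()]); an unpopulated field is an error naming it.
#' @return A list with `accepted` (unit list) and `table`, a data.frame of
#'   all units with their criterion values, `accepted` flag and
#'   comma-separated `rejection_reasons`.
#' @export
filter_novel_tus <- function(units) {
  rows <- lapply(units, function(u) {
    for (f in c("mean_coverage", "repeat_fraction", "min_junction_support"))
      if (is.na(u[[f]]))
        stop("filter_novel_tus: evidence field '", f, "' not populated for ",
             u$unit_id)
    reasons <- TU_CRITERIA[c(
      u$distance_to_nearest_gene < 1000,
      u$total_length < 250,
      u$mean_coverage < 5,
      u$repeat_fraction >= 0.5,
      u$min_junction_support < 2)]
    data.frame(
      unit_id = u$unit_id, chrom = u$chrom,
      start = u$exonic_span[1L, "start"],
      end = u$exonic_span[nrow(u$exonic_span), "end"],
      strand = u$strand, n_exons = u$n_exons,
      distance = u$distance_to_nearest_gene, length = u$total_length,
      coverage = u$mean_coverage, repeat_fraction = u$repeat_fraction,
      junction_support = u$min_junction_support,
      accepted = length(reasons) == 0L,
      rejection_reasons = paste(reasons, collapse = ","),
      est_count = u$est_count,
      est_coverage_fraction = u$est_coverage_fraction,
      supported = u$supported,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(unit_id = character(0), accepted = logical(0),
                      rejection_reasons = character(0))
  }
  rownames(tab) <- NULL
  list(accepted = units[tab$accepted], table = tab)
}
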