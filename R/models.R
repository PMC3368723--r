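#' @importFrom methods is
#' @importFrom stats quantile sd setNames rmultinom rnorm runif rlnorm binom.test p.adjust plogis
#' @importFrom utils read.delim write.table combn head tail
NULL

.STRANDS <- c("+", "-", ".")

#' Construct a transcript model
#'
#' A transcript model is one isoform: an ordered chain of exons on a single
#' chromosome and strand.  All coordinates in this package are BED-style,
#' 0-based half-open `[start, end)`; GTF input/output is converted at the
#' file boundary.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param starts,ends Integer vectors of exon starts/ends (0-based half-open).
#' @param strand One of `"+"`, `"-"`, `"."`.  An unstranded `"."` transcript
#'   is oriented as `"+"` for 5'/3' purposes (a warning is emitted where that
#'   matters).
#' @return An object of class `transcript_model` with an `exons` matrix
#'   (columns `start`, `end`), sorted by start.
#' @details Exons must be pairwise non-overlapping and non-adjacent (at least
#'   1 bp of intron between consecutive exons); violations indicate corrupt
#'   upstream assemblies and are rejected rather than repaired.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, starts, ends,
                             strand = "+") {
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("transcript '", transcript_id, "': need >= 1 exon with matching starts/ends")
  if (!strand %in% .STRANDS)
    stop("transcript '", transcript_id, "': invalid strand '", strand, "'")
  o <- order(starts)
  starts <- as.numeric(starts)[o]
  ends <- as.numeric(ends)[o]
  if (any(starts < 0) || any(ends <= starts))
    stop("transcript '", transcript_id, "': exon with start < 0 or end <= start")
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("transcript '", transcript_id,
         "': overlapping or adjacent exons (gap >= 1 bp required)")
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = cbind(start = starts, end = ends)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s [%d exon(s)]\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

n_exons <- function(t) nrow(t$exons)

exonic_length <- function(t) sum(t$exons[, "end"] - t$exons[, "start"])

genomic_span <- function(t) c(t$exons[1L, "start"], t$exons[nrow(t$exons), "end"])

#' Introns of a transcript
#'
#' @param t A [transcript_model()].
#' @return A matrix with columns `start`, `end` (0-based half-open), one row
#'   per intron; zero rows for a single-exon transcript.
#' @export
derive_introns <- function(t) {
  stopifnot(is(t, "transcript_model"))
  n <- nrow(t$exons)
  if (n < 2L) return(cbind(start = numeric(0), end = numeric(0)))
  cbind(start = t$exons[-n, "end"], end = t$exons[-1L, "start"])
}

#' Transcription start site
#'
#' The 5'-most genomic coordinate of a transcript: the start of the first
#' exon on the `+` strand, the (half-open) end of the last exon on the `-`
#' strand.  Unstranded transcripts are oriented as `+`.
#'
#' @param t A [transcript_model()].
#' @param warn_unstranded Emit a warning for strand `"."` (default `FALSE`;
#'   turned on where orientation is load-bearing).
#' @return A single numeric coordinate.
#' @export
tss_position <- function(t, warn_unstranded = FALSE) {
  stopifnot(is(t, "transcript_model"))
  if (t$strand == "." && warn_unstranded)
    warning("transcript '", t$transcript_id, "' is unstranded; treating as '+'")
  unname(if (t$strand == "-") t$exons[nrow(t$exons), "end"] else t$exons[1L, "start"])
}

#' Group transcripts into genes
#'
#' @param transcripts A list of [transcript_model()] objects.
#' @return A named list (by `gene_id`) of lists of transcripts.
#' @export
group_genes <- function(transcripts) {
  stopifnot(is.list(transcripts))
  ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  split(transcripts, factor(ids, levels = unique(ids)))
}

## ---- GTF I/O (rtracklayer does the parsing; we convert coordinates and
## validate the transcript structure) ----

#' Read transcript models from a GTF file
#'
#' Reads `exon` feature lines (Ensembl-dialect attributes `gene_id`,
#' `transcript_id`) and assembles one [transcript_model()] per distinct
#' `transcript_id`.  GTF 1-based closed coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return A list of `transcript_model` objects (empty list for an empty file).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0) return(list())
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) return(list())
  m <- S4Vectors::mcols(gr)
  if (is.null(m$transcript_id) || is.null(m$gene_id) ||
      anyNA(m$transcript_id) || anyNA(m$gene_id))
    stop("GTF exon lines must carry gene_id and transcript_id attributes: ", path)
  tid <- as.character(m$transcript_id)
  out <- lapply(split(seq_along(gr), factor(tid, levels = unique(tid))), function(i) {
    g <- gr[i]
    chrom <- unique(as.character(GenomicRanges::seqnames(g)))
    strand <- unique(as.character(GenomicRanges::strand(g)))
    if (length(chrom) != 1L || length(strand) != 1L)
      stop("transcript '", tid[i[1L]], "' spans multiple chromosomes or strands")
    if (strand == "*") strand <- "."
    transcript_model(tid[i[1L]], as.character(m$gene_id[i[1L]]), chrom,
                     GenomicRanges::start(g) - 1L, GenomicRanges::end(g), strand)
  })
  names(out) <- NULL
  out
}

#' Write transcript models to a GTF file
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "splicescape") {
  lines <- unlist(lapply(transcripts, function(t) {
    strand <- if (t$strand == ".") "." else t$strand
    apply(t$exons, 1L, function(e) {
      sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              t$chrom, source, as.integer(e[["start"]]) + 1L,
              as.integer(e[["end"]]), strand, t$gene_id, t$transcript_id)
    })
  }))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}

## ---- BED I/O ----

#' Read a BED file (BED3/BED6/BED12)
#'
#' @param path Path to a BED file (0-based half-open, as BED is defined).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, and a list-column `blocks` holding one `start`/`end` matrix
#'   per record.  For BED3/BED6 the single block is the whole interval; for
#'   BED12 the blocks are the expanded `blockStarts`/`blockSizes` intervals.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      name = character(0), strand = character(0))
  empty$blocks <- list()
  if (file.info(path)$size == 0) return(empty)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(empty)
  m <- S4Vectors::mcols(gr)
  has_blocks <- !is.null(m$blocks)
  blocks <- if (has_blocks) {
    bl <- rtracklayer::blocks(gr)
    lapply(seq_along(bl), function(i) {
      b <- bl[[i]]
      cbind(start = GenomicRanges::start(b) - 1, end = as.numeric(GenomicRanges::end(b)))
    })
  } else {
    lapply(seq_along(gr), function(i)
      cbind(start = GenomicRanges::start(gr)[i] - 1, end = as.numeric(GenomicRanges::end(gr)[i])))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    name = if (!is.null(m$name)) as.character(m$name) else sprintf("rec%d", seq_along(gr)),
    strand = strand,
    stringsAsFactors = FALSE)
  # rtracklayer validates blockSizes/blockStarts consistency; re-check the
  # outer bounds so a malformed record cannot slip through as truncated.
  if (has_blocks) {
    ok <- vapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      b[1L, "start"] == out$start[i] && b[nrow(b), "end"] == out$end[i]
    }, logical(1))
    if (!all(ok))
      stop("BED12 blocks inconsistent with chromStart/chromEnd at record(s): ",
           paste(which(!ok), collapse = ", "))
  }
  out$blocks <- blocks
  out
}

## ---- small interval helpers (0-based half-open matrices) ----

# merge possibly-overlapping intervals; rows sorted
merge_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], m[i, 2L])
    } else out <- rbind(out, m[i, , drop = FALSE])
  }
  colnames(out) <- c("start", "end")
  out
}

interval_total <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2L] - m[, 1L])

# bases of merged `a` covered by merged `b`
interval_intersect <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(cbind(start = numeric(0), end = numeric(0)))
  out <- NULL
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L]); e <- pmin(a[i, 2L], b[, 2L])
    keep <- s < e
    if (any(keep)) out <- rbind(out, cbind(start = s[keep], end = e[keep]))
  }
  if (is.null(out)) cbind(start = numeric(0), end = numeric(0)) else out
}

# merged `a` minus merged `b`
interval_setdiff <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    segs <- cbind(a[i, 1L], a[i, 2L])
    for (j in seq_len(nrow(b))) {
      new <- NULL
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1L]; e <- segs[k, 2L]
        bs <- b[j, 1L]; be <- b[j, 2L]
        if (be <= s || bs >= e) { new <- rbind(new, c(s, e)); next }
        if (bs > s) new <- rbind(new, c(s, bs))
        if (be < e) new <- rbind(new, c(be, e))
      }
      segs <- if (is.null(new)) matrix(numeric(0), 0, 2) else new
      if (nrow(segs) == 0L) break
    }
    if (nrow(segs) > 0L) out <- rbind(out, segs)
  }
  if (is.null(out)) return(cbind(start = numeric(0), end = numeric(0)))
  colnames(out) <- c("start", "end")
  out[order(out[, 1L]), , drop = FALSE]
}
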