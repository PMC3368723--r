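## FPKM, upper-quartile normalization, expression calls and fold-change
## binning.
##
## Count tables are data.frames with columns `feature_id`, `gene_id`,
## `length`, then one numeric column per sample named `condition:sample`.

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param count Fragment count(s).
#' @param length Feature effective length in bp (sum of exon lengths; no
#'   fragment-length correction).
#' @param library_size Total mapped fragments in the library.
#' @return FPKM value(s): `count * 1e9 / (length * library_size)`.
#' @export
fpkm <- function(count, length, library_size) {
  if (any(length <= 0)) stop("fpkm: length must be > 0")
  if (any(library_size <= 0)) stop("fpkm: library_size must be > 0")
  count * 1e9 / (length * library_size)
}

#' Upper-quartile normalization of a count matrix
#'
#' Per sample, the scale factor is the 75th percentile (linear-interpolation
#' quantile) of the counts of features with a nonzero count in that sample.
#' Normalized counts are `raw / factor * geometric mean of factors`, so an
#' already-normalized table is only changed by a shared global constant.
#'
#' @param counts Numeric matrix, features x samples.
#' @return A list with `normalized` (matrix) and `factors` (named vector).
#' @export
upper_quartile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  factors <- apply(counts, 2L, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0L) stop("upper_quartile_normalize: all-zero sample")
    as.numeric(quantile(nz, 0.75, type = 7))
  })
  gm <- exp(mean(log(factors)))
  normalized <- sweep(counts, 2L, factors, "/") * gm
  list(normalized = normalized, factors = factors)
}

#' Read a feature-by-sample count table
#'
#' @param path TSV with header `feature_id`, `gene_id`, `length`, then one
#'   column per sample named `condition:sample`.
#' @return A list with `counts` (matrix), `feature_id`, `gene_id`, `length`,
#'   `condition` (per sample), `sample` names.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "gene_id", "length")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  samp_cols <- setdiff(names(df), need)
  if (!all(grepl(":", samp_cols, fixed = TRUE)))
    stop("sample columns must be named 'condition:sample'")
  m <- as.matrix(df[, samp_cols, drop = FALSE])
  rownames(m) <- df$feature_id
  list(counts = m,
       feature_id = df$feature_id,
       gene_id = df$gene_id,
       length = df$length,
       condition = sub(":.*$", "", samp_cols),
       sample = samp_cols)
}

#' Transcript FPKM matrix from a count table
#'
#' @param tbl A list as returned by [read_counts()].
#' @return Numeric matrix of per-sample transcript FPKM values.
#' @export
transcript_fpkm <- function(tbl) {
  libsize <- colSums(tbl$counts)
  out <- sweep(tbl$counts / tbl$length, 2L, libsize, "/") * 1e9
  dimnames(out) <- dimnames(tbl$counts)
  out
}

#' Gene-level condition FPKM from a transcript count table
#'
#' Per-sample transcript FPKMs (optionally upper-quartile normalized across
#' samples, which removes library-composition shifts between conditions)
#' are summed within genes — FPKM is additive over a gene's isoforms — and
#' averaged across the samples of each condition.
#'
#' @param tbl A list as returned by [read_counts()].
#' @param normalize Upper-quartile normalize the FPKM matrix first
#'   (default `TRUE`).
#' @return data.frame `gene_id`, one FPKM column per condition; the
#'   per-sample scale factors are attached as attribute `"factors"` when
#'   `normalize` is on.
#' @export
gene_fpkm <- function(tbl, normalize = TRUE) {
  conds <- unique(tbl$condition)
  f <- transcript_fpkm(tbl)
  factors <- NULL
  if (normalize) {
    uq <- upper_quartile_normalize(f)
    f <- uq$normalized
    factors <- uq$factors
  }
  gsum <- rowsum(f, tbl$gene_id)
  out <- data.frame(gene_id = rownames(gsum), stringsAsFactors = FALSE)
  for (cc in conds)
    out[[cc]] <- rowMeans(gsum[, tbl$condition == cc, drop = FALSE])
  attr(out, "factors") <- factors
  out
}

#' Expression and exclusive-expression calls
#'
#' A feature is called expressed in a condition when its FPKM is at or above
#' `threshold`; it is exclusive to condition A when expressed in A and not
#' in B.
#'
#' @param fpkm_a,fpkm_b FPKM vectors for the two conditions.
#' @param threshold Expression threshold in FPKM units (default 0.5).
#' @return data.frame with logical columns `expressed_a`, `expressed_b`,
#'   `exclusive_a`, `exclusive_b`.
#' @export
call_expression <- function(fpkm_a, fpkm_b, threshold = 0.5) {
  ea <- fpkm_a >= threshold
  eb <- fpkm_b >= threshold
  data.frame(expressed_a = ea, expressed_b = eb,
             exclusive_a = ea & !eb, exclusive_b = eb & !ea)
}

FOLD_BINS <- c("<=5", "5-10", "10-15", "15-20", ">20")

#' Bin oriented fold changes
#'
#' Fold changes must already be oriented (>= 1, with a direction label
#' saying which condition is the higher one).  Bins are right-closed:
#' `(1,5], (5,10], (10,15], (15,20], (20, Inf)`.
#'
#' @param fold Numeric vector of fold changes, all >= 1.
#' @param direction Character vector, the condition each gene is
#'   over-expressed in.
#' @return A direction-by-bin contingency table (data.frame).
#' @export
bin_fold_changes <- function(fold, direction) {
  if (any(fold < 1)) stop("bin_fold_changes: fold changes must be >= 1 (orient first)")
  stopifnot(length(fold) == length(direction))
  bin <- cut(fold, breaks = c(1, 5, 10, 15, 20, Inf), labels = FOLD_BINS,
             include.lowest = TRUE, right = TRUE)
  tab <- table(direction = direction, bin = bin)
  as.data.frame.matrix(tab)
}
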