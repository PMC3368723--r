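## geNorm-style reference-gene stability and delta-delta-Ct fold changes.

#' Read a Ct table
#'
#' @param path TSV with column `gene_id` then one numeric column per sample
#'   named `condition:sample`.
#' @return A list with `ct` (genes x samples matrix), `condition`, `sample`.
#' @export
read_ct <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("Ct table must start with a gene_id column")
  samp <- names(df)[-1L]
  if (!all(grepl(":", samp, fixed = TRUE)))
    stop("sample columns must be named 'condition:sample'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  if (!all(is.finite(m))) stop("Ct values must be finite")
  list(ct = m, condition = sub(":.*$", "", samp), sample = samp)
}

#' geNorm stability values M for candidate control genes
#'
#' Expression is `2^-Ct`; for genes j, k the pairwise variation `V(j,k)` is
#' the standard deviation across samples of `log2` of their expression
#' ratio, i.e. the SD of `Ct_k - Ct_j` (sample SD, n-1 denominator).  The
#' stability value `M_j` is the mean of `V(j,k)` over all other candidates;
#' low M means stable.  Per-sample additive Ct shifts (loading differences)
#' cancel in the ratios and leave M unchanged.
#'
#' @param ct Genes x samples Ct matrix (e.g. `read_ct(path)$ct`).
#' @param candidates Character vector of >= 3 candidate control genes.
#' @return data.frame `gene_id`, `M`, sorted by increasing M.
#' @export
stability_m <- function(ct, candidates) {
  if (length(candidates) < 3L)
    stop("stability_m: need >= 3 candidate control genes")
  if (ncol(ct) < 3L) stop("stability_m: need >= 3 samples")
  if (!all(candidates %in% rownames(ct)))
    stop("stability_m: candidate gene(s) missing from Ct table")
  M <- vapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(vapply(others, function(k) sd(ct[k, ] - ct[j, ]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene_id = candidates, M = as.numeric(M),
                    stringsAsFactors = FALSE)
  out[order(out$M, out$gene_id), , drop = FALSE]
}

#' Select the most stable reference gene
#'
#' @param stability data.frame from [stability_m()].
#' @return The `gene_id` with the smallest M; ties are broken
#'   lexicographically with a warning.
#' @export
select_reference <- function(stability) {
  if (nrow(stability) == 0L) stop("select_reference: empty stability table")
  mmin <- min(stability$M)
  best <- sort(stability$gene_id[stability$M == mmin])
  if (length(best) > 1L)
    warning("select_reference: tie on M; choosing '", best[1L], "' lexicographically")
  best[1L]
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(Ct_target - Ct_reference)` within each condition;
#' `ddCt = dCt_b - dCt_a`; the fold change of condition B relative to A is
#' `2^-ddCt`.
#'
#' @param ct_tbl List from [read_ct()] (fields `ct`, `condition`).
#' @param target,reference Gene ids (must differ).
#' @param condition_a,condition_b Condition labels present in the table.
#' @return A list: `fold` (2^-ddCt, B relative to A), `ddct`, `dct_a`,
#'   `dct_b`, and `per_sample_fold` (fold per condition-B sample against the
#'   condition-A mean dCt).
#' @export
ddct_fold_change <- function(ct_tbl, target, reference, condition_a, condition_b) {
  if (identical(target, reference)) stop("ddct_fold_change: target == reference")
  ct <- ct_tbl$ct
  cond <- ct_tbl$condition
  for (cc in c(condition_a, condition_b))
    if (!any(cond == cc)) stop("ddct_fold_change: condition '", cc, "' absent")
  for (g in c(target, reference))
    if (!g %in% rownames(ct)) stop("ddct_fold_change: gene '", g, "' absent")
  dct <- ct[target, ] - ct[reference, ]
  dct_a <- mean(dct[cond == condition_a])
  dct_b <- mean(dct[cond == condition_b])
  ddct <- dct_b - dct_a
  list(fold = 2^(-ddct), ddct = ddct, dct_a = dct_a, dct_b = dct_b,
       per_sample_fold = 2^(-(dct[cond == condition_b] - dct_a)))
}
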