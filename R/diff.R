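## Differential expression (no-replicate, binomial) and differential isoform
## usage (Jensen-Shannon distance with a multinomial parametric bootstrap).

#' Jensen-Shannon distance between two probability vectors
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms:
#' `JSD = KL(p||m)/2 + KL(q||m)/2`, `m = (p+q)/2`, with `0*log(0) = 0`.
#' Bounded in `[0, 1]`; equals 1 for disjoint supports.
#'
#' @param p,q Nonnegative vectors of equal length (>= 2) summing to 1.
#' @return The Jensen-Shannon distance.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q) || length(p) < 2L)
    stop("js_distance: p and q must have equal length >= 2")
  if (any(p < 0) || any(q < 0)) stop("js_distance: negative entries")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("js_distance: inputs must lie on the probability simplex")
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * (log2(x[i]) - log2(y[i])))
  }
  jsd <- kl(p, m) / 2 + kl(q, m) / 2
  sqrt(max(jsd, 0))
}

.js_rows <- function(P, Q) {
  # vectorized JS distance for matching rows of two proportion matrices
  M <- (P + Q) / 2
  term <- function(X) {
    Z <- X * (log2(X) - log2(M))
    Z[X == 0] <- 0
    rowSums(Z)
  }
  sqrt(pmax(term(P) / 2 + term(Q) / 2, 0))
}

#' Differential isoform usage test for one gene
#'
#' The statistic is the Jensen-Shannon distance between the two conditions'
#' isoform-proportion vectors.  The null distribution is generated by a
#' multinomial parametric bootstrap: both conditions' counts are pooled into
#' a common proportion vector and `n_boot` pairs of multinomial samples are
#' drawn at the observed per-condition depths.  The p-value uses the add-one
#' convention `p = (1 + #[null >= observed]) / (n_boot + 1)`, so it is never
#' zero.
#'
#' @param counts_a,counts_b Integer vectors of per-isoform fragment counts
#'   (length >= 2) for the two conditions.
#' @param n_boot Number of bootstrap resamples (default 999).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return A list with `statistic` (JS distance), `p_value`, `n_a`, `n_b`.
#' @export
test_usage <- function(counts_a, counts_b, n_boot = 999L, seed) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2L)
    stop("test_usage: need >= 2 isoforms in both conditions")
  na <- sum(counts_a); nb <- sum(counts_b)
  if (na <= 0 || nb <= 0) stop("test_usage: both conditions need total count > 0")
  if (missing(seed)) stop("test_usage: seed is required")
  obs <- js_distance(counts_a / na, counts_b / nb)
  pool <- (counts_a + counts_b) / (na + nb)
  null <- withr::with_seed(as.integer(seed), {
    XA <- t(rmultinom(n_boot, na, pool)) / na
    XB <- t(rmultinom(n_boot, nb, pool)) / nb
    .js_rows(XA, XB)
  })
  p <- (1 + sum(null >= obs)) / (n_boot + 1)
  list(statistic = obs, p_value = p, n_a = na, n_b = nb)
}

#' Differential expression test for one feature (no replicates)
#'
#' Log2 fold change with a depth-scaled pseudocount, and an exact binomial
#' test of the condition-A count against the expected split given the two
#' library sizes.
#'
#' @param count_a,count_b Fragment counts in the two conditions.
#' @param size_a,size_b Library sizes (total mapped fragments).
#' @return A list with `statistic` (log2 fold change, B over A) and
#'   `p_value` (two-sided).
#' @export
test_expression <- function(count_a, count_b, size_a, size_b) {
  if (size_a <= 0 || size_b <= 0) stop("test_expression: library sizes must be > 0")
  pc <- 0.5 / min(size_a, size_b)
  stat <- log2((count_b / size_b + pc) / (count_a / size_a + pc))
  n <- count_a + count_b
  p <- if (n == 0) 1 else
    binom.test(count_a, n, p = size_a / (size_a + size_b))$p.value
  list(statistic = stat, p_value = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment, mapped back to input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential usage tests across a count table
#'
#' Applies [test_usage()] to every gene with >= 2 isoforms; per-gene seeds
#' are derived deterministically from `seed` and the gene's rank.
#'
#' @param tbl Count table list from [read_counts()].
#' @param n_boot Bootstrap resamples per gene.
#' @param seed Master integer seed.
#' @param genes Optional character vector restricting the genes tested.
#' @return data.frame `gene_id`, `statistic`, `p_value`, `q_value`,
#'   `significant` (at `fdr`).
#' @param fdr Significance level applied to q-values (default 0.05).
#' @export
run_usage_tests <- function(tbl, n_boot = 999L, seed, genes = NULL, fdr = 0.05) {
  conds <- unique(tbl$condition)
  if (length(conds) != 2L) stop("run_usage_tests: exactly two conditions required")
  ca <- rowSums(tbl$counts[, tbl$condition == conds[1L], drop = FALSE])
  cb <- rowSums(tbl$counts[, tbl$condition == conds[2L], drop = FALSE])
  gid <- tbl$gene_id
  keep <- names(which(table(gid) >= 2L))
  if (!is.null(genes)) keep <- intersect(keep, genes)
  keep <- sort(keep)
  res <- lapply(seq_along(keep), function(k) {
    i <- which(gid == keep[k])
    if (sum(ca[i]) == 0 || sum(cb[i]) == 0) return(NULL)
    r <- test_usage(ca[i], cb[i], n_boot = n_boot,
                    seed = (as.integer(seed) + 7L * k) %% .Machine$integer.max)
    data.frame(gene_id = keep[k], statistic = r$statistic,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene_id = character(0), statistic = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0)))
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr
  rownames(out) <- NULL
  out
}

#' Differential expression tests across a gene-level count table
#'
#' @param tbl Count table list from [read_counts()]; transcript counts are
#'   summed within genes, samples pooled within conditions.
#' @param fdr Significance level applied to q-values (default 0.05).
#' @param sizes Optional named per-sample effective library sizes (e.g.
#'   raw sizes times upper-quartile factors, which corrects composition
#'   shifts between the two pools); defaults to the raw column sums.
#' @return data.frame `gene_id`, `statistic` (log2 FC, condition B over A),
#'   `p_value`, `q_value`, `significant`.
#' @export
run_expression_tests <- function(tbl, fdr = 0.05, sizes = NULL) {
  conds <- unique(tbl$condition)
  if (length(conds) != 2L) stop("run_expression_tests: exactly two conditions required")
  if (is.null(sizes)) sizes <- colSums(tbl$counts)
  gsum <- rowsum(tbl$counts, tbl$gene_id)
  ca <- rowSums(gsum[, tbl$condition == conds[1L], drop = FALSE])
  cb <- rowSums(gsum[, tbl$condition == conds[2L], drop = FALSE])
  sa <- sum(sizes[tbl$condition == conds[1L]])
  sb <- sum(sizes[tbl$condition == conds[2L]])
  res <- lapply(seq_along(ca), function(i) test_expression(ca[i], cb[i], sa, sb))
  out <- data.frame(gene_id = rownames(gsum),
                    statistic = vapply(res, `[[`, numeric(1), "statistic"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"),
                    stringsAsFactors = FALSE)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr
  rownames(out) <- NULL
  out
}
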