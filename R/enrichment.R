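## Gene-category enrichment with gene-length selection-bias correction.
##
## Long genes yield more fragments and are easier to call differentially
## expressed; a category full of long genes is then spuriously enriched
## under the central hypergeometric model.  Following the probability
## weighting idea, the per-gene probability of being called DE is estimated
## as a monotone function of gene length, and each category is tested under
## a Wallenius noncentral hypergeometric null whose odds parameter is the
## ratio of mean weights inside versus outside the category.

# weighted pool-adjacent-violators: isotonic (non-decreasing) fit of y on a
# pre-sorted grid with weights w
.pava <- function(y, w) {
  n <- length(y)
  bv <- c(); bw <- c(); bn <- c()
  for (i in seq_len(n)) {
    bv <- c(bv, y[i]); bw <- c(bw, w[i]); bn <- c(bn, 1L)
    while (length(bv) > 1L && bv[length(bv) - 1L] > bv[length(bv)]) {
      k <- length(bv)
      wsum <- bw[k - 1L] + bw[k]
      bv[k - 1L] <- (bv[k - 1L] * bw[k - 1L] + bv[k] * bw[k]) / wsum
      bw[k - 1L] <- wsum
      bn[k - 1L] <- bn[k - 1L] + bn[k]
      bv <- bv[-k]; bw <- bw[-k]; bn <- bn[-k]
    }
  }
  rep(bv, bn)
}

#' Probability weighting function: DE propensity versus gene length
#'
#' Fits a monotone non-decreasing (isotonic) regression of the DE indicator
#' on gene length, so each gene receives a weight in `(0, 1)` estimating its
#' length-driven propensity to be called differentially expressed.  Weights
#' are floored at `1e-6` and capped at `1 - 1e-6`.
#'
#' @param de_flags Named logical/0-1 vector, one entry per gene.
#' @param lengths Named numeric vector of gene lengths (bp), same genes.
#' @return Named numeric vector of weights, one per gene.
#' @export
fit_pwf <- function(de_flags, lengths) {
  genes <- names(de_flags)
  if (is.null(genes) || is.null(names(lengths)))
    stop("fit_pwf: de_flags and lengths must be named by gene")
  lengths <- lengths[genes]
  if (anyNA(lengths) || any(lengths <= 0)) stop("fit_pwf: missing or nonpositive lengths")
  if (length(genes) < 20L) stop("fit_pwf: need >= 20 genes")
  de <- as.numeric(de_flags)
  if (length(unique(lengths)) == 1L) {
    warning("fit_pwf: constant lengths; using uniform weights")
    w <- rep(mean(de), length(genes))
  } else {
    # aggregate ties (the weight must be a function of length alone), then
    # pre-bin neighbouring lengths to ~100 genes per bin before the weighted
    # PAVA fit; unbinned isotonic fits spike at the extremes under the null
    ul <- sort(unique(lengths))
    ybar <- as.numeric(tapply(de, lengths, mean)[as.character(ul)])
    wts <- as.numeric(tapply(de, lengths, length)[as.character(ul)])
    target <- max(1, min(100, floor(length(genes) / 20)))
    bin <- floor((cumsum(wts) - wts / 2) / target)
    yb <- tapply(ybar * wts, bin, sum) / tapply(wts, bin, sum)
    wb <- as.numeric(tapply(wts, bin, sum))
    fit_b <- .pava(as.numeric(yb), wb)
    fit <- fit_b[match(bin, sort(unique(bin)))]
    w <- fit[match(lengths, ul)]
  }
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  names(w) <- genes
  w
}

#' Upper tail of the Wallenius noncentral hypergeometric distribution
#'
#' Exact evaluation by the sequential-draw recursion: `n` balls are drawn
#' one at a time without replacement from an urn with `m1` weighted (odds
#' `omega`) and `m2` unweighted balls.
#'
#' @param x_obs Observed number of category balls drawn.
#' @param m1 Category size.
#' @param m2 Complement size.
#' @param n Number of draws (DE genes).
#' @param omega Odds parameter (> 0).
#' @return `P(X >= x_obs)`.
#' @export
pwallenius_upper <- function(x_obs, m1, m2, n, omega) {
  stopifnot(m1 >= 0, m2 >= 0, n >= 0, n <= m1 + m2, omega > 0)
  if (x_obs <= 0) return(1)
  if (x_obs > min(m1, n)) return(0)
  # prob[x + 1] = P(x category balls after k draws)
  prob <- c(1, rep(0, min(m1, n)))
  for (k in 0:(n - 1L)) {
    xmax <- min(k, m1)
    x <- 0:xmax
    red <- (m1 - x) * omega
    white <- pmax(m2 - (k - x), 0)
    tot <- red + white
    pr <- ifelse(tot > 0, red / tot, 0)       # P(next draw is from category)
    newp <- numeric(length(prob))
    stay <- prob[x + 1L] * (1 - pr)
    move <- prob[x + 1L] * pr
    newp[x + 1L] <- stay
    idx <- x + 2L
    ok <- idx <= length(prob)       # move out of x = m1 has probability 0
    newp[idx[ok]] <- newp[idx[ok]] + move[ok]
    prob <- newp
  }
  sum(prob[(x_obs + 1L):length(prob)])
}

#' Wallenius enrichment test for one category
#'
#' @param cat_genes Character vector: genes in the category.
#' @param de_genes Character vector: differentially expressed genes.
#' @param all_genes Character vector: the gene universe.
#' @param weights Named weight vector from [fit_pwf()].
#' @return A one-row data.frame: `n_de_in_cat`, `n_cat`, `n_de_total`,
#'   `n_genes_total`, `odds`, `p_value`.
#' @export
wallenius_test <- function(cat_genes, de_genes, all_genes, weights) {
  cat_genes <- unique(cat_genes)
  de_genes <- unique(de_genes)
  if (!all(cat_genes %in% all_genes)) stop("wallenius_test: category not a subset of universe")
  if (length(cat_genes) == 0L) stop("wallenius_test: empty category")
  n_cat <- length(cat_genes)
  n_tot <- length(all_genes)
  n_de <- length(de_genes)
  x <- length(intersect(cat_genes, de_genes))
  w_in <- mean(weights[cat_genes])
  out_genes <- setdiff(all_genes, cat_genes)
  w_out <- if (length(out_genes)) mean(weights[out_genes]) else w_in
  odds <- w_in / w_out
  p <- pwallenius_upper(x, n_cat, n_tot - n_cat, n_de, odds)
  data.frame(n_de_in_cat = x, n_cat = n_cat, n_de_total = n_de,
             n_genes_total = n_tot, odds = odds, p_value = p)
}

#' Enrichment across all categories with FDR control
#'
#' @param gene2cat data.frame with columns `gene_id`, `category_id`
#'   (duplicate rows are de-duplicated).
#' @param de_flags Named logical vector over the gene universe.
#' @param lengths Named numeric vector of gene lengths.
#' @param fdr Significance level on q-values (default 0.01).
#' @return data.frame ranked by increasing q then p: `category_id`, the
#'   [wallenius_test()] columns, `q_value`, `significant`.
#' @export
enrich_all <- function(gene2cat, de_flags, lengths, fdr = 0.01) {
  stopifnot(all(c("gene_id", "category_id") %in% names(gene2cat)))
  gene2cat <- unique(gene2cat[, c("gene_id", "category_id")])
  all_genes <- names(de_flags)
  gene2cat <- gene2cat[gene2cat$gene_id %in% all_genes, , drop = FALSE]
  w <- fit_pwf(de_flags, lengths)
  de_genes <- all_genes[as.logical(de_flags)]
  cats <- split(gene2cat$gene_id, gene2cat$category_id)
  rows <- lapply(names(cats), function(cid) {
    r <- wallenius_test(cats[[cid]], de_genes, all_genes, w)
    cbind(category_id = cid, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr
  out <- out[order(out$q_value, out$p_value, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
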