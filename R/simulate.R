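## Seeded synthetic-data generator.
##
## Emulates the inputs of a two-condition, pooled-library RNA-seq comparison
## on one linear pseudo-chromosome: an annotation of single-isoform genes, an
## assembly in which some genes carry a second isoform differing by exactly
## one planted splicing event, intergenic novel transcribed units (true ones
## satisfying all five detection criteria, decoys each violating exactly
## one), supporting evidence files, fragment-count tables with planted
## differential usage and expression, and a qPCR Ct table with one planted
## stable control gene.  All randomness flows from one integer seed through
## named per-file substreams, so generated data are byte-reproducible.

SIMPLE_CATEGORIES <- EVENT_CATEGORIES[1:6]

.sub_seed <- function(seed, label) {
  off <- c(annotation = 11L, abundance = 23L, evidence = 37L, ct = 53L,
           genesets = 71L)[[label]]
  (as.integer(seed) * 97L + off) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Defaults are the study conditions exercised throughout the test-suite:
#' 20 two-isoform genes per splicing category, 20 true novel units and 25
#' decoys (five per violated criterion), one pooled library per condition,
#' and a fold-change spectrum spanning every reported bin.
#'
#' @param seed Integer master seed (required).
#' @param n_genes Reference genes (single isoform each).
#' @param events_per_category Two-isoform genes planted per simple category.
#' @param n_novel_tu True intergenic novel units.
#' @param n_decoy_tu Decoy units, cycling through the five criteria.
#' @param n_samples_per_condition Libraries per condition.
#' @param depth Total fragments per library.
#' @param usage_shift Isoform-usage effect size in `[0, 1]` for planted
#'   differential-usage genes.
#' @param prop_usage_genes Fraction of event genes planted as differential
#'   usage.
#' @param de_fold_changes Planted gene-level fold changes (condition B over
#'   A), one gene each; values below 1 plant the reciprocal direction.
#' @param target_ct_folds Planted fold changes of the four qPCR target
#'   genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 200L,
                       events_per_category = 20L,
                       n_novel_tu = 20L,
                       n_decoy_tu = 25L,
                       n_samples_per_condition = 1L,
                       depth = 2e6,
                       usage_shift = 0.4,
                       prop_usage_genes = 0.5,
                       de_fold_changes = c(3, 7, 12, 17, 25, 1/3, 1/7, 1/12, 1/17, 1/25),
                       target_ct_folds = c(8, 2, 0.5, 1)) {
  if (missing(seed)) stop("sim_config: seed is required")
  stopifnot(n_genes >= 6 * events_per_category,
            usage_shift >= 0, usage_shift <= 1,
            depth > 0, n_samples_per_condition >= 1,
            length(target_ct_folds) == 4L)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 events_per_category = as.integer(events_per_category),
                 n_novel_tu = as.integer(n_novel_tu),
                 n_decoy_tu = as.integer(n_decoy_tu),
                 n_samples_per_condition = as.integer(n_samples_per_condition),
                 depth = depth, usage_shift = usage_shift,
                 prop_usage_genes = prop_usage_genes,
                 de_fold_changes = de_fold_changes,
                 target_ct_folds = target_ct_folds),
            class = "sim_config")
}

# mirror a set of exon matrices inside a window [w0, w1); strand flips are
# handled by the caller
.mirror_exons <- function(ex, w0, w1) {
  cbind(start = w0 + (w1 - ex[, "end"]), end = w0 + (w1 - ex[, "start"]))[rev(seq_len(nrow(ex))), , drop = FALSE]
}

# base 4-exon chain (relative coordinates) with generous introns so every
# event template has room; jittered per gene
.base_exons <- function() {
  # exons of 200 bp separated by 600 bp introns
  s <- c(0, 800, 1600, 2400)
  cbind(start = s, end = s + 200)
}

# second isoform differing from `ex` by exactly one simple event (built on
# the + template; minus-strand genes are mirrored afterwards)
.plant_event <- function(ex, category) {
  switch(category,
    exon_skipping = ex[-2L, , drop = FALSE],
    intron_retention = {
      out <- ex[-3L, , drop = FALSE]
      out[2L, "end"] <- ex[3L, "end"]     # exon 2 spans exon2-intron-exon3
      out
    },
    alt_5prime = { out <- ex; out[2L, "end"] <- ex[2L, "end"] + 60; out },
    alt_3prime = { out <- ex; out[2L, "start"] <- ex[2L, "start"] - 60; out },
    mutually_exclusive = {
      out <- ex
      # replace internal exon 2 by a disjoint exon inside the same intron pair
      out[2L, ] <- c(ex[2L, "end"] + 150, ex[2L, "end"] + 350)
      out
    },
    alt_last_exon = {
      out <- ex
      out[4L, ] <- c(ex[4L, "end"] + 200, ex[4L, "end"] + 400)
      out
    },
    stop("unknown category: ", category))
}

#' Generate the reference and assembled annotations with ground truth
#'
#' Reference genes are spaced >= 5000 bp apart on one pseudo-chromosome so
#' the 1000 bp intergenic-distance rule is never ambiguous.  The assembly
#' contains every reference isoform, a second isoform differing by exactly
#' one planted simple event for the first `6 * events_per_category` genes,
#' `n_novel_tu` true intergenic multi-exonic units (>= 1000 bp from all
#' gene boundaries, length >= 250 bp), and `n_decoy_tu` units each violating
#' exactly one of the five detection criteria.
#'
#' @param cfg A [sim_config()].
#' @return A list `reference` (transcript list), `assembled` (transcript
#'   list), `truth` (planted labels; see fields in source).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  withr::with_seed(.sub_seed(cfg$seed, "annotation"), {
    chrom <- "chrS"
    gene_window <- 6000   # widest isoform footprint is < 3200 bp
    spacing <- 5000
    n_ev <- 6L * cfg$events_per_category
    reference <- list(); assembled <- list()
    planted <- character(0)
    gene_span_end <- numeric(cfg$n_genes)
    pos <- 1000
    categories <- rep(SIMPLE_CATEGORIES, each = cfg$events_per_category)
    for (i in seq_len(cfg$n_genes)) {
      gid <- sprintf("G%04d", i)
      strand <- if (i %% 2L == 0L) "-" else "+"
      jit <- sample.int(200L, 1L)
      ex <- .base_exons() + pos + jit
      iso1 <- ex
      iso2 <- NULL
      if (i <= n_ev) {
        cat_i <- categories[i]
        iso2 <- .plant_event(ex, cat_i)
        planted[gid] <- cat_i
      }
      if (strand == "-") {
        w0 <- pos; w1 <- pos + gene_window
        iso1 <- .mirror_exons(iso1, w0, w1)
        if (!is.null(iso2)) iso2 <- .mirror_exons(iso2, w0, w1)
      }
      t1 <- transcript_model(paste0(gid, ".1"), gid, chrom,
                             iso1[, "start"], iso1[, "end"], strand)
      gene_span_end[i] <- genomic_span(t1)[2L]
      reference[[length(reference) + 1L]] <- t1
      assembled[[length(assembled) + 1L]] <- t1
      if (!is.null(iso2))
        assembled[[length(assembled) + 1L]] <-
          transcript_model(paste0(gid, ".2"), gid, chrom,
                           iso2[, "start"], iso2[, "end"], strand)
      pos <- pos + gene_window + spacing
    }
    last_gene_end <- pos - spacing

    # intergenic region for novel units, starting 2000 bp past the genes
    tu_pos <- last_gene_end + 2000
    tu_ids <- character(0); decoy_reason <- character(0)
    mk_tu <- function(id, start, exlen = c(180, 160), intron = 300) {
      s1 <- start; e1 <- s1 + exlen[1L]
      s2 <- e1 + intron; e2 <- s2 + exlen[2L]
      transcript_model(id, id, chrom, c(s1, s2), c(e1, e2), "+")
    }
    for (i in seq_len(cfg$n_novel_tu)) {
      id <- sprintf("NTU%03d", i)
      assembled[[length(assembled) + 1L]] <- mk_tu(id, tu_pos)
      tu_ids <- c(tu_ids, id)
      tu_pos <- tu_pos + 3000
    }
    reasons <- rep(TU_CRITERIA, length.out = cfg$n_decoy_tu)
    k_dist <- 0L
    for (i in seq_len(cfg$n_decoy_tu)) {
      id <- sprintf("DTU%03d", i)
      r <- reasons[i]
      if (r == "distance") {
        # 400 bp downstream of a different exon-skipping gene each time
        # (those isoforms never extend beyond the reference span); violates
        # only the 1000 bp intergenic-distance criterion
        k_dist <- k_dist + 1L
        t <- mk_tu(id, gene_span_end[k_dist] + 400)
      } else if (r == "length") {
        t <- mk_tu(id, tu_pos, exlen = c(90, 80))  # 170 bp < 250
      } else {
        t <- mk_tu(id, tu_pos)
      }
      if (r != "distance") tu_pos <- tu_pos + 3000
      assembled[[length(assembled) + 1L]] <- t
      decoy_reason[id] <- r
    }

    ev_genes <- names(planted)
    n_usage <- round(cfg$prop_usage_genes * length(ev_genes))
    usage_genes <- if (n_usage > 0) sort(sample(ev_genes, n_usage)) else character(0)
    # DE genes: single-isoform genes beyond the event block
    de_pool <- sprintf("G%04d", seq_len(cfg$n_genes))[-seq_len(n_ev)]
    n_de <- min(length(cfg$de_fold_changes), length(de_pool))
    de_genes <- if (n_de > 0) sort(sample(de_pool, n_de)) else character(0)
    de_fc <- setNames(cfg$de_fold_changes[seq_len(n_de)], de_genes)

    truth <- list(
      planted_event_by_gene = planted,
      true_novel_tu_ids = tu_ids,
      decoy_failure_reason = decoy_reason,
      differential_usage_genes = usage_genes,
      de_fold_changes = de_fc,
      stable_control_gene_id = "CTRLSTABLE",
      chrom = chrom,
      last_gene_end = last_gene_end)
    list(reference = reference, assembled = assembled, truth = truth)
  })
}

#' Generate per-sample transcript fragment counts
#'
#' Counts are multinomial at the configured library depth (no
#' overdispersion: the design emulated has one pooled library per
#' condition, so there is no replicate variance to model).  Baseline gene
#' expression weights are log-normal; differential-usage genes shift their
#' isoform proportions from `(p, 1-p)` in condition A to the renormalized
#' `(p + usage_shift * (1 - p), 1 - p)` in condition B; planted DE genes
#' scale their condition-B weight by the planted fold change.
#'
#' @param cfg A [sim_config()].
#' @param annot Output of [generate_annotation()] run with the same `cfg`.
#' @return A count-table list (as from [read_counts()]) with conditions
#'   `"A"` and `"B"`; a `warning_low_depth` attribute lists planted
#'   transcripts whose expected count falls below 1.
#' @export
generate_abundances <- function(cfg, annot) {
  stopifnot(is(cfg, "sim_config"))
  truth <- annot$truth
  txs <- annot$assembled
  withr::with_seed(.sub_seed(cfg$seed, "abundance"), {
    tid <- vapply(txs, function(t) t$transcript_id, character(1))
    gid <- vapply(txs, function(t) t$gene_id, character(1))
    len <- vapply(txs, exonic_length, numeric(1))
    genes <- unique(gid)
    gw <- setNames(rlnorm(length(genes), meanlog = 0, sdlog = 0.3), genes)
    # isoform base proportions for two-isoform genes
    two_iso <- names(which(table(gid) == 2L))
    p_base <- setNames(runif(length(two_iso), 0.3, 0.7), two_iso)

    weight_for <- function(cond) {
      w <- numeric(length(txs))
      for (g in genes) {
        i <- which(gid == g)
        base <- gw[[g]]
        if (cond == "B" && g %in% names(truth$de_fold_changes))
          base <- base * truth$de_fold_changes[[g]]
        if (length(i) == 1L) { w[i] <- base; next }
        p <- p_base[[g]]
        pr <- c(p, 1 - p)
        if (cond == "B" && g %in% truth$differential_usage_genes) {
          pr <- c(p + cfg$usage_shift * (1 - p), 1 - p)
          pr <- pr / sum(pr)
        }
        w[i] <- base * pr
      }
      w / sum(w)
    }
    conds <- c("A", "B")
    cols <- list(); cn <- character(0)
    low <- character(0)
    for (cond in conds) {
      pr <- weight_for(cond)
      low <- union(low, tid[pr * cfg$depth < 1 &
                              (gid %in% names(truth$planted_event_by_gene) |
                                 gid %in% truth$true_novel_tu_ids)])
      for (s in seq_len(cfg$n_samples_per_condition)) {
        cols[[length(cols) + 1L]] <- as.numeric(rmultinom(1L, cfg$depth, pr))
        cn <- c(cn, sprintf("%s:s%d", cond, s))
      }
    }
    m <- do.call(cbind, cols)
    dimnames(m) <- list(tid, cn)
    if (length(low))
      warning("expected count < 1 for planted transcript(s): ",
              paste(head(low, 5L), collapse = ", "))
    out <- list(counts = m, feature_id = tid, gene_id = gid, length = len,
                condition = sub(":.*$", "", cn), sample = cn)
    attr(out, "warning_low_depth") <- low
    out
  })
}

#' Generate repeat, EST, junction, and coverage evidence
#'
#' True novel units receive >= 5 ESTs jointly covering all exonic bases,
#' junction support >= 2 at every intron, coverage >= 5 and no repeat
#' overlap.  Each decoy's evidence violates only its designated criterion.
#'
#' @param cfg A [sim_config()].
#' @param annot Output of [generate_annotation()].
#' @return A list: `repeats` (BED-style data.frame), `ests` (BED12-style
#'   data.frame with `blocks`), `junctions`, `coverage` (data.frames).
#' @export
generate_evidence <- function(cfg, annot) {
  stopifnot(is(cfg, "sim_config"))
  truth <- annot$truth
  withr::with_seed(.sub_seed(cfg$seed, "evidence"), {
    txs <- annot$assembled
    tid <- vapply(txs, function(t) t$transcript_id, character(1))
    is_tu <- tid %in% c(truth$true_novel_tu_ids, names(truth$decoy_failure_reason))
    reason <- truth$decoy_failure_reason

    repeats <- NULL; ests <- NULL; junctions <- NULL
    coverage <- data.frame(transcript_id = character(0), mean_coverage = numeric(0))
    est_i <- 0L
    for (k in which(is_tu)) {
      t <- txs[[k]]
      r <- if (tid[k] %in% names(reason)) reason[[tid[k]]] else "none"
      cov <- if (r == "coverage") 3 else round(runif(1, 6, 20), 2)
      coverage <- rbind(coverage, data.frame(transcript_id = tid[k],
                                             mean_coverage = cov))
      intr <- derive_introns(t)
      supp <- if (r == "junction_support") 1L else sample(2:6, nrow(intr), replace = TRUE)
      if (nrow(intr))
        junctions <- rbind(junctions, data.frame(
          chrom = t$chrom, donor_end = intr[, "start"],
          acceptor_start = intr[, "end"], strand = t$strand,
          support_count = supp))
      if (r == "repeat_fraction") {
        # repeat covering 60% of the first exon span plus part of the second
        tot <- exonic_length(t)
        need <- ceiling(0.6 * tot)
        e1 <- t$exons[1L, ]
        take1 <- min(need, e1[["end"]] - e1[["start"]])
        repeats <- rbind(repeats, data.frame(chrom = t$chrom,
                                             start = e1[["start"]],
                                             end = e1[["start"]] + take1))
        if (need > take1) {
          e2 <- t$exons[2L, ]
          repeats <- rbind(repeats, data.frame(chrom = t$chrom,
                                               start = e2[["start"]],
                                               end = e2[["start"]] + (need - take1)))
        }
      }
      if (tid[k] %in% truth$true_novel_tu_ids) {
        for (j in seq_len(sample(5:7, 1L))) {
          est_i <- est_i + 1L
          ests <- rbind(ests, data.frame(
            chrom = t$chrom, start = t$exons[1L, "start"], end = t$exons[nrow(t$exons), "end"],
            name = sprintf("EST%04d", est_i), strand = t$strand,
            block_starts = paste(t$exons[, "start"] - t$exons[1L, "start"], collapse = ","),
            block_sizes = paste(t$exons[, "end"] - t$exons[, "start"], collapse = ","),
            stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(repeats))
      repeats <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    if (is.null(junctions))
      junctions <- data.frame(chrom = character(0), donor_end = numeric(0),
                              acceptor_start = numeric(0), strand = character(0),
                              support_count = numeric(0))
    est_df <- if (is.null(ests)) {
      z <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      name = character(0), strand = character(0))
      z$blocks <- list()
      z
    } else {
      bl <- lapply(seq_len(nrow(ests)), function(i) {
        ss <- as.numeric(strsplit(ests$block_starts[i], ",")[[1L]]) + ests$start[i]
        sz <- as.numeric(strsplit(ests$block_sizes[i], ",")[[1L]])
        cbind(start = ss, end = ss + sz)
      })
      z <- ests[, c("chrom", "start", "end", "name", "strand")]
      z$blocks <- bl
      z
    }
    rownames(repeats) <- rownames(junctions) <- rownames(coverage) <- NULL
    list(repeats = repeats, ests = est_df, junctions = junctions,
         coverage = coverage)
  })
}

#' Generate a qPCR Ct table with a planted stable control
#'
#' One stable control gene tracks per-sample loading exactly up to Gaussian
#' noise (sd 0.05 cycles); two unstable candidates add sample-specific
#' shifts (sd 0.5 cycles) and opposite condition-level regulation
#' (`unstable_cond_shift` cycles), the signature of a reference gene that
#' responds to treatment; four target genes carry the planted condition
#' fold changes of `cfg$target_ct_folds`.  Five samples per condition, as
#' in a five-embryo validation panel.
#'
#' @param cfg A [sim_config()].
#' @param sd_stable,sd_unstable,sd_target Noise levels in Ct cycles.
#' @param unstable_cond_shift Condition effect (+/- cycles) applied with
#'   opposite sign to the two unstable candidates.
#' @return A Ct-table list (as from [read_ct()]).  Gene ids: `CTRLSTABLE`,
#'   `CTRLU1`, `CTRLU2`, `TGT1`..`TGT4`.
#' @export
generate_ct_table <- function(cfg, sd_stable = 0.05, sd_unstable = 0.5,
                              sd_target = 0.05, unstable_cond_shift = 0.75) {
  stopifnot(is(cfg, "sim_config"))
  withr::with_seed(.sub_seed(cfg$seed, "ct"), {
    n_per <- 5L
    cond <- rep(c("A", "B"), each = n_per)
    samp <- sprintf("%s:e%d", cond, rep(seq_len(n_per), 2L))
    loading <- 2^rnorm(length(samp), 0, 0.5)   # per-sample input amount
    base <- c(CTRLSTABLE = 22, CTRLU1 = 24, CTRLU2 = 20,
              TGT1 = 26, TGT2 = 27, TGT3 = 25, TGT4 = 28)
    ct <- matrix(0, nrow = length(base), ncol = length(samp),
                 dimnames = list(names(base), samp))
    ct["CTRLSTABLE", ] <- base["CTRLSTABLE"] - log2(loading) +
      rnorm(length(samp), 0, sd_stable)
    cshift <- ifelse(cond == "B", unstable_cond_shift, -unstable_cond_shift)
    ct["CTRLU1", ] <- base["CTRLU1"] - log2(loading) + cshift +
      rnorm(length(samp), 0, sd_unstable)
    ct["CTRLU2", ] <- base["CTRLU2"] - log2(loading) - cshift +
      rnorm(length(samp), 0, sd_unstable)
    for (i in 1:4) {
      g <- sprintf("TGT%d", i)
      fold <- cfg$target_ct_folds[i]
      ct[g, ] <- base[g] - log2(loading) - ifelse(cond == "B", log2(fold), 0) +
        rnorm(length(samp), 0, sd_target)
    }
    list(ct = ct, condition = cond, sample = samp)
  })
}

#' Generate a gene-to-category map with one planted enriched category
#'
#' Categories are sampled uniformly at random over the gene universe except
#' `CAT_ENRICHED`, which preferentially contains planted DE genes.  Used to
#' exercise the enrichment stage end-to-end.
#'
#' @param cfg A [sim_config()].
#' @param annot Output of [generate_annotation()].
#' @param n_categories Number of random categories.
#' @param cat_size Genes per category.
#' @return data.frame `gene_id`, `category_id`.
#' @export
generate_gene_sets <- function(cfg, annot, n_categories = 20L, cat_size = 25L) {
  stopifnot(is(cfg, "sim_config"))
  withr::with_seed(.sub_seed(cfg$seed, "genesets"), {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    de <- names(annot$truth$de_fold_changes)
    rows <- lapply(seq_len(n_categories), function(i)
      data.frame(gene_id = sample(genes, min(cat_size, length(genes))),
                 category_id = sprintf("CAT%03d", i)))
    enriched <- data.frame(
      gene_id = unique(c(de, sample(genes, max(cat_size - length(de), 3L)))),
      category_id = "CAT_ENRICHED")
    out <- rbind(do.call(rbind, rows), enriched)
    rownames(out) <- NULL
    out
  })
}

#' Simulate length-biased differential-expression calls with null categories
#'
#' Emulates the selection bias that motivates the Wallenius enrichment
#' model: gene lengths are log-normal, the probability of a gene being
#' called DE increases with log-length (logistic, slope `slope` per SD of
#' log-length), and every category is drawn with probability proportional
#' to gene length — so no category is truly enriched, yet long-gene
#' categories are spuriously enriched under a central hypergeometric test.
#'
#' @param seed Integer seed.
#' @param n_genes Universe size.
#' @param n_categories Number of null categories.
#' @param cat_size Genes per category.
#' @param slope Logistic slope of DE propensity per SD of log-length.
#' @param intercept Logistic intercept (controls the overall DE fraction).
#' @return A list: `de_flags` (named logical), `lengths` (named), and
#'   `categories` (list of gene-id vectors).
#' @export
generate_length_bias_sim <- function(seed, n_genes = 2000L, n_categories = 400L,
                                     cat_size = 150L, slope = 0.8,
                                     intercept = -2.2) {
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("g%05d", seq_len(n_genes))
    lengths <- setNames(round(rlnorm(n_genes, log(2000), 0.6)), genes)
    z <- as.numeric(scale(log(lengths)))
    de <- setNames(runif(n_genes) < plogis(intercept + slope * z), genes)
    cats <- lapply(seq_len(n_categories), function(i)
      sample(genes, cat_size, prob = lengths))
    names(cats) <- sprintf("NULLCAT%03d", seq_len(n_categories))
    list(de_flags = de, lengths = lengths, categories = cats)
  })
}

#' Write a complete synthetic scenario to disk
#'
#' Emits `reference.gtf`, `assembled.gtf`, `repeats.bed`, `ests.bed`
#' (BED12), `junctions.tsv`, `coverage.tsv`, `counts.tsv`, `ct.tsv`,
#' `go.tsv`, `lengths.tsv` and `truth.json` under `outdir`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly; the in-memory scenario as attribute
#'   `"scenario"`.
#' @export
simulate_scenario <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  annot <- generate_annotation(cfg)
  counts <- suppressWarnings(generate_abundances(cfg, annot))
  ev <- generate_evidence(cfg, annot)
  ctt <- generate_ct_table(cfg)
  g2c <- generate_gene_sets(cfg, annot)

  write_gtf(annot$reference, file.path(outdir, "reference.gtf"))
  write_gtf(annot$assembled, file.path(outdir, "assembled.gtf"))

  .write_tsv <- function(df, f) write.table(df, file.path(outdir, f),
                                            sep = "\t", quote = FALSE, row.names = FALSE)
  rep_bed <- ev$repeats
  writeLines(if (nrow(rep_bed)) sprintf("%s\t%d\t%d", rep_bed$chrom,
                                        as.integer(rep_bed$start),
                                        as.integer(rep_bed$end)) else character(0),
             file.path(outdir, "repeats.bed"))
  est <- ev$ests
  est_lines <- if (nrow(est)) vapply(seq_len(nrow(est)), function(i) {
    b <- est$blocks[[i]]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            est$chrom[i], as.integer(est$start[i]), as.integer(est$end[i]),
            est$name[i], est$strand[i], as.integer(est$start[i]),
            as.integer(est$end[i]), nrow(b),
            paste0(paste(as.integer(b[, "end"] - b[, "start"]), collapse = ","), ","),
            paste0(paste(as.integer(b[, "start"] - est$start[i]), collapse = ","), ","))
  }, character(1)) else character(0)
  writeLines(est_lines, file.path(outdir, "ests.bed"))
  .write_tsv(ev$junctions, "junctions.tsv")
  .write_tsv(ev$coverage, "coverage.tsv")

  cdf <- data.frame(feature_id = counts$feature_id, gene_id = counts$gene_id,
                    length = counts$length, check.names = FALSE)
  cdf <- cbind(cdf, as.data.frame(counts$counts, check.names = FALSE))
  .write_tsv(cdf, "counts.tsv")

  ctdf <- cbind(data.frame(gene_id = rownames(ctt$ct)),
                as.data.frame(ctt$ct, check.names = FALSE))
  .write_tsv(ctdf, "ct.tsv")
  .write_tsv(g2c, "go.tsv")

  glen <- tapply(counts$length, counts$gene_id, max)
  .write_tsv(data.frame(gene_id = names(glen), length = as.numeric(glen)),
             "lengths.tsv")
  jsonlite::write_json(annot$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- outdir
  attr(out, "scenario") <- list(annot = annot, counts = counts, evidence = ev,
                                ct = ctt, gene2cat = g2c)
  invisible(out)
}
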