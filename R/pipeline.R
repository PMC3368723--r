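## End-to-end orchestration: novel-TU discovery, splicing classification,
## quantification, differential expression and usage, enrichment, qPCR,
## consolidated into one deterministic report.

#' Pipeline run configuration
#'
#' @param reference_gtf,assembled_gtf,counts_tsv Required input paths.
#' @param repeats_bed,ests_bed,junctions_tsv,coverage_tsv Novel-TU evidence
#'   paths (all required for the novel-TU stage).
#' @param gene2cat_tsv,lengths_tsv Optional enrichment inputs (columns
#'   `gene_id`/`category_id` and `gene_id`/`length`).
#' @param ct_tsv,ct_candidates,ct_targets Optional qPCR inputs: Ct table
#'   path, candidate control genes (>= 3), target genes.
#' @param de_fdr,splice_fdr,enrich_fdr FDR thresholds (defaults 0.05, 0.05,
#'   0.01).
#' @param expression_threshold FPKM threshold for expression calls.
#' @param n_boot Bootstrap resamples for the usage test.
#' @param seed Integer seed (required; the usage bootstrap is the only
#'   stochastic stage).
#' @return A `run_config` list.
#' @export
run_config <- function(reference_gtf, assembled_gtf, counts_tsv,
                       repeats_bed = NULL, ests_bed = NULL,
                       junctions_tsv = NULL, coverage_tsv = NULL,
                       gene2cat_tsv = NULL, lengths_tsv = NULL,
                       ct_tsv = NULL, ct_candidates = NULL, ct_targets = NULL,
                       de_fdr = 0.05, splice_fdr = 0.05, enrich_fdr = 0.01,
                       expression_threshold = 0.5, n_boot = 999L, seed) {
  if (missing(seed)) stop("run_config: seed is required")
  stopifnot(de_fdr > 0, de_fdr < 1, splice_fdr > 0, splice_fdr < 1,
            enrich_fdr > 0, enrich_fdr < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of [run_config()];
#'   relative input paths are resolved against the file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_run_config requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  for (f in grep("(_gtf|_tsv|_bed)$", names(y), value = TRUE))
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]])) y[[f]] <- file.path(dir, y[[f]])
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Stages: novel-TU discovery and filtering; single-TSS splicing event
#' classification and summary; FPKM quantification with upper-quartile
#' normalization and exclusive-expression calls; differential expression
#' (binomial, no replicates) with fold-change binning; Jensen-Shannon
#' differential usage with the splicing/expression decomposition;
#' optionally enrichment and qPCR stages.  Identical config plus inputs
#' yield a byte-identical `report.json`.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory for `report.json` and stage TSVs.
#' @return The report, invisibly.
#' @export
run_all <- function(cfg, outdir) {
  stopifnot(is(cfg, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  report <- list(
    tool = "splicescape",
    thresholds = list(de_fdr = cfg$de_fdr, splice_fdr = cfg$splice_fdr,
                      enrich_fdr = cfg$enrich_fdr,
                      expression_threshold = cfg$expression_threshold,
                      n_boot = cfg$n_boot, seed = cfg$seed),
    inputs = list(reference_gtf = basename(cfg$reference_gtf),
                  assembled_gtf = basename(cfg$assembled_gtf)))

  reference <- stage("read_reference", read_gtf(cfg$reference_gtf))
  assembled <- stage("read_assembled", read_gtf(cfg$assembled_gtf))

  # -- novel transcribed units ------------------------------------------
  if (!is.null(cfg$repeats_bed)) {
    tu <- stage("novel_tu", {
      cand <- candidate_units(assembled, reference)
      cand <- annotate_evidence(cand, read_bed(cfg$repeats_bed),
                                read.delim(cfg$junctions_tsv),
                                read.delim(cfg$coverage_tsv))
      cand <- est_support(cand, read_bed(cfg$ests_bed))
      filter_novel_tus(cand)
    })
    write.table(tu$table, file.path(outdir, "novel_tu.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$novel_tu <- list(
      n_candidates = nrow(tu$table),
      n_accepted = sum(tu$table$accepted),
      n_supported = sum(tu$table$accepted & tu$table$supported),
      accepted_ids = sort(tu$table$unit_id[tu$table$accepted]))
  }

  # -- alternative splicing classification ------------------------------
  events <- stage("as_events", {
    genes <- select_single_tss_genes(group_genes(assembled))
    ev <- do.call(rbind, lapply(genes, classify_gene))
    if (is.null(ev)) ev <- .event_df()
    rownames(ev) <- NULL
    ev
  })
  write.table(events, file.path(outdir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ev_sum <- summarize_events(events)
  write.table(ev_sum, file.path(outdir, "event_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$splicing <- list(
    n_single_tss_multi_isoform = length(select_single_tss_genes(group_genes(assembled))),
    event_summary = ev_sum,
    dedup_rule = "(category, locus)")

  # -- quantification ----------------------------------------------------
  tbl <- stage("quantify", read_counts(cfg$counts_tsv))
  gf <- stage("quantify", gene_fpkm(tbl, normalize = TRUE))
  factors <- attr(gf, "factors")
  conds <- unique(tbl$condition)
  calls <- call_expression(gf[[conds[1L]]], gf[[conds[2L]]],
                           cfg$expression_threshold)
  write.table(cbind(gf, calls), file.path(outdir, "fpkm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = tbl$sample, factor = as.numeric(factors)),
              file.path(outdir, "factors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # -- differential expression ------------------------------------------
  # effective library sizes: raw depth times the FPKM upper-quartile
  # factor, so composition shifts from strongly-DE genes do not bleed into
  # every null gene's test
  eff_sizes <- colSums(tbl$counts) * factors / mean(factors)
  de <- stage("diff_expression",
              run_expression_tests(tbl, fdr = cfg$de_fdr, sizes = eff_sizes))
  write.table(de, file.path(outdir, "de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sig <- de$gene_id[de$significant]
  gidx <- match(de$gene_id, gf$gene_id)
  fa <- gf[[conds[1L]]][gidx]; fb <- gf[[conds[2L]]][gidx]
  excl_a <- de$gene_id[de$significant & calls$exclusive_a[gidx]]
  excl_b <- de$gene_id[de$significant & calls$exclusive_b[gidx]]
  both <- de$significant & calls$expressed_a[gidx] & calls$expressed_b[gidx]
  fold <- ifelse(fb[both] >= fa[both], fb[both] / fa[both], fa[both] / fb[both])
  dirn <- ifelse(fb[both] >= fa[both], conds[2L], conds[1L])
  bins <- if (any(both)) bin_fold_changes(fold, dirn) else NULL
  report$expression <- list(
    n_tested = nrow(de), n_de = length(sig),
    n_exclusive_a = length(excl_a), n_exclusive_b = length(excl_b),
    fold_change_bins = bins)
  if (!is.null(bins))
    write.table(cbind(direction = rownames(bins), bins),
                file.path(outdir, "fold_bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  # -- differential usage ------------------------------------------------
  single_tss <- names(select_single_tss_genes(group_genes(assembled)))
  usage <- stage("diff_usage", run_usage_tests(
    tbl, n_boot = cfg$n_boot, seed = cfg$seed, genes = single_tss,
    fdr = cfg$splice_fdr))
  write.table(usage, file.path(outdir, "usage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  us <- usage$gene_id[usage$significant]
  report$usage <- list(
    n_tested = nrow(usage), n_significant = length(us),
    n_splicing_and_de = length(intersect(us, sig)),
    n_splicing_without_de = length(setdiff(us, sig)))

  # -- enrichment --------------------------------------------------------
  if (!is.null(cfg$gene2cat_tsv)) {
    enr <- stage("enrichment", {
      g2c <- read.delim(cfg$gene2cat_tsv, stringsAsFactors = FALSE)
      lens <- read.delim(cfg$lengths_tsv, stringsAsFactors = FALSE)
      de_flags <- setNames(de$significant, de$gene_id)
      lengths <- setNames(lens$length, lens$gene_id)
      enrich_all(g2c, de_flags, lengths[names(de_flags)], fdr = cfg$enrich_fdr)
    })
    write.table(enr, file.path(outdir, "enrich.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$enrichment <- list(
      n_categories = nrow(enr), n_significant = sum(enr$significant),
      top_category = if (nrow(enr)) enr$category_id[1L] else NA)
  }

  # -- qPCR --------------------------------------------------------------
  if (!is.null(cfg$ct_tsv)) {
    qp <- stage("qpcr", {
      ctt <- read_ct(cfg$ct_tsv)
      stab <- stability_m(ctt$ct, cfg$ct_candidates)
      ref <- select_reference(stab)
      cnds <- unique(ctt$condition)
      folds <- lapply(cfg$ct_targets, function(g)
        ddct_fold_change(ctt, g, ref, cnds[1L], cnds[2L]))
      list(stability = stab, reference = ref,
           folds = data.frame(
             target = cfg$ct_targets,
             ddct = vapply(folds, `[[`, numeric(1), "ddct"),
             fold = vapply(folds, `[[`, numeric(1), "fold")))
    })
    write.table(qp$folds, file.path(outdir, "qpcr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$qpcr <- list(stability = qp$stability, reference = qp$reference,
                        folds = qp$folds)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
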