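#' Pipeline configuration
#'
#' Surfaces every analysis threshold in one object. Defaults are the
#' pipeline's standard operating point: |log2FC| >= 1 and FDR <= 0.05 for
#' mRNA/lncRNA, linear FC >= 1.5 / <= 0.667 for miRNA, PWM p < 5e-4 with at
#' most 4 consensus mismatches for ERE detection over a 500 bp window per
#' site, the < 50 kb strict upstream rule for direct targets (requiring an
#' ERE in the supporting site), and a 2-of-3 predictor consensus.
#'
#' @param lfc,fdr,mirna_fc,mirna_fc_down DE thresholds (see
#'   \code{\link{call_de}}).
#' @param p_threshold,max_mismatch,window ERE scan settings (see
#'   \code{\link{scan_peaks}}).
#' @param max_upstream,require_ere direct-target rule (see
#'   \code{\link{call_direct_targets}}).
#' @param min_votes consensus vote threshold (see
#'   \code{\link{consensus_pairs}}).
#' @param merge_peaks merge overlapping/abutting peaks before scanning.
#' @return a named list of settings.
#' @export
pipeline_config <- function(lfc = 1, fdr = 0.05, mirna_fc = 1.5,
                            mirna_fc_down = 0.667, p_threshold = 5e-4,
                            max_mismatch = 4, window = 500,
                            max_upstream = 50000, require_ere = TRUE,
                            min_votes = 2, merge_peaks = FALSE) {
  as.list(environment())
}

#' Run the full direct-target pipeline on an input bundle
#'
#' Executes the stages in dependency order — input parsing, ERE scanning,
#' site classification, peak localization, DE calling, direct-target
#' calling, lncRNA filtering, consensus network, qPCR summaries — and
#' assembles a report of the headline tallies. Stage outputs are written as
#' TSV/JSON under \code{out_dir} when given. The run is deterministic: the
#' report carries an md5 hash of its own content, identical across reruns
#' on the same inputs and config.
#'
#' @param bundle_dir directory holding the standard input files (as written
#'   by \code{\link{simulate_bundle}}): genome.fa, genes.gtf, peaks.bed,
#'   de_genes.tsv, predictor*.tsv, transcripts.tsv(+.fa), qpcr_ct.tsv,
#'   chip_ct.tsv. Optional files may be absent; the matching stages are
#'   skipped.
#' @param out_dir optional output directory for stage files and the report.
#' @param config a \code{\link{pipeline_config}}.
#' @param motif the scanning motif (default \code{\link{ere_motif}()}).
#' @return a \code{pipeline_report} list (invisibly writes files when
#'   \code{out_dir} is set).
#' @export
run_pipeline <- function(bundle_dir, out_dir = NULL,
                         config = pipeline_config(), motif = ere_motif()) {
  pth <- function(f) file.path(bundle_dir, f)
  need <- c("genome.fa", "genes.gtf", "peaks.bed", "de_genes.tsv")
  miss <- need[!file.exists(pth(need))]
  if (length(miss) > 0)
    stopf("bundle is missing required input(s): %s",
          paste(miss, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  genome <- stage("io", read_genome_fasta(pth("genome.fa")))
  gm <- stage("io", read_gtf(pth("genes.gtf")))
  peaks <- stage("io", read_peaks(pth("peaks.bed")))
  if (isTRUE(config$merge_peaks)) peaks <- merge_peaks(peaks)
  pattern <- consensus_pattern(max_mismatch = config$max_mismatch)
  hits <- stage("scan",
                scan_peaks(genome, peaks, motif = motif, pattern = pattern,
                           p_threshold = config$p_threshold,
                           window = config$window))
  sites <- stage("classify", classify_sites(peaks, hits))
  ann <- if (length(peaks) > 0)
    stage("annotate", annotate_peaks(peaks, gm)) else NULL
  loc <- if (!is.null(ann)) localization_summary(ann) else NULL
  de <- stage("de", call_de(read_de_table(pth("de_genes.tsv")),
                            lfc = config$lfc, fdr = config$fdr,
                            mirna_fc = config$mirna_fc,
                            mirna_fc_down = config$mirna_fc_down))
  targets <- stage("direct_targets",
                   call_direct_targets(de, peaks, gm, hits = hits,
                                       max_upstream = config$max_upstream,
                                       require_ere = config$require_ere))
  lnc <- NULL
  if (file.exists(pth("transcripts.tsv"))) {
    seqs <- if (file.exists(pth("transcripts.fa")))
      read_genome_fasta(pth("transcripts.fa")) else NULL
    lnc <- stage("lncrna",
                 filter_lncrna(read_tsv_strict(pth("transcripts.tsv")),
                               seqs))
  }
  network <- NULL
  pred_files <- Sys.glob(file.path(bundle_dir, "predictor*.tsv"))
  if (length(pred_files) >= 2) {
    tables <- lapply(pred_files, read_tsv_strict,
                     required = c("mirna_id", "gene_id"))
    names(tables) <- sub("\\.tsv$", "", basename(pred_files))
    pairs <- stage("network",
                   consensus_pairs(tables, min_votes = config$min_votes))
    network <- stage("network", build_network(pairs, de))
  }
  qpcr <- NULL
  if (file.exists(pth("qpcr_ct.tsv"))) {
    ct <- read_tsv_strict(pth("qpcr_ct.tsv"),
                          c("sample_id", "group", "ct_target",
                            "ct_reference"))
    split_by <- if ("target" %in% names(ct)) ct$target else "target"
    qpcr <- stage("qpcr", lapply(split(ct, split_by), function(x) {
      r <- ddct_fold_change(x)
      r$group[r$group$group == "treated", , drop = FALSE]
    }))
  }
  chip <- NULL
  if (file.exists(pth("chip_ct.tsv"))) {
    cc <- read_tsv_strict(pth("chip_ct.tsv"),
                          c("ct_ip", "ct_input", "ct_igg"))
    fr <- if ("input_fraction" %in% names(cc)) cc$input_fraction else 0.2
    chip <- stage("chip", cbind(
      locus_id = if ("locus_id" %in% names(cc)) cc$locus_id
                 else sprintf("locus_%d", seq_len(nrow(cc))),
      chip_fold_enrichment(cc$ct_ip, cc$ct_input, cc$ct_igg, fr)))
  }
  resp <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  class_counts <- do.call(rbind, lapply(
    c("mRNA", "lncRNA", "miRNA"), function(bt)
      data.frame(class = bt,
                 up = sum(resp$biotype == bt & resp$direction == "up"),
                 down = sum(resp$biotype == bt & resp$direction == "down"),
                 stringsAsFactors = FALSE)))
  totals <- summarize_counts(class_counts)
  report <- list(
    n_peaks = length(peaks),
    n_ere_hits = nrow(hits),
    site_classification = list(
      counts = as.list(sites$counts),
      fraction_with_ere = sites$fraction_with_ere),
    localization = loc,
    responsive = list(per_class = class_counts,
                      class_totals = totals$class_totals,
                      total = totals$total),
    n_direct_targets = nrow(targets),
    direct_target_genes = targets$gene_id,
    network_edges = if (!is.null(network)) nrow(network$edges) else NA,
    lncrna_passing = if (!is.null(lnc)) length(lnc$passing) else NA,
    qpcr_treated_mean_folds = if (!is.null(qpcr))
      lapply(qpcr, function(g) g$mean_fold) else NULL,
    chip_fold_enrichment = if (!is.null(chip))
      stats::setNames(as.list(chip$fold_enrichment), chip$locus_id)
      else NULL,
    config = config)
  report$report_hash <- report_hash(report)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits(hits, file.path(out_dir, "ere_hits.bed"),
               file.path(out_dir, "ere_hits.tsv"))
    write_tsv(sites$per_peak, file.path(out_dir, "site_classification.tsv"))
    if (!is.null(ann)) write_tsv(ann, file.path(out_dir, "annotations.tsv"))
    if (!is.null(loc)) write_tsv(loc, file.path(out_dir, "localization.tsv"))
    write_tsv(de, file.path(out_dir, "de_called.tsv"))
    write_tsv(targets, file.path(out_dir, "direct_targets.tsv"))
    if (!is.null(lnc))
      write_tsv(lnc$trace, file.path(out_dir, "lncrna_trace.tsv"))
    if (!is.null(network)) {
      write_tsv(network$edges, file.path(out_dir, "network_edges.tsv"))
      write_tsv(network$nodes, file.path(out_dir, "network_nodes.tsv"))
      write_network_graphml(network,
                            file.path(out_dir, "network.graphml"))
    }
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
    writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

report_hash <- function(report) {
  report$report_hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Summation-only consistency check over per-class DE counts
#'
#' Computes class totals and the grand total of responsive genes purely by
#' summation of the supplied up/down counts. When expected totals are
#' supplied they are verified and any discrepancy is an error naming the
#' offending class.
#'
#' @param class_counts data.frame with columns class, up, down.
#' @param expected_class_totals optional named vector of per-class totals.
#' @param expected_total optional grand total.
#' @return list with \code{class_totals} (named) and \code{total}.
#' @export
summarize_counts <- function(class_counts, expected_class_totals = NULL,
                             expected_total = NULL) {
  miss <- setdiff(c("class", "up", "down"), names(class_counts))
  if (length(miss) > 0)
    stopf("class_counts missing column(s): %s", paste(miss, collapse = ", "))
  class_totals <- stats::setNames(class_counts$up + class_counts$down,
                                  class_counts$class)
  total <- sum(class_totals)
  if (!is.null(expected_class_totals)) {
    for (cl in names(expected_class_totals)) {
      if (!cl %in% names(class_totals))
        stopf("no such class in the counts: %s", cl)
      if (class_totals[cl] != expected_class_totals[cl])
        stopf("inconsistent sums for class %s: %d + %d = %d, expected %d",
              cl, class_counts$up[class_counts$class == cl],
              class_counts$down[class_counts$class == cl],
              class_totals[cl], expected_class_totals[cl])
    }
  }
  if (!is.null(expected_total) && total != expected_total)
    stopf("inconsistent grand total: sum of class totals is %d, expected %d",
          total, expected_total)
  list(class_totals = class_totals, total = total)
}

format_report_md <- function(r) {
  c("# Pipeline report", "",
    sprintf("- binding sites: %d (%d ERE hits; with ERE: %.1f%%)",
            r$n_peaks, r$n_ere_hits,
            100 * r$site_classification$fraction_with_ere),
    sprintf("- responsive genes: %d (%s)", r$responsive$total,
            paste(sprintf("%s %d", names(r$responsive$class_totals),
                          r$responsive$class_totals), collapse = ", ")),
    sprintf("- direct targets: %d", r$n_direct_targets),
    sprintf("- network edges: %s", r$network_edges),
    sprintf("- report hash: %s", r$report_hash))
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(format_report_md(x))
  invisible(x)
}
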