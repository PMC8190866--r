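#' Read a differential-expression table
#'
#' TSV with header columns gene_id, biotype (mRNA/lncRNA/miRNA), effect
#' (log2 fold change for mRNA/lncRNA, linear fold change for miRNA) and fdr.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  read_tsv_strict(path, c("gene_id", "biotype", "effect", "fdr"))
}

#' Call estrogen-responsive genes from a DE table
#'
#' Applies the printed thresholds, all inclusive at the boundary: mRNA and
#' lncRNA are up when log2FC >= \code{lfc} and FDR <= \code{fdr}, down when
#' log2FC <= -\code{lfc}; miRNA (linear fold change) are up when
#' FC >= \code{mirna_fc}, down when FC <= \code{mirna_fc_down}. Everything
#' else is \code{ns}. Idempotent.
#'
#' @param de data.frame with gene_id, biotype, effect, fdr.
#' @param lfc absolute log2 fold-change threshold for mRNA/lncRNA.
#' @param fdr FDR ceiling for all classes.
#' @param mirna_fc,mirna_fc_down linear fold-change thresholds for miRNA
#'   (kept as printed: 1.5 and 0.667, not 2/3 exactly).
#' @return the input with a \code{direction} column in \{up, down, ns\}.
#' @export
call_de <- function(de, lfc = 1, fdr = 0.05, mirna_fc = 1.5,
                    mirna_fc_down = 0.667) {
  miss <- setdiff(c("gene_id", "biotype", "effect", "fdr"), names(de))
  if (length(miss) > 0)
    stopf("DE table missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(de$biotype %in% c("mRNA", "lncRNA", "miRNA")))
    stopf("biotype must be mRNA, lncRNA or miRNA")
  mir <- de$biotype == "miRNA"
  if (any(mir & de$effect <= 0))
    stopf("miRNA fold change must be positive (gene %s)",
          de$gene_id[which(mir & de$effect <= 0)[1]])
  sig <- de$fdr <= fdr
  up <- ifelse(mir, de$effect >= mirna_fc, de$effect >= lfc) & sig
  down <- ifelse(mir, de$effect <= mirna_fc_down, de$effect <= -lfc) & sig
  de$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  de
}

#' Call genes directly targeted via ERE-containing binding sites
#'
#' An estrogen-responsive gene (direction up or down) is a direct target iff
#' at least one qualifying binding site has its summit less than
#' \code{max_upstream} bp (strict) upstream, strand-aware, of any of the
#' gene's TSSs (distance 0, summit exactly at a TSS, qualifies). By default a
#' qualifying site must contain an ERE (\code{require_ere = TRUE});
#' \code{require_ere = FALSE} relaxes to any binding site.
#'
#' @param de a DE table with directions set (run \code{\link{call_de}} first).
#' @param peaks a peaks \code{GRanges}.
#' @param gm a \code{\link{gene_models}} object; every DE gene id must be
#'   annotated in it.
#' @param hits ERE hits from \code{\link{scan_peaks}} (required when
#'   \code{require_ere}); hit peak ids must exist in \code{peaks}.
#' @param max_upstream upstream distance bound in bp, strict.
#' @param require_ere restrict supporting sites to ERE-containing ones.
#' @return data.frame sorted by gene_id: gene_id, biotype, direction,
#'   peak_ids (comma-separated supporting peaks), n_peaks,
#'   min_upstream_distance, n_ere_in_support.
#' @export
call_direct_targets <- function(de, peaks, gm, hits = NULL,
                                max_upstream = 50000, require_ere = TRUE) {
  if (!"direction" %in% names(de))
    stopf("DE table has no direction column; run call_de() first")
  md <- S4Vectors::mcols(peaks)
  peak_ids <- md$peak_id
  if (!is.null(hits)) {
    unknown <- setdiff(unique(hits$peak_id), peak_ids)
    if (length(unknown) > 0)
      stopf("hit(s) reference unknown peak id(s): %s",
            paste(unknown, collapse = ", "))
  }
  if (require_ere && is.null(hits))
    stopf("require_ere = TRUE needs the ERE hits table")
  de_resp <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  unknown <- setdiff(de_resp$gene_id, gm$genes$gene_id)
  if (length(unknown) > 0)
    stopf("DE gene(s) not in the gene models: %s",
          paste(unknown, collapse = ", "))
  candidate <- if (require_ere) peak_ids %in% unique(hits$peak_id)
               else rep(TRUE, length(peak_ids))
  ere_per_peak <- if (!is.null(hits))
    table(factor(hits$peak_id, levels = peak_ids)) else NULL
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  psummit <- md$summit
  genes <- gm$genes
  calls <- list()
  for (gid in sort(unique(de_resp$gene_id))) {
    gi <- match(gid, genes$gene_id)
    tsss <- gm$tss$tss[gm$tss$gene_id == gid]
    sel <- which(candidate & pchrom == genes$chrom[gi])
    if (length(sel) == 0) next
    # min over TSSs of the strand-aware upstream distance; negative or NA
    # when the summit is never 5' of a TSS
    dmin <- rep(Inf, length(sel))
    for (t in tsss) {
      d <- if (genes$strand[gi] == "+") t - psummit[sel]
           else psummit[sel] - t
      ok <- d >= 0 & d < dmin
      dmin[ok] <- d[ok]
    }
    support <- which(dmin < max_upstream)
    if (length(support) == 0) next
    sp <- sel[support]
    calls[[gid]] <- data.frame(
      gene_id = gid,
      biotype = de_resp$biotype[match(gid, de_resp$gene_id)],
      direction = de_resp$direction[match(gid, de_resp$gene_id)],
      peak_ids = paste(peak_ids[sp], collapse = ","),
      n_peaks = length(sp),
      min_upstream_distance = min(dmin[support]),
      n_ere_in_support = if (!is.null(ere_per_peak))
        sum(ere_per_peak[peak_ids[sp]]) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), biotype = character(0),
                      direction = character(0), peak_ids = character(0),
                      n_peaks = integer(0),
                      min_upstream_distance = numeric(0),
                      n_ere_in_support = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Over-representation of a gene set in annotation terms
#'
#' Hypergeometric upper-tail test per term with fold enrichment
#' GeneRatio / BgRatio = (k/n) / (K/N), where k = DE genes in the term,
#' n = DE genes in the universe, K = universe genes in the term, N =
#' universe size; q-values are Benjamini-Hochberg over all tested terms.
#'
#' @param de_genes character vector of gene ids (must lie in the universe).
#' @param term_table data.frame term_id/gene_id (one row per membership).
#' @param universe background gene ids; defaults to all genes in
#'   \code{term_table}.
#' @return data.frame term_id, k, n, K, N, fold_enrichment, p_value, q_value
#'   sorted by p_value. Terms with no universe gene are skipped with a
#'   warning.
#' @export
enrich <- function(de_genes, term_table, universe = NULL) {
  miss <- setdiff(c("term_id", "gene_id"), names(term_table))
  if (length(miss) > 0)
    stopf("term table missing column(s): %s", paste(miss, collapse = ", "))
  universe <- unique(universe %||% term_table$gene_id)
  de_genes <- unique(de_genes)
  out_uni <- setdiff(de_genes, universe)
  if (length(out_uni) > 0)
    stopf("DE gene(s) outside the background universe: %s",
          paste(out_uni, collapse = ", "))
  n <- length(de_genes)
  N <- length(universe)
  res <- list()
  for (term in unique(term_table$term_id)) {
    tg <- intersect(unique(term_table$gene_id[term_table$term_id == term]),
                    universe)
    K <- length(tg)
    if (K == 0) {
      warnf("term %s has no gene in the universe; skipped", term)
      next
    }
    k <- length(intersect(de_genes, tg))
    res[[term]] <- data.frame(
      term_id = term, k = k, n = n, K = K, N = N,
      fold_enrichment = (k / n) / (K / N),
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stopf("no testable terms")
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
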