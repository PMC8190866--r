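PEAK_CATEGORIES <- c("upstream_lt2kb", "upstream_2_10kb", "upstream_10_50kb",
                     "gene_body", "downstream", "distal")

#' Annotate peaks by genomic localization relative to gene TSSs
#'
#' Each peak is assigned exactly one category from its summit position:
#' \code{gene_body} when the summit lies inside any gene body; otherwise the
#' strand-aware upstream bins \code{upstream_lt2kb} / \code{upstream_2_10kb}
#' / \code{upstream_10_50kb} when the summit is 5' of some TSS within 50 kb
#' (bins half-open on the outer edge); otherwise \code{downstream} when the
#' summit is 3' of a gene end within 50 kb; otherwise \code{distal}. The
#' signed distance is measured summit to nearest TSS over all isoforms of
#' all genes, negative when the summit is upstream in the gene's orientation,
#' and equidistant ties break by lexicographic gene id.
#'
#' @param peaks a peaks \code{GRanges}.
#' @param gm a \code{\link{gene_models}} object.
#' @param upstream_bins upstream bin edges in bp (outer edge exclusive).
#' @param max_downstream downstream window in bp past the gene 3' end.
#' @return data.frame: peak_id, gene_id (NA when distal with no gene on the
#'   chromosome), signed_distance, category.
#' @export
annotate_peaks <- function(peaks, gm, upstream_bins = c(2000, 10000, 50000),
                           max_downstream = 50000) {
  genes <- gm$genes
  tss <- gm$tss
  tss$strand <- genes$strand[match(tss$gene_id, genes$gene_id)]
  tss$chrom <- genes$chrom[match(tss$gene_id, genes$gene_id)]
  md <- S4Vectors::mcols(peaks)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  n <- length(peaks)
  out <- data.frame(peak_id = md$peak_id, gene_id = NA_character_,
                    signed_distance = NA_real_, category = "distal",
                    stringsAsFactors = FALSE)
  max_up <- max(upstream_bins)
  for (i in seq_len(n)) {
    s <- md$summit[i]
    g <- genes[genes$chrom == chroms[i], , drop = FALSE]
    if (nrow(g) == 0) next
    t <- tss[tss$chrom == chroms[i], , drop = FALSE]
    # signed distance: negative = summit upstream of the TSS
    d <- ifelse(t$strand == "+", s - t$tss, t$tss - s)
    ord <- order(abs(d), t$gene_id, t$tss)
    nearest <- ord[1]
    out$gene_id[i] <- t$gene_id[nearest]
    out$signed_distance[i] <- d[nearest]
    in_body <- g$start <= s & s <= g$end
    if (any(in_body)) {
      out$category[i] <- "gene_body"
      next
    }
    up <- which(d < 0 & -d < max_up)
    if (length(up) > 0) {
      du <- min(-d[up])
      bin <- findInterval(du, c(0, upstream_bins))
      out$category[i] <- c("upstream_lt2kb", "upstream_2_10kb",
                           "upstream_10_50kb")[bin]
      # the categorizing gene: nearest qualifying upstream TSS
      j <- up[order(-d[up], t$gene_id[up])][1]
      out$gene_id[i] <- t$gene_id[j]
      out$signed_distance[i] <- d[j]
      next
    }
    end3 <- ifelse(g$strand == "+", g$end, g$start)
    dd <- ifelse(g$strand == "+", s - end3, end3 - s)
    if (any(dd > 0 & dd <= max_downstream)) {
      out$category[i] <- "downstream"
      j <- which(dd > 0 & dd <= max_downstream)
      jg <- j[order(dd[j], g$gene_id[j])][1]
      out$gene_id[i] <- g$gene_id[jg]
      tj <- which(t$gene_id == g$gene_id[jg])
      out$signed_distance[i] <- d[tj[which.min(abs(d[tj]))]]
    }
  }
  out
}

#' Localization summary over peak annotations
#'
#' @param annotations data.frame from \code{\link{annotate_peaks}}.
#' @return data.frame category/count/fraction; fractions sum to 1.
#' @export
localization_summary <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0)
    stopf("no annotations to summarize")
  tab <- table(factor(annotations$category, levels = PEAK_CATEGORIES))
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(annotations),
             stringsAsFactors = FALSE)
}
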