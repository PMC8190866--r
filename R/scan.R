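# score all windows of an integer-encoded sequence; windows containing NA
# (i.e. N bases) get NA scores and never pass
score_windows_int <- function(iv, int_scores) {
  L <- ncol(int_scores)
  nw <- length(iv) - L + 1
  if (nw < 1) return(integer(0))
  s <- rep(0L, nw)
  na <- rep(FALSE, nw)
  for (j in seq_len(L)) {
    v <- int_scores[, j][iv[j:(j + nw - 1)]]
    na <- na | is.na(v)
    v[is.na(v)] <- 0L
    s <- s + v
  }
  s[na] <- NA_integer_
  s
}

#' Scan ChIP peaks for estrogen response elements
#'
#' Identifies ERE occurrences inside binding sites with the dual criterion:
#' exact PWM p-value below \code{p_threshold} AND at most
#' \code{pattern$max_mismatch} mismatches against the core consensus. Each
#' peak is first extended symmetrically around its summit to a fixed window
#' (default 500 bp total, clipped at chromosome ends with a warning); both
#' strands are scanned. Hits at the same location on opposite strands (the
#' consensus is palindromic) are deduplicated keeping the higher-scoring
#' orientation, and remaining overlapping hits within a peak are resolved by
#' greedy non-overlapping selection in order of ascending p-value, so the
#' per-peak ERE count is a count of distinct occurrences.
#'
#' @param genome a \code{DNAStringSet} from \code{\link{read_genome_fasta}}.
#' @param peaks a peaks \code{GRanges} from \code{\link{read_peaks}}.
#' @param motif a \code{count_matrix_motif}; default \code{\link{ere_motif}()}.
#' @param pattern a \code{\link{consensus_pattern}}.
#' @param p_threshold hit requires p_value strictly below this (default 5e-4).
#' @param window total scan window per peak in bp, centered on the summit;
#'   \code{NULL} or 0 scans the peak interval as-is.
#' @return data.frame of hits: peak_id, chrom, start, end (1-based
#'   inclusive), strand, score (bits), p_value, mismatches, match_seq (the
#'   matching-orientation sequence).
#' @export
scan_peaks <- function(genome, peaks, motif = ere_motif(),
                       pattern = consensus_pattern(),
                       p_threshold = 5e-4, window = 500) {
  L <- motif_length(motif)
  if (length(pattern$chars) != L)
    stopf("pattern length (%d) differs from motif length (%d)",
          length(pattern$chars), L)
  p_int <- round(motif$log_odds / motif$resolution)  # same as motif$int_scores
  hits <- vector("list", length(peaks))
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  md <- S4Vectors::mcols(peaks)
  clipped <- 0L
  for (i in seq_along(peaks)) {
    chrom <- chroms[i]
    if (!chrom %in% names(genome))
      stopf("peak %s on unknown chromosome %s", md$peak_id[i], chrom)
    clen <- Biostrings::width(genome[chrom])
    if (is.null(window) || window <= 0) {
      ws <- GenomicRanges::start(peaks)[i]
      we <- GenomicRanges::end(peaks)[i]
    } else {
      ws <- md$summit[i] - window %/% 2L
      we <- ws + window - 1L
    }
    if (ws < 1 || we > clen) {
      clipped <- clipped + 1L
      ws <- max(1L, ws); we <- min(clen, we)
    }
    seq_chr <- as.character(Biostrings::subseq(genome[[chrom]], ws, we))
    iv <- encode_seq(seq_chr)
    n <- length(iv)
    if (n < L) next
    peak_hits <- list()
    for (strand in c("+", "-")) {
      v <- if (strand == "+") iv else rev(5L - iv)
      s <- score_windows_int(v, motif$int_scores)
      pv <- pvalue_int(motif, s)
      pass <- which(!is.na(pv) & pv < p_threshold)
      if (length(pass) == 0) next
      sseq <- if (strand == "+") seq_chr else revcomp_chr(seq_chr)
      for (k in pass) {
        if (strand == "+") {
          st <- ws + k - 1L
        } else {
          # position k in the reverse-complemented sequence maps back
          st <- ws + (n - (k + L - 1L))
        }
        mseq <- substr(sseq, k, k + L - 1L)
        mm <- mismatch_count(mseq, pattern)
        if (mm > pattern$max_mismatch) next
        peak_hits[[length(peak_hits) + 1L]] <- data.frame(
          peak_id = md$peak_id[i], chrom = chrom,
          start = st, end = st + L - 1L, strand = strand,
          score = s[k] * motif$resolution, p_value = pv[k],
          mismatches = mm, match_seq = mseq, stringsAsFactors = FALSE)
      }
    }
    if (length(peak_hits) == 0) next
    h <- do.call(rbind, peak_hits)
    hits[[i]] <- resolve_peak_hits(h)
  }
  if (clipped > 0)
    warnf("%d scan window(s) extended past a chromosome end were clipped",
          clipped)
  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0), mismatches = integer(0),
                      match_seq = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# within one peak: opposite-strand duplicates at the same location collapse
# to the better orientation, then greedy non-overlapping selection by
# ascending p-value (ties broken by start, then strand)
resolve_peak_hits <- function(h) {
  h <- h[order(h$start, h$strand), , drop = FALSE]
  key <- paste(h$start, h$end)
  if (anyDuplicated(key)) {
    keep <- logical(nrow(h))
    for (k in unique(key)) {
      ii <- which(key == k)
      best <- ii[order(-h$score[ii], h$strand[ii])][1]
      keep[best] <- TRUE
    }
    h <- h[keep, , drop = FALSE]
  }
  h <- h[order(h$p_value, h$start, h$strand), , drop = FALSE]
  sel <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    if (any(sel)) {
      ok <- all(h$end[sel] < h$start[i] | h$start[sel] > h$end[i])
    }
    sel[i] <- ok
  }
  h <- h[sel, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

#' Classify binding sites by ERE content
#'
#' Assigns each peak the class zero, one or multiple according to its count
#' of distinct ERE hits, and summarizes the distribution over all peaks.
#'
#' @param peaks a peaks \code{GRanges}.
#' @param hits a hits data.frame from \code{\link{scan_peaks}}; hits
#'   referencing unknown peak ids are an error.
#' @return an object of class \code{site_classification}: list with
#'   \code{per_peak} (peak_id, n_ere, class), \code{counts} (zero/one/
#'   multiple), \code{n_peaks}, \code{n_ere_total} and
#'   \code{fraction_with_ere}.
#' @export
classify_sites <- function(peaks, hits) {
  ids <- S4Vectors::mcols(peaks)$peak_id
  unknown <- setdiff(unique(hits$peak_id), ids)
  if (length(unknown) > 0)
    stopf("hit(s) reference unknown peak id(s): %s",
          paste(unknown, collapse = ", "))
  n_ere <- as.integer(table(factor(hits$peak_id, levels = ids)))
  cls <- cut(n_ere, breaks = c(-1, 0, 1, Inf),
             labels = c("zero", "one", "multiple"))
  counts <- c(zero = sum(cls == "zero"), one = sum(cls == "one"),
              multiple = sum(cls == "multiple"))
  structure(list(
    per_peak = data.frame(peak_id = ids, n_ere = n_ere,
                          class = as.character(cls),
                          stringsAsFactors = FALSE),
    counts = counts,
    n_peaks = length(ids),
    n_ere_total = nrow(hits),
    fraction_with_ere = if (length(ids) > 0)
      unname((counts["one"] + counts["multiple"]) / length(ids)) else NA_real_),
    class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(paste0("site_classification: %d peaks, %d EREs ",
                     "(zero/one/multiple = %d/%d/%d, with ERE = %.1f%%)\n"),
              x$n_peaks, x$n_ere_total, x$counts["zero"], x$counts["one"],
              x$counts["multiple"], 100 * x$fraction_with_ere))
  invisible(x)
}

#' Reconstruct a count matrix from ERE hits
#'
#' Stacks the matching-orientation hit sequences into a new position count
#' matrix (column sums all equal the number of hits) and tabulates the
#' trinucleotide composition of the spacer block (pattern positions 7-9).
#'
#' @param hits a hits data.frame from \code{\link{scan_peaks}} (its
#'   \code{match_seq} column is used); at least one hit is required.
#' @param spacer_positions positions of the spacer block within the motif.
#' @inheritParams count_matrix_motif
#' @return list with \code{motif} (a \code{count_matrix_motif}),
#'   \code{consensus} (per-column argmax string) and
#'   \code{spacer_composition} (data.frame spacer/count/frequency).
#' @export
reconstruct_motif <- function(hits, spacer_positions = 7:9,
                              pseudocount = 0.1, background = rep(0.25, 4),
                              resolution = 0.001) {
  if (is.null(hits) || nrow(hits) == 0)
    stopf("cannot reconstruct a motif from zero hits")
  seqs <- Biostrings::DNAStringSet(hits$match_seq)
  cm <- Biostrings::consensusMatrix(seqs)[BASES, , drop = FALSE]
  spacer <- substr(hits$match_seq, min(spacer_positions),
                   max(spacer_positions))
  tab <- sort(table(spacer), decreasing = TRUE)
  motif <- count_matrix_motif(cm, pseudocount = pseudocount,
                              background = background,
                              resolution = resolution,
                              name = "reconstructed")
  list(motif = motif,
       consensus = paste(BASES[apply(cm, 2, which.max)], collapse = ""),
       spacer_composition = data.frame(
         spacer = names(tab), count = as.integer(tab),
         frequency = as.numeric(tab) / nrow(hits),
         stringsAsFactors = FALSE))
}

#' Write ERE hits as BED6 and TSV
#'
#' BED column 4 carries the peak id, column 5 \code{round(100 * score)}; a
#' companion TSV keeps p-values and mismatch counts.
#'
#' @param hits a hits data.frame.
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_hits <- function(hits, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    df <- data.frame(hits$chrom, hits$start - 1, hits$end, hits$peak_id,
                     round(100 * hits$score), hits$strand)
    utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  if (!is.null(tsv_path)) write_tsv(hits, tsv_path)
  invisible(hits)
}
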