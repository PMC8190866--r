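#' Read a genome FASTA file
#'
#' Reads a multi-record FASTA into a \code{DNAStringSet}. All sequences are
#' uppercased (soft-masked lowercase bases are kept, as uppercase) and
#' validated to contain only A/C/G/T/N. Ambiguity gaps (N) are permitted;
#' downstream motif scanning treats windows containing N as non-scoring.
#'
#' @param path path to a FASTA file.
#' @return a \code{Biostrings::DNAStringSet}, one element per record.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stopf("%s: empty FASTA file", path)
  nm <- names(seqs)
  # FASTA headers may carry descriptions; the sequence name is the first word
  nm <- sub("\\s.*$", "", nm)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0)
    stopf("%s: duplicate sequence name(s): %s", path,
          paste(unique(dup), collapse = ", "))
  names(seqs) <- nm
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- colSums(af[, !colnames(af) %in% c(BASES, "N"), drop = FALSE])
  if (any(bad > 0))
    stopf("%s: sequences contain letters outside A/C/G/T/N: %s", path,
          paste(names(bad)[bad > 0], collapse = ", "))
  seqs
}

#' Write a genome FASTA file
#'
#' @param genome a \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Gene models: genes, strands and transcription start sites
#'
#' Container pairing a gene table (one row per gene: id, chromosome, strand,
#' body span, biotype) with a TSS table (one row per distinct transcription
#' start site; genes with alternative promoters carry several). Coordinates
#' are 1-based and inclusive throughout the package; conversion to the
#' 0-based conventions of BED happens only at file boundaries.
#'
#' @param genes data.frame with columns gene_id, chrom, strand ("+"/"-"),
#'   start, end, biotype ("protein_coding", "lncRNA" or "miRNA").
#' @param tss data.frame with columns gene_id, tss (1-based position).
#' @return an object of class \code{gene_models}.
#' @export
gene_models <- function(genes, tss) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0)
    stopf("gene table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene_id in gene table")
  if (any(genes$start > genes$end))
    stopf("gene with start > end: %s",
          paste(genes$gene_id[genes$start > genes$end], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  tss <- unique(tss[, c("gene_id", "tss")])
  unknown <- setdiff(tss$gene_id, genes$gene_id)
  if (length(unknown) > 0)
    stopf("TSS for unknown gene(s): %s", paste(unknown, collapse = ", "))
  m <- match(tss$gene_id, genes$gene_id)
  out_of_body <- tss$tss < genes$start[m] | tss$tss > genes$end[m]
  if (any(out_of_body))
    stopf("TSS outside gene body for gene(s): %s",
          paste(unique(tss$gene_id[out_of_body]), collapse = ", "))
  tss <- tss[order(tss$gene_id, tss$tss), , drop = FALSE]
  rownames(tss) <- NULL
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, tss = tss), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%s), %d TSSs on %d chromosome(s)\n",
              nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$biotype)),
                            table(x$genes$biotype)), collapse = ", "),
              nrow(x$tss), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Parses gene/transcript features (GTF 1-based inclusive coordinates) into a
#' \code{\link{gene_models}} object. The TSS of a "+" strand transcript is its
#' start; of a "-" strand transcript its end. Duplicate TSSs across isoforms
#' of one gene are collapsed. A transcript whose \code{gene_id} has no gene
#' feature is an error, as is a feature with end < start.
#'
#' @param path path to a GTF file with \code{gene_id}, \code{transcript_id}
#'   and (optionally) \code{gene_biotype} attributes.
#' @return a \code{gene_models} object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stopf("%s line %d: fewer than 9 GTF fields", path, i)
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) stopf("%s line %d: non-numeric coordinates", path, i)
    if (e < s) stopf("%s line %d: end < start", path, i)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_tx <- md$type == "transcript"
  if (!any(is_gene) && any(is_tx))
    stopf("%s: transcript(s) without a parent gene feature: %s", path,
          paste(unique(as.character(md$gene_id[is_tx])), collapse = ", "))
  if (!any(is_gene)) stopf("%s: no gene features", path)
  if (!any(is_tx)) stopf("%s: no transcript features", path)
  biotype <- if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype)
             else rep("protein_coding", length(gr))
  genes <- data.frame(
    gene_id = as.character(md$gene_id[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    biotype = ifelse(is.na(biotype[is_gene]), "protein_coding",
                     biotype[is_gene]),
    stringsAsFactors = FALSE)
  tx_gene <- as.character(md$gene_id[is_tx])
  orphan <- setdiff(tx_gene, genes$gene_id)
  if (length(orphan) > 0)
    stopf("%s: transcript(s) without a parent gene feature: %s", path,
          paste(orphan, collapse = ", "))
  tx_strand <- as.character(GenomicRanges::strand(gr)[is_tx])
  tss <- data.frame(
    gene_id = tx_gene,
    tss = ifelse(tx_strand == "+", GenomicRanges::start(gr)[is_tx],
                 GenomicRanges::end(gr)[is_tx]),
    stringsAsFactors = FALSE)
  gene_models(genes, tss)
}

#' Write gene models to a GTF file
#'
#' Emits one gene feature per gene and one transcript feature per TSS (the
#' transcript span runs from the TSS to the far body edge), so that
#' \code{read_gtf(write_gtf(x))} round-trips.
#'
#' @param gm a \code{gene_models} object.
#' @param path output path.
#' @export
write_gtf <- function(gm, path) {
  g <- gm$genes
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";',
                      g$gene_id[i], g$biotype[i])
    lines <- c(lines, paste(g$chrom[i], "eretarget", "gene", g$start[i],
                            g$end[i], ".", g$strand[i], ".", attr_g,
                            sep = "\t"))
    tsss <- gm$tss$tss[gm$tss$gene_id == g$gene_id[i]]
    for (k in seq_along(tsss)) {
      if (g$strand[i] == "+") { s <- tsss[k]; e <- g$end[i] }
      else { s <- g$start[i]; e <- tsss[k] }
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t%d"; gene_biotype "%s";',
                        g$gene_id[i], g$gene_id[i], k, g$biotype[i])
      lines <- c(lines, paste(g$chrom[i], "eretarget", "transcript", s, e,
                              ".", g$strand[i], ".", attr_t, sep = "\t"))
    }
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

peak_summit <- function(start, width) start + width %/% 2L

#' Read ChIP-seq peaks from a BED file
#'
#' Accepts BED3+ (0-based half-open per the BED standard); coordinates are
#' converted to the package-internal 1-based inclusive convention. Column 4,
#' when present, names the peak; otherwise peaks are named
#' \code{peak_<n>} in file order. The summit is the interval midpoint.
#'
#' @param path path to a BED file.
#' @return a \code{GRanges} with metadata columns \code{peak_id} and
#'   \code{summit} (1-based position), plus any extra BED columns.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(GenomicRanges::GRanges(peak_id = character(0),
                                  summit = integer(0)))
  }
  fields <- strsplit(lines[idx], "\t| +")
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stopf("%s line %d: fewer than 3 BED fields", path, idx[which(ncols < 3)[1]])
  n <- length(idx)
  chrom <- vapply(fields, `[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0)
    stopf("%s line %d: non-numeric coordinates", path, idx[bad[1]])
  bad <- which(start0 >= end0)
  if (length(bad) > 0)
    stopf("%s line %d: start >= end", path, idx[bad[1]])
  peak_id <- if (all(ncols >= 4)) vapply(fields, `[`, character(1), 4)
             else sprintf("peak_%d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0))
  S4Vectors::mcols(gr)$peak_id <- peak_id
  S4Vectors::mcols(gr)$summit <-
    peak_summit(GenomicRanges::start(gr), GenomicRanges::width(gr))
  # preserve further BED columns (score, strand, ...) for write-back
  maxc <- max(ncols)
  if (maxc >= 5) {
    for (j in 5:maxc) {
      S4Vectors::mcols(gr)[[sprintf("bed%d", j)]] <-
        vapply(fields, function(f) if (length(f) >= j) f[j] else ".",
               character(1))
    }
  }
  sort_peaks(gr)
}

sort_peaks <- function(gr) {
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr[ord]
}

#' Merge overlapping or abutting peaks
#'
#' Reduces the peak set to "unique" binding sites: any two intervals on the
#' same chromosome that overlap or abut are merged into one. Merged peaks are
#' renamed \code{merged_<n>} and their summit is the midpoint of the merged
#' interval. Idempotent.
#'
#' @param peaks a peaks \code{GRanges} as from \code{\link{read_peaks}}.
#' @return a merged, sorted peaks \code{GRanges}.
#' @export
merge_peaks <- function(peaks) {
  red <- GenomicRanges::reduce(peaks, min.gapwidth = 1L)
  red <- sort_peaks(red)
  S4Vectors::mcols(red)$peak_id <- sprintf("merged_%d", seq_along(red))
  S4Vectors::mcols(red)$summit <-
    peak_summit(GenomicRanges::start(red), GenomicRanges::width(red))
  red
}

#' Write peaks to a BED file
#'
#' Emits BED with 0-based half-open coordinates; \code{peak_id} becomes
#' column 4 and any preserved extra columns follow.
#'
#' @param peaks a peaks \code{GRanges}.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  md <- S4Vectors::mcols(peaks)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1,
    end = GenomicRanges::end(peaks),
    name = md$peak_id,
    stringsAsFactors = FALSE)
  extra <- grep("^bed[0-9]+$", names(md), value = TRUE)
  for (cl in extra) df[[cl]] <- md[[cl]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
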