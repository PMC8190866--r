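#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames (assembled transcripts are oriented) for
#' ATG-initiated, stop-terminated reading frames; an ORF runs from an ATG to
#' the first in-frame stop and its length counts the stop codon. Returns 0
#' when no complete ORF exists. Codons containing N neither start nor stop
#' an ORF.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @return longest ORF length in nucleotides (multiple of 3), or 0.
#' @export
longest_orf <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) < 6) return(0L)
  s <- toupper(sequence)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_codons <- (nchar(s) - frame) %/% 3
    if (n_codons < 2) next
    codons <- substring(s, frame + 1 + 3 * (seq_len(n_codons) - 1),
                        frame + 3 * seq_len(n_codons))
    open <- NA_integer_  # earliest ATG since the last stop
    for (i in seq_len(n_codons)) {
      if (codons[i] %in% stops) {
        if (!is.na(open)) {
          len <- (i - open + 1L) * 3L
          if (len > best) best <- len
          open <- NA_integer_
        }
      } else if (is.na(open) && codons[i] == "ATG") {
        open <- i
      }
    }
  }
  best
}

LNC_CRITERIA <- c("exon_ge2", "length_ge200", "orf_lt300", "no_pfam_hit",
                  "cnci_lt0", "cpc_lt0")

#' Six-criterion lncRNA identification cascade
#'
#' A transcript passes iff all of: (1) exon count >= 2; (2) length >= 200 bp;
#' (3) longest predicted ORF < 300 bp (strict); (4) no Pfam hit; (5)
#' coding-noncoding index score < 0; (6) coding potential calculator score
#' < 0. External classifier scores (Pfam/CNCI/CPC) are input columns, not
#' computed. The ORF is computed from the transcript sequence when one is
#' supplied, else taken from an \code{orf_length} column. The trace records
#' every criterion's evaluation and the first failing criterion; the verdict
#' is the conjunction and therefore order-independent.
#'
#' @param records data.frame with transcript_id, exon_count, length,
#'   pfam_hit (logical), cnci_score, cpc_score, and orf_length unless
#'   \code{sequences} provides all sequences.
#' @param sequences optional named character vector or \code{DNAStringSet}
#'   of transcript sequences (names = transcript_id).
#' @return list with \code{passing} (transcript ids) and \code{trace}
#'   (per-transcript data.frame of criterion evaluations, orf_length,
#'   first_fail and pass).
#' @export
filter_lncrna <- function(records, sequences = NULL) {
  need <- c("transcript_id", "exon_count", "length", "pfam_hit",
            "cnci_score", "cpc_score")
  for (col in need) {
    if (!col %in% names(records))
      stopf("transcript table missing column: %s", col)
    bad <- which(is.na(records[[col]]))
    if (length(bad) > 0)
      stopf("transcript %s: missing value in field %s",
            records$transcript_id[bad[1]], col)
  }
  if (!is.null(sequences)) {
    if (inherits(sequences, "DNAStringSet"))
      sequences <- as.character(sequences)
    sequences <- sequences[records$transcript_id]
  }
  orf <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!is.null(sequences) && !is.na(sequences[i])) {
      orf[i] <- longest_orf(sequences[i])
    } else if ("orf_length" %in% names(records) &&
               !is.na(records$orf_length[i])) {
      orf[i] <- records$orf_length[i]
    } else {
      stopf("transcript %s: missing field orf_length (and no sequence)",
            records$transcript_id[i])
    }
  }
  crit <- data.frame(
    exon_ge2 = records$exon_count >= 2,
    length_ge200 = records$length >= 200,
    orf_lt300 = orf < 300,
    no_pfam_hit = !as.logical(records$pfam_hit),
    cnci_lt0 = records$cnci_score < 0,
    cpc_lt0 = records$cpc_score < 0)
  pass <- Reduce(`&`, crit)
  first_fail <- apply(crit, 1, function(r)
    if (all(r)) NA_character_ else LNC_CRITERIA[which(!r)[1]])
  trace <- cbind(
    data.frame(transcript_id = records$transcript_id,
               orf_length = orf, stringsAsFactors = FALSE),
    crit,
    data.frame(first_fail = first_fail, pass = pass,
               stringsAsFactors = FALSE))
  list(passing = records$transcript_id[pass], trace = trace)
}
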