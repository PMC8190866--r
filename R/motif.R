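#' Count-matrix motif with exact score-distribution p-values
#'
#' Builds a position count matrix into a log-odds scoring matrix and
#' precomputes the exact null distribution of the score of a random
#' background L-mer. Per-position log-odds (bits) are
#' \code{log2((count + pseudocount * background) / (colsum + pseudocount) /
#' background)}. Scores are discretized to integer multiples of
#' \code{resolution} bits; both the null distribution (computed by exact
#' per-position convolution) and window scoring during scanning use the same
#' integerized matrix, so reported p-values \code{P(score >= s)} are exact
#' for the discretized score.
#'
#' @param counts 4 x L matrix of non-negative counts, rows A, C, G, T.
#' @param pseudocount total pseudocount, distributed by background frequency.
#' @param background background base probabilities (A, C, G, T), summing to 1.
#' @param resolution score discretization bin width in bits. An error is
#'   raised if it is so coarse that every column collapses to a single bin.
#' @param name optional motif name.
#' @return an object of class \code{count_matrix_motif}.
#' @export
count_matrix_motif <- function(counts, pseudocount = 0.1,
                               background = rep(0.25, 4),
                               resolution = 0.001, name = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("count matrix must have 4 rows (A,C,G,T)")
  if (is.null(rownames(counts))) rownames(counts) <- BASES
  counts <- counts[BASES, , drop = FALSE]
  if (any(counts < 0)) stopf("count matrix has negative entries")
  if (any(colSums(counts) == 0) && pseudocount <= 0)
    stopf("zero column sum with non-positive pseudocount")
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stopf("background must be 4 positive probabilities summing to 1")
  if (resolution <= 0) stopf("resolution must be positive")
  colsum <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, colsum + pseudocount, "/")
  log_odds <- log2(prob / background)
  int_scores <- round(log_odds / resolution)
  if (all(apply(int_scores, 2, max) == apply(int_scores, 2, min)))
    stopf("resolution %g too coarse: all columns collapse to one score bin",
          resolution)
  dist <- score_distribution_dp(int_scores, background)
  structure(list(counts = counts, pseudocount = pseudocount,
                 background = background, resolution = resolution,
                 log_odds = log_odds, int_scores = int_scores,
                 dist = dist, name = name),
            class = "count_matrix_motif")
}

# Exact distribution of the integerized score of a random background L-mer.
# Column-by-column convolution over the integer score lattice.
score_distribution_dp <- function(int_scores, background) {
  cur <- 1
  offset <- 0
  for (j in seq_len(ncol(int_scores))) {
    col <- int_scores[, j]
    lo <- min(col)
    new <- numeric(length(cur) + max(col) - lo)
    for (b in 1:4) {
      sh <- col[b] - lo
      ii <- seq_along(cur) + sh
      new[ii] <- new[ii] + background[b] * cur
    }
    cur <- new
    offset <- offset + lo
  }
  p_ge <- rev(cumsum(rev(cur)))
  list(offset = offset, prob = cur, p_ge = p_ge)
}

#' @export
print.count_matrix_motif <- function(x, ...) {
  cat(sprintf("count_matrix_motif%s: length %d, max score %.3f bits\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              ncol(x$counts), motif_max_score(x)))
  invisible(x)
}

motif_length <- function(motif) ncol(motif$counts)
motif_max_score <- function(motif)
  sum(apply(motif$int_scores, 2, max)) * motif$resolution

# p-value lookup for integer scores (vectorized); P(score >= s)
pvalue_int <- function(motif, s_int) {
  d <- motif$dist
  idx <- s_int - d$offset + 1
  p <- rep(1, length(s_int))
  inr <- !is.na(idx) & idx >= 1 & idx <= length(d$p_ge)
  p[inr] <- d$p_ge[idx[inr]]
  p[!is.na(idx) & idx > length(d$p_ge)] <- 0
  p[is.na(s_int)] <- NA_real_
  p
}

#' Score-to-p-value table for a motif
#'
#' Exact null p-values \code{P(score >= s)} for every achievable discretized
#' score of a random background L-mer. p is non-increasing in the score and
#' equals 1 at the minimum possible score.
#'
#' @param motif a \code{count_matrix_motif}.
#' @return data.frame with columns \code{score} (bits) and \code{p_value}.
#' @export
score_pvalue_table <- function(motif) {
  d <- motif$dist
  ach <- which(d$prob > 0)
  data.frame(score = (d$offset + ach - 1) * motif$resolution,
             p_value = d$p_ge[ach])
}

#' p-values for arbitrary scores
#'
#' @param motif a \code{count_matrix_motif}.
#' @param score numeric vector of scores in bits.
#' @return \code{P(score_null >= score)} under the background model.
#' @export
score_to_pvalue <- function(motif, score) {
  pvalue_int(motif, round(score / motif$resolution))
}

#' Read a JASPAR-format count matrix
#'
#' Parses the JASPAR \code{.jaspar}/\code{.pfm} text format: an optional
#' \code{>ID name} header line followed by four rows of counts for A, C, G, T
#' (with or without the \code{A [ ... ]} bracket style).
#'
#' @param path path to the matrix file.
#' @inheritParams count_matrix_motif
#' @return a \code{count_matrix_motif}.
#' @export
read_jaspar <- function(path, pseudocount = 0.1, background = rep(0.25, 4),
                        resolution = 0.001) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- NULL
  if (grepl("^>", lines[1])) {
    name <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4) stopf("%s: expected 4 count rows", path)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("\\[|\\]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  L <- unique(lengths(rows))
  if (length(L) != 1) stopf("%s: count rows have unequal lengths", path)
  counts <- do.call(rbind, rows)
  rownames(counts) <- BASES
  count_matrix_motif(counts, pseudocount = pseudocount,
                     background = background, resolution = resolution,
                     name = name)
}

#' Write a count matrix in JASPAR format
#' @param motif a \code{count_matrix_motif} (or 4 x L count matrix).
#' @param path output path.
#' @param name header name.
#' @export
write_jaspar <- function(motif, path, name = NULL) {
  counts <- if (inherits(motif, "count_matrix_motif")) motif$counts else motif
  name <- name %||% (if (inherits(motif, "count_matrix_motif"))
    motif$name else NULL) %||% "motif"
  lines <- c(paste0(">", name),
             vapply(BASES, function(b)
               sprintf("%s  [ %s ]", b,
                       paste(format(counts[b, ], trim = TRUE),
                             collapse = " ")), character(1)))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' The package's estrogen response element motif
#'
#' Loads the ERE count matrix shipped with the package
#' (\code{inst/extdata/ere_synthetic.jaspar}). This is a synthetic matrix
#' constructed on the palindromic core consensus AGGTCAnnnTGACCT: the three
#' spacer positions are uninformative, three anchor positions admit only the
#' consensus base, and the remaining nine half-site positions tolerate the
#' transition partner of the consensus base. See the methods vignette for the
#' design rationale (the two-level column structure gives the score
#' distribution a sharp discrete tail, so chance hits at the scanning
#' threshold are rare).
#'
#' @inheritParams count_matrix_motif
#' @return a \code{count_matrix_motif} of length 15.
#' @export
ere_motif <- function(pseudocount = 0.1, background = rep(0.25, 4),
                      resolution = 0.001) {
  path <- system.file("extdata", "ere_synthetic.jaspar",
                      package = "eretarget", mustWork = TRUE)
  read_jaspar(path, pseudocount = pseudocount, background = background,
              resolution = resolution)
}

#' Consensus pattern for mismatch counting
#'
#' The core 15 bp ERE consensus AGGTCAnnnTGACCT; \code{n} positions match any
#' base. The default pattern equals its own reverse complement.
#'
#' @param pattern pattern string over A/C/G/T/n (case-insensitive n or N).
#' @param max_mismatch maximum mismatches tolerated by the scanner.
#' @return an object of class \code{consensus_pattern}.
#' @export
consensus_pattern <- function(pattern = "AGGTCAnnnTGACCT", max_mismatch = 4) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% c(BASES, "N")))
    stopf("pattern may contain only A/C/G/T/n")
  structure(list(pattern = toupper(pattern), chars = chars,
                 fixed = chars %in% BASES, max_mismatch = max_mismatch),
            class = "consensus_pattern")
}

#' Count mismatches of a sequence against a consensus pattern
#'
#' Positions where the pattern is \code{n} contribute nothing; at fixed
#' positions any differing base, including N, counts as one mismatch.
#'
#' @param seq character vector of sequences, each the pattern's length.
#' @param pattern a \code{consensus_pattern}.
#' @return integer vector of mismatch counts.
#' @export
mismatch_count <- function(seq, pattern = consensus_pattern()) {
  L <- length(pattern$chars)
  if (any(nchar(seq) != L))
    stopf("sequence length must be %d", L)
  vapply(toupper(seq), function(s) {
    sc <- strsplit(s, "")[[1]]
    sum(pattern$fixed & sc != pattern$chars)
  }, integer(1), USE.NAMES = FALSE)
}
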