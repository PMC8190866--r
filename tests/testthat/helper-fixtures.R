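bases4 <- c("A", "C", "G", "T")

# build a peaks GRanges directly (1-based closed), summit = midpoint unless
# given
make_peaks <- function(chrom, start, end, peak_id = NULL, summit = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$peak_id <-
    peak_id %||% sprintf("peak_%d", seq_along(gr))
  S4Vectors::mcols(gr)$summit <-
    summit %||% (start + (end - start + 1L) %/% 2L)
  gr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_genome <- function(...) Biostrings::DNAStringSet(c(...))

random_dna <- function(n) paste(sample(bases4, n, replace = TRUE),
                                collapse = "")

# independent brute-force oracle for PWM p-values: enumerate all 4^L k-mers,
# score with the motif's integerized matrix, tabulate the exact upper tail
enum_pvalues <- function(motif) {
  ints <- motif$int_scores
  L <- ncol(ints)
  stopifnot(L <= 8)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(grid))
  for (j in seq_len(L)) sc <- sc + ints[cbind(grid[, j], j)]
  w <- rep(1, nrow(grid))
  for (j in seq_len(L)) w <- w * motif$background[grid[, j]]
  scores <- sort(unique(sc))
  p <- vapply(scores, function(s) sum(w[sc >= s]), numeric(1))
  data.frame(score_int = scores, p = p)
}

# independent brute-force ORF oracle: every ATG paired with the first
# in-frame stop downstream
orf_oracle <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  codon_at <- function(i) substr(s, i, i + 2)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(max(0, n - 2))) {
    if (codon_at(i) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      if (codon_at(j) %in% stops) {
        best <- max(best, j + 2 - i + 1)
        break
      }
      j <- j + 3
    }
  }
  best
}

# exhaustive hypergeometric oracle on a small universe: enumerate all draws
hyper_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)  # wlog the first K genes form the term
  hits <- colSums(matrix(draws %in% in_term, nrow = n))
  mean(hits >= k)
}

# a shared small synthetic bundle, generated once per test session
small_sim_config <- function(...) {
  defaults <- list(seed = 42, genome_length = 8e5, n_genes = 100,
                   n_mirna_genes = 8, n_lncrna_genes = 12,
                   n_peaks = 80, n_de_mrna = 20, n_de_lncrna = 2,
                   n_de_mirna = 3, n_direct_targets = 6,
                   mirna_consensus_pairs = 8, predictor_noise_pairs = 5,
                   nonresponsive_consensus_pairs = 3,
                   n_lnc_like = 4, n_mrna_like = 4)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

shared_bundle_dir <- function() {
  dir <- file.path(tempdir(), "eretarget_shared_bundle")
  if (!file.exists(file.path(dir, "ground_truth.json")))
    simulate_bundle(small_sim_config(), dir)
  dir
}

read_ground_truth <- function(dir) {
  jsonlite::read_json(file.path(dir, "ground_truth.json"),
                      simplifyVector = TRUE)
}

# mirror a genome + peaks + gene models through coordinate reversal with
# strand flip (for invariance tests)
mirror_gene_models <- function(gm, len) {
  g <- gm$genes
  new_start <- len - g$end + 1L
  new_end <- len - g$start + 1L
  g$start <- new_start; g$end <- new_end
  g$strand <- ifelse(g$strand == "+", "-", "+")
  t <- gm$tss
  t$tss <- len - t$tss + 1L
  gene_models(g, t)
}

mirror_peaks <- function(peaks, len) {
  md <- S4Vectors::mcols(peaks)
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(len - GenomicRanges::end(peaks) + 1L,
                     len - GenomicRanges::start(peaks) + 1L))
  S4Vectors::mcols(gr)$peak_id <- md$peak_id
  S4Vectors::mcols(gr)$summit <- len - md$summit + 1L
  gr
}
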