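#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions the pipeline is built for: a 2 Mb
#' genome carrying 200 genes on both strands, 300 binding sites of 201 bp
#' with consensus EREs planted in 55% of them, 69 differentially expressed
#' genes (60 mRNA, 5 lncRNA, 4 miRNA) of which 20 receive an ERE-containing
#' site within 50 kb upstream (the planted direct targets), a CNG-biased
#' spacer distribution, consensus miRNA-target pairs over three predictors,
#' transcript records exercising every lncRNA criterion, and Ct tables
#' inverted from known fold changes.
#'
#' @param seed integer RNG seed; the bundle is a deterministic function of
#'   the config.
#' @param genome_length,chrom genome size (bp) and chromosome name.
#' @param n_genes,strand_fraction gene count and fraction on "+".
#' @param n_mirna_genes,n_lncrna_genes genes of each noncoding biotype (the
#'   rest are protein_coding).
#' @param n_peaks,peak_width binding-site count and width (odd width centers
#'   the summit).
#' @param ere_planting_rate fraction of peaks receiving a planted ERE.
#' @param ere_planting_mismatches substitutions introduced into each planted
#'   ERE's fixed positions (0 = exact consensus).
#' @param spacer_cng_rate probability that a planted spacer is C-N-G.
#' @param n_direct_targets DE genes given an ERE site < 50 kb upstream.
#' @param n_de_mrna,n_de_lncrna,n_de_mirna DE gene counts per class.
#' @param body_peak_fraction when non-NULL, this fraction of background
#'   peaks is forced to have its summit inside a gene body.
#' @param mirna_consensus_pairs planted true consensus pairs (2-3 votes,
#'   both endpoints DE).
#' @param predictor_noise_pairs single-predictor pairs (below consensus).
#' @param nonresponsive_consensus_pairs consensus pairs targeting non-DE
#'   genes (excluded from the network).
#' @param n_lnc_like,n_mrna_like transcript records passing / failing the
#'   lncRNA cascade (long-ORF mRNA-like transcripts fail at the ORF
#'   criterion); crafted single-criterion failures are always added.
#' @param qpcr_true_folds named vector of true expression fold changes for
#'   the qPCR table.
#' @param chip_true_folds named vector of true ChIP-qPCR fold enrichments.
#' @param chip_input_fraction input chromatin fraction for the ChIP table.
#' @param ct_noise_sd Gaussian Ct noise (cycles); 0 gives exact recovery.
#' @param n_treated,n_control qPCR group sizes.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1,
                       genome_length = 2e6, chrom = "chr1",
                       n_genes = 200, strand_fraction = 0.5,
                       n_mirna_genes = 10, n_lncrna_genes = 20,
                       n_peaks = 300, peak_width = 201,
                       ere_planting_rate = 0.55,
                       ere_planting_mismatches = 0,
                       spacer_cng_rate = 0.8,
                       n_direct_targets = 20,
                       n_de_mrna = 60, n_de_lncrna = 5, n_de_mirna = 4,
                       body_peak_fraction = NULL,
                       mirna_consensus_pairs = 30,
                       predictor_noise_pairs = 15,
                       nonresponsive_consensus_pairs = 10,
                       n_lnc_like = 10, n_mrna_like = 10,
                       qpcr_true_folds = c(APOB = 80, APOV1 = 1250),
                       chip_true_folds = c(site_A = 16, site_B = 8,
                                           site_C = 4),
                       chip_input_fraction = 0.2,
                       ct_noise_sd = 0.2,
                       n_treated = 8, n_control = 6) {
  cfg <- as.list(environment())
  rates <- c(strand_fraction = strand_fraction,
             ere_planting_rate = ere_planting_rate,
             spacer_cng_rate = spacer_cng_rate)
  if (any(rates < 0 | rates > 1))
    stopf("rates must lie in [0, 1]")
  if (n_de_mrna + n_de_lncrna + n_de_mirna < n_direct_targets)
    stopf("more direct targets requested than DE genes")
  if (n_mirna_genes < n_de_mirna || n_lncrna_genes < n_de_lncrna ||
      n_genes - n_mirna_genes - n_lncrna_genes < n_de_mrna)
    stopf("DE counts exceed available genes of that biotype")
  structure(cfg, class = "sim_config")
}

# uniform draw of an interval start such that [s, s + w - 1] fits inside the
# free set; returns NA when no placement exists
draw_start <- function(free, w) {
  valid <- pmax(0L, IRanges::width(free) - w + 1L)
  total <- sum(valid)
  if (total == 0) return(NA_integer_)
  r <- sample.int(total, 1)
  cs <- cumsum(valid)
  j <- which(r <= cs)[1]
  IRanges::start(free)[j] + (r - c(0, cs)[j]) - 1L
}

# uniform draw of a single position from an IRanges set
draw_position <- function(set) {
  total <- sum(IRanges::width(set))
  if (total == 0) return(NA_integer_)
  r <- sample.int(total, 1)
  cs <- cumsum(IRanges::width(set))
  j <- which(r <= cs)[1]
  IRanges::start(set)[j] + (r - c(0, cs)[j]) - 1L
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

sense_codons <- function(n) {
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste,
                      collapse = "")
  pool <- setdiff(all_codons, c(STOP_CODONS, "ATG"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# a planted ERE 15-mer: consensus core, spacer CNG-biased, optional
# substitutions at fixed positions, random orientation
make_planted_ere <- function(pattern, cng_rate, n_mismatch) {
  chars <- pattern$chars
  spacer_at <- which(!pattern$fixed)
  if (stats::runif(1) < cng_rate) {
    chars[spacer_at] <- c("C", sample(BASES, 1), "G")
  } else {
    chars[spacer_at] <- sample(BASES, 3, replace = TRUE)
  }
  if (n_mismatch > 0) {
    at <- sample(which(pattern$fixed), n_mismatch)
    for (p in at) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  s <- paste(chars, collapse = "")
  strand <- if (stats::runif(1) < 0.5) "+" else "-"
  list(seq = if (strand == "+") s else revcomp_chr(s),
       spacer = paste(chars[spacer_at], collapse = ""), strand = strand)
}

#' Generate a synthetic input bundle with ground truth
#'
#' Writes every input the pipeline consumes — genome FASTA, gene GTF, peak
#' BED, DE tables, predictor tables, transcript table + FASTA, and qPCR /
#' ChIP-qPCR Ct tables — together with a \code{ground_truth.json} recording
#' what was planted. Deterministic given the config seed. Direct-target
#' genes receive an ERE-containing peak at a uniform distance in [0, 50 kb)
#' upstream of their primary TSS; all background peaks are placed outside
#' the 50 kb upstream windows of every DE gene, so no spurious direct-target
#' call can arise from the placement.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{files} (named paths) and
#'   \code{ground_truth}.
#' @export
simulate_bundle <- function(config = sim_config(), dir) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- cfg$genome_length
  genome_chars <- sample(BASES, L, replace = TRUE)

  ## ---- genes -------------------------------------------------------------
  margin <- 60000L
  if (L <= 2 * margin) stopf("genome too small for gene placement")
  biotype <- sample(c(rep("miRNA", cfg$n_mirna_genes),
                      rep("lncRNA", cfg$n_lncrna_genes),
                      rep("protein_coding",
                          cfg$n_genes - cfg$n_mirna_genes -
                            cfg$n_lncrna_genes)))
  glen <- integer(cfg$n_genes)
  glen[biotype == "miRNA"] <- sample(80:150, sum(biotype == "miRNA"), TRUE)
  glen[biotype == "lncRNA"] <- sample(500:2000, sum(biotype == "lncRNA"), TRUE)
  glen[biotype == "protein_coding"] <-
    sample(1000:3000, sum(biotype == "protein_coding"), TRUE)
  strand <- ifelse(stats::runif(cfg$n_genes) < cfg$strand_fraction, "+", "-")
  free <- IRanges::IRanges(margin + 1L, L - margin)
  gstart <- integer(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    s <- draw_start(free, glen[i])
    if (is.na(s)) stopf("infeasible gene placement: genome too small")
    gstart[i] <- s
    free <- IRanges::setdiff(free,
                             IRanges::IRanges(s - 500L, s + glen[i] + 499L))
  }
  ord <- order(gstart)
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
                      chrom = cfg$chrom, strand = strand[ord],
                      start = gstart[ord], end = gstart[ord] + glen[ord] - 1L,
                      biotype = biotype[ord], stringsAsFactors = FALSE)
  tss_rows <- list()
  for (i in seq_len(nrow(genes))) {
    primary <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i]
    extra <- integer(0)
    n_iso <- sample(1:3, 1)
    if (n_iso > 1 && genes$end[i] - genes$start[i] > 10)
      extra <- sample(genes$start[i]:genes$end[i], n_iso - 1)
    tss_rows[[i]] <- data.frame(gene_id = genes$gene_id[i],
                                tss = unique(c(primary, extra)),
                                stringsAsFactors = FALSE)
  }
  gm <- gene_models(genes, do.call(rbind, tss_rows))

  ## ---- differential expression -------------------------------------------
  pick_de <- function(bt, n) sample(genes$gene_id[genes$biotype == bt], n)
  de_ids <- list(mRNA = pick_de("protein_coding", cfg$n_de_mrna),
                 lncRNA = pick_de("lncRNA", cfg$n_de_lncrna),
                 miRNA = pick_de("miRNA", cfg$n_de_mirna))
  de <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  de$biotype <- c(protein_coding = "mRNA", lncRNA = "lncRNA",
                  miRNA = "miRNA")[genes$biotype]
  de$direction_true <- "ns"
  for (bt in names(de_ids)) {
    ii <- match(de_ids[[bt]], de$gene_id)
    de$direction_true[ii] <- sample(c("up", "down"), length(ii),
                                    replace = TRUE)
  }
  n <- nrow(de)
  de$effect <- stats::runif(n, -0.9, 0.9)
  de$effect[de$biotype == "miRNA"] <-
    stats::runif(sum(de$biotype == "miRNA"), 0.72, 1.38)
  de$fdr <- stats::runif(n, 0, 1)
  up <- de$direction_true == "up"; down <- de$direction_true == "down"
  mir <- de$biotype == "miRNA"
  de$effect[up & !mir] <- stats::runif(sum(up & !mir), 1, 3.5)
  de$effect[down & !mir] <- -stats::runif(sum(down & !mir), 1, 3.5)
  de$effect[up & mir] <- stats::runif(sum(up & mir), 1.5, 4)
  de$effect[down & mir] <- stats::runif(sum(down & mir), 0.25, 0.667)
  de$fdr[up | down] <- stats::runif(sum(up | down), 1e-6, 0.05)
  all_de_ids <- unlist(de_ids, use.names = FALSE)

  ## ---- peaks and planted EREs --------------------------------------------
  pw <- cfg$peak_width
  half <- pw %/% 2L
  pattern <- consensus_pattern()
  # strand-aware 50 kb upstream windows (in summit space) of every DE gene,
  # spanning all isoform TSSs (a summit qualifies via any TSS)
  up_win <- function(gid) {
    gi <- match(gid, genes$gene_id)
    tsss <- gm$tss$tss[gm$tss$gene_id == gid]
    if (genes$strand[gi] == "+")
      IRanges::IRanges(max(1L, min(tsss) - 49999L), max(tsss))
    else IRanges::IRanges(min(tsss), min(L, max(tsss) + 49999L))
  }
  de_windows <- IRanges::reduce(do.call(c, lapply(all_de_ids, up_win)))
  summit_space <- IRanges::IRanges(half + 1L, L - half)
  occupied <- IRanges::IRanges()
  blocked <- function() {
    if (length(occupied) == 0) IRanges::IRanges()
    else IRanges::IRanges(IRanges::start(occupied) - half - 1L,
                          IRanges::end(occupied) + half + 1L)
  }
  n_ere_total <- round(cfg$ere_planting_rate * cfg$n_peaks)
  peaks_acc <- list()
  add_peak <- function(summit, target_gene, plant) {
    rec <- data.frame(start = summit - half, end = summit + half,
                      summit = summit,
                      target_gene = target_gene %||% NA_character_,
                      has_ere = plant, ere_start = NA_integer_,
                      ere_seq = NA_character_, ere_strand = NA_character_,
                      ere_spacer = NA_character_, stringsAsFactors = FALSE)
    if (plant) {
      e <- make_planted_ere(pattern, cfg$spacer_cng_rate,
                            cfg$ere_planting_mismatches)
      off <- sample((summit - 90L):(summit + 90L - 14L), 1)
      genome_chars[off:(off + 14L)] <<- strsplit(e$seq, "")[[1]]
      rec$ere_start <- off; rec$ere_seq <- e$seq
      rec$ere_strand <- e$strand; rec$ere_spacer <- e$spacer
    }
    occupied <<- c(occupied, IRanges::IRanges(rec$start, rec$end))
    peaks_acc[[length(peaks_acc) + 1L]] <<- rec
  }
  # direct-target genes are drawn from the DE genes whose upstream window
  # retains free space once every other DE gene's window is excluded (the
  # windows overlap heavily at this gene density)
  targets <- character(0)
  n_ere_targets <- min(cfg$n_direct_targets, n_ere_total)
  for (gid in sample(all_de_ids)) {
    if (length(targets) >= cfg$n_direct_targets) break
    others <- IRanges::reduce(do.call(c, lapply(
      setdiff(all_de_ids, gid), up_win)))
    allowed <- IRanges::setdiff(
      IRanges::intersect(up_win(gid), summit_space), others)
    allowed <- IRanges::setdiff(allowed, blocked())
    s <- draw_position(allowed)
    if (is.na(s)) next
    targets <- c(targets, gid)
    add_peak(s, gid, plant = length(targets) <= n_ere_targets)
  }
  if (length(targets) < cfg$n_direct_targets)
    stopf(paste0("infeasible direct-target placement: only %d of %d DE ",
                 "genes have free upstream space"),
          length(targets), cfg$n_direct_targets)
  n_bg <- cfg$n_peaks - length(targets)
  n_ere_bg <- max(0L, n_ere_total - n_ere_targets)
  bg_space <- IRanges::setdiff(summit_space, de_windows)
  # ERE-carrying sites are placed first; ERE-free sites then keep their
  # summit far enough from every planted ERE that their 500 bp scan window
  # cannot reach it (250 bp half-window + 90 bp ERE offset + motif length)
  bleed_gap <- 360L
  for (k in seq_len(n_ere_bg)) {
    s <- draw_position(IRanges::setdiff(bg_space, blocked()))
    if (is.na(s)) stopf("infeasible background peak placement")
    add_peak(s, NULL, plant = TRUE)
  }
  ere_summits <- vapply(peaks_acc, `[[`, numeric(1), "summit")
  ere_summits <- ere_summits[vapply(peaks_acc, `[[`, logical(1), "has_ere")]
  ere_zone <- if (length(ere_summits) == 0) IRanges::IRanges()
              else IRanges::reduce(IRanges::IRanges(ere_summits - bleed_gap,
                                                    ere_summits + bleed_gap))
  n_free <- n_bg - n_ere_bg
  n_body <- if (is.null(cfg$body_peak_fraction)) 0L
            else round(cfg$body_peak_fraction * n_free)
  body_space <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
  for (k in seq_len(n_free)) {
    base <- if (k <= n_body) IRanges::intersect(bg_space, body_space)
            else bg_space
    s <- draw_position(IRanges::setdiff(IRanges::setdiff(base, ere_zone),
                                        blocked()))
    if (is.na(s)) stopf("infeasible background peak placement")
    add_peak(s, NULL, plant = FALSE)
  }
  peaks_df <- do.call(rbind, peaks_acc)
  ord <- order(peaks_df$start)
  peaks_df <- peaks_df[ord, , drop = FALSE]
  peaks_df$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks_df)))

  direct_truth <- peaks_df[!is.na(peaks_df$target_gene) & peaks_df$has_ere,
                           c("target_gene", "peak_id", "summit")]
  direct_truth$distance <- vapply(seq_len(nrow(direct_truth)), function(i) {
    gi <- match(direct_truth$target_gene[i], genes$gene_id)
    tsss <- gm$tss$tss[gm$tss$gene_id == direct_truth$target_gene[i]]
    d <- if (genes$strand[gi] == "+") tsss - direct_truth$summit[i]
         else direct_truth$summit[i] - tsss
    min(d[d >= 0])
  }, numeric(1))
  names(direct_truth)[1] <- "gene_id"
  direct_truth <- direct_truth[order(direct_truth$gene_id), , drop = FALSE]

  ## ---- miRNA target predictor tables -------------------------------------
  mirna_de <- de_ids$miRNA
  mrna_de <- de_ids$mRNA
  combos <- expand.grid(mirna_id = mirna_de, gene_id = mrna_de,
                        stringsAsFactors = FALSE)
  if (nrow(combos) < cfg$mirna_consensus_pairs + cfg$predictor_noise_pairs)
    stopf("not enough DE miRNA x mRNA combinations for the requested pairs")
  pick <- sample(nrow(combos),
                 cfg$mirna_consensus_pairs + cfg$predictor_noise_pairs)
  true_pairs <- combos[pick[seq_len(cfg$mirna_consensus_pairs)], ,
                       drop = FALSE]
  noise_pairs <- combos[pick[-seq_len(cfg$mirna_consensus_pairs)], ,
                        drop = FALSE]
  ns_genes <- sample(setdiff(genes$gene_id[genes$biotype == "protein_coding"],
                             mrna_de),
                     cfg$nonresponsive_consensus_pairs, replace = FALSE)
  ns_pairs <- data.frame(mirna_id = sample(mirna_de, length(ns_genes),
                                           replace = TRUE),
                         gene_id = ns_genes, stringsAsFactors = FALSE)
  preds <- list(predictorA = list(), predictorB = list(), predictorC = list())
  assign_votes <- function(pair, k) {
    for (p in sample(names(preds), k))
      preds[[p]][[length(preds[[p]]) + 1L]] <<- pair
  }
  true_pairs$votes <- sample(2:3, nrow(true_pairs), replace = TRUE,
                             prob = c(0.6, 0.4))
  for (i in seq_len(nrow(true_pairs)))
    assign_votes(true_pairs[i, c("mirna_id", "gene_id")],
                 true_pairs$votes[i])
  ns_pairs$votes <- sample(2:3, nrow(ns_pairs), replace = TRUE)
  for (i in seq_len(nrow(ns_pairs)))
    assign_votes(ns_pairs[i, c("mirna_id", "gene_id")], ns_pairs$votes[i])
  for (i in seq_len(nrow(noise_pairs)))
    assign_votes(noise_pairs[i, , drop = FALSE], 1)
  pred_tables <- lapply(preds, function(rows) {
    t <- do.call(rbind, rows)
    t$score <- round(stats::runif(nrow(t), 0.5, 1), 3)
    t[order(t$mirna_id, t$gene_id), , drop = FALSE]
  })

  ## ---- transcript records for the lncRNA cascade -------------------------
  tx <- list()
  add_tx <- function(id, seq, exon, pfam, cnci, cpc, label, expect_pass,
                     expect_fail) {
    tx[[length(tx) + 1L]] <<- list(
      row = data.frame(transcript_id = id, exon_count = exon,
                       length = nchar(seq), pfam_hit = pfam,
                       cnci_score = cnci, cpc_score = cpc,
                       stringsAsFactors = FALSE),
      seq = seq, label = label, expect_pass = expect_pass,
      expect_fail = expect_fail)
  }
  lnc_seq <- function(len) {
    for (try in 1:50) {
      s <- random_seq(len)
      if (longest_orf(s) < 300) return(s)
    }
    stopf("could not draw a short-ORF transcript sequence")
  }
  neg <- function() round(stats::runif(1, -2, -0.1), 3)
  pos <- function() round(stats::runif(1, 0.1, 2), 3)
  for (i in seq_len(cfg$n_lnc_like))
    add_tx(sprintf("lnc_like_%02d", i), lnc_seq(sample(300:2000, 1)),
           sample(2:6, 1), FALSE, neg(), neg(), "lncRNA_like", TRUE,
           NA_character_)
  for (i in seq_len(cfg$n_mrna_like))
    add_tx(sprintf("mrna_like_%02d", i),
           paste0(random_seq(50), "ATG", sense_codons(150), "TAA",
                  random_seq(50)),
           sample(4:12, 1), stats::runif(1) < 0.5, pos(), pos(),
           "mRNA_like", FALSE, "orf_lt300")
  add_tx("fail_exon", lnc_seq(600), 1, FALSE, neg(), neg(),
         "crafted_fail_exon", FALSE, "exon_ge2")
  add_tx("fail_length", lnc_seq(150), 2, FALSE, neg(), neg(),
         "crafted_fail_length", FALSE, "length_ge200")
  add_tx("fail_orf_boundary",
         paste0(random_seq(30), "ATG", sense_codons(98), "TAA",
                random_seq(30)),
         3, FALSE, neg(), neg(), "crafted_fail_orf_300", FALSE, "orf_lt300")
  add_tx("fail_pfam", lnc_seq(600), 2, TRUE, neg(), neg(),
         "crafted_fail_pfam", FALSE, "no_pfam_hit")
  add_tx("fail_cnci", lnc_seq(600), 2, FALSE, pos(), neg(),
         "crafted_fail_cnci", FALSE, "cnci_lt0")
  add_tx("fail_cpc", lnc_seq(600), 2, FALSE, neg(), pos(),
         "crafted_fail_cpc", FALSE, "cpc_lt0")
  tx_table <- do.call(rbind, lapply(tx, `[[`, "row"))
  tx_seqs <- stats::setNames(vapply(tx, `[[`, character(1), "seq"),
                             tx_table$transcript_id)
  tx_truth <- data.frame(
    transcript_id = tx_table$transcript_id,
    label = vapply(tx, `[[`, character(1), "label"),
    expected_pass = vapply(tx, `[[`, logical(1), "expect_pass"),
    expected_first_fail = vapply(tx, `[[`, character(1), "expect_fail"),
    stringsAsFactors = FALSE)

  ## ---- Ct tables ----------------------------------------------------------
  qpcr_rows <- list()
  for (target in names(cfg$qpcr_true_folds)) {
    fold <- cfg$qpcr_true_folds[[target]]
    dct0 <- stats::runif(1, 4, 9)
    for (grp in c("control", "treated")) {
      ng <- if (grp == "control") cfg$n_control else cfg$n_treated
      dct <- (if (grp == "control") dct0 else dct0 - log2(fold)) +
        stats::rnorm(ng, 0, cfg$ct_noise_sd)
      ref <- 18 + stats::runif(ng, -0.5, 0.5)
      qpcr_rows[[length(qpcr_rows) + 1L]] <- data.frame(
        target = target,
        sample_id = sprintf("%s_%s_%d", target, grp, seq_len(ng)),
        group = grp, ct_target = ref + dct,
        ct_reference = ref, reference = "ACTB",
        stringsAsFactors = FALSE)
    }
  }
  qpcr_ct <- do.call(rbind, qpcr_rows)
  chip_ct <- data.frame(
    locus_id = names(cfg$chip_true_folds),
    ct_ip = 28 - log2(unlist(cfg$chip_true_folds)) +
      stats::rnorm(length(cfg$chip_true_folds), 0, cfg$ct_noise_sd),
    ct_input = 22 + stats::runif(length(cfg$chip_true_folds), -0.5, 0.5),
    ct_igg = 28,
    input_fraction = cfg$chip_input_fraction,
    stringsAsFactors = FALSE)

  ## ---- write the bundle ---------------------------------------------------
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(genome_chars, collapse = ""), cfg$chrom))
  files <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "genes.gtf"),
             peaks = file.path(dir, "peaks.bed"),
             de = file.path(dir, "de_genes.tsv"),
             predictorA = file.path(dir, "predictorA.tsv"),
             predictorB = file.path(dir, "predictorB.tsv"),
             predictorC = file.path(dir, "predictorC.tsv"),
             transcripts = file.path(dir, "transcripts.tsv"),
             transcripts_fa = file.path(dir, "transcripts.fa"),
             qpcr = file.path(dir, "qpcr_ct.tsv"),
             chip = file.path(dir, "chip_ct.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_genome_fasta(genome, files["genome"])
  write_gtf(gm, files["gtf"])
  bed <- data.frame(cfg$chrom, peaks_df$start - 1L, peaks_df$end,
                    peaks_df$peak_id, 0L, ".")
  utils::write.table(bed, files["peaks"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  write_tsv(de[, c("gene_id", "biotype", "effect", "fdr")], files["de"])
  for (p in names(pred_tables)) write_tsv(pred_tables[[p]], files[p])
  write_tsv(tx_table, files["transcripts"])
  write_genome_fasta(Biostrings::DNAStringSet(tx_seqs),
                     files["transcripts_fa"])
  write_tsv(qpcr_ct, files["qpcr"])
  write_tsv(chip_ct, files["chip"])

  ground_truth <- list(
    config = unclass(cfg),
    n_peaks = nrow(peaks_df),
    n_ere_planted = sum(peaks_df$has_ere),
    eres = peaks_df[peaks_df$has_ere,
                    c("peak_id", "ere_start", "ere_strand", "ere_seq",
                      "ere_spacer")],
    peak_ere_count = data.frame(peak_id = peaks_df$peak_id,
                                n_planted = as.integer(peaks_df$has_ere),
                                stringsAsFactors = FALSE),
    de = de[, c("gene_id", "biotype", "direction_true", "effect", "fdr")],
    direct_targets = direct_truth[, c("gene_id", "peak_id", "distance")],
    consensus_pairs = rbind(true_pairs, ns_pairs),
    network_pairs = true_pairs,
    transcripts = tx_truth,
    qpcr_true_folds = as.list(cfg$qpcr_true_folds),
    chip_true_folds = as.list(cfg$chip_true_folds))
  jsonlite::write_json(ground_truth, files["ground_truth"],
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", pretty = TRUE)
  invisible(list(files = files, ground_truth = ground_truth))
}

#' Cross-validate a generated bundle against its ground truth
#'
#' Re-reads the emitted files with the package's own readers and checks that
#' they agree with \code{ground_truth.json}: every planted ERE sequence is
#' present at its recorded genome location, gene and peak counts match, DE
#' directions recomputed by \code{\link{call_de}} equal the planted ones,
#' and the lncRNA cascade reproduces the planted transcript labels.
#'
#' @param dir a bundle directory from \code{\link{simulate_bundle}}.
#' @return invisibly TRUE; inconsistencies are errors.
#' @export
check_bundle <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  gm <- read_gtf(file.path(dir, "genes.gtf"))
  peaks <- read_peaks(file.path(dir, "peaks.bed"))
  if (nrow(gm$genes) != gt$config$n_genes)
    stopf("gene count mismatch: %d vs %d", nrow(gm$genes),
          gt$config$n_genes)
  if (length(peaks) != gt$n_peaks)
    stopf("peak count mismatch")
  chrom <- gt$config$chrom
  eres <- as.data.frame(gt$eres)
  for (i in seq_len(nrow(eres))) {
    obs <- as.character(Biostrings::subseq(genome[[chrom]],
                                           eres$ere_start[i],
                                           eres$ere_start[i] + 14L))
    if (obs != eres$ere_seq[i])
      stopf("planted ERE mismatch at %s", eres$peak_id[i])
  }
  de <- call_de(read_de_table(file.path(dir, "de_genes.tsv")))
  truth <- as.data.frame(gt$de)
  if (!identical(de$direction[match(truth$gene_id, de$gene_id)],
                 truth$direction_true))
    stopf("recomputed DE directions differ from planted ones")
  tx <- read_tsv_strict(file.path(dir, "transcripts.tsv"))
  seqs <- read_genome_fasta(file.path(dir, "transcripts.fa"))
  res <- filter_lncrna(tx, seqs)
  tx_truth <- as.data.frame(gt$transcripts)
  obs_pass <- tx_truth$transcript_id %in% res$passing
  if (!identical(obs_pass, tx_truth$expected_pass))
    stopf("lncRNA cascade verdicts differ from planted labels")
  invisible(TRUE)
}
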