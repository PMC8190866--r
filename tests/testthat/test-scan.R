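plant_in <- function(seq, ere, at) {
  paste0(substr(seq, 1, at - 1), ere,
         substr(seq, at + nchar(ere), nchar(seq)))
}

test_that("a planted consensus ERE yields exactly one zero-mismatch hit", {
  set.seed(5)
  s <- plant_in(random_dna(600), "AGGTCAACGTGACCT", 300)
  genome <- make_genome(chr1 = s)
  peaks <- make_peaks("chr1", 250L, 450L, "pk1")
  hits <- scan_peaks(genome, peaks)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$start, 300L)
  expect_equal(hits$match_seq, "AGGTCAACGTGACCT")
  expect_lt(hits$p_value, 5e-4)
})

test_that("scanning is invariant under reverse complement of the genome", {
  set.seed(6)
  s <- random_dna(1400)
  s <- plant_in(s, "AGGTCACAGTGACCT", 500)
  s <- plant_in(s, "AGGTCATTTTGACCT", 820)
  genome <- make_genome(chr1 = s)
  peaks <- make_peaks("chr1", c(450L, 780L), c(650L, 980L), c("p1", "p2"))
  fwd <- scan_peaks(genome, peaks)
  n <- nchar(s)
  rc_genome <- make_genome(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  rc_peaks <- mirror_peaks(peaks, n)
  rev <- scan_peaks(rc_genome, rc_peaks)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(sort(table(rev$peak_id)), sort(table(fwd$peak_id)))
  # with a spacer the matching orientation can flip, so compare hits by
  # their strand-canonical form
  canon <- function(s) pmin(s, vapply(s, function(x)
    eretarget:::revcomp_chr(x), character(1)))
  expect_equal(sort(canon(rev$match_seq)), sort(canon(fwd$match_seq)))
  expect_equal(sort(rev$score), sort(fwd$score))
  expect_equal(sort(rev$mismatches), sort(fwd$mismatches))
})

test_that("windows containing N never score and clipping warns", {
  genome <- make_genome(chr1 = strrep("N", 800))
  peaks <- make_peaks("chr1", 300L, 500L, "pN")
  expect_equal(nrow(scan_peaks(genome, peaks)), 0L)

  genome2 <- make_genome(chr1 = random_dna(300))
  peaks2 <- make_peaks("chr1", 1L, 201L, "pEdge")
  expect_warning(scan_peaks(genome2, peaks2), "clipped")
})

test_that("overlapping occurrences resolve to distinct non-overlapping EREs", {
  set.seed(7)
  # two planted EREs 20 bp apart: both must be reported and not collapse
  s <- random_dna(600)
  s <- plant_in(s, "AGGTCAACGTGACCT", 290)
  s <- plant_in(s, "AGGTCAGGGTGACCT", 310)
  genome <- make_genome(chr1 = s)
  hits <- scan_peaks(genome, make_peaks("chr1", 200L, 400L, "pk"))
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$end[1] < hits$start[2]))
  # p-value is monotone non-increasing in score across hits
  ord <- order(hits$score)
  expect_true(all(diff(hits$p_value[ord]) <= 0))
})

test_that("site classification partitions peaks and counts EREs", {
  set.seed(8)
  s <- random_dna(2600)
  s <- plant_in(s, "AGGTCAACGTGACCT", 500)           # one in p2
  s <- plant_in(s, "AGGTCATCGTGACCT", 1300)          # two in p3
  s <- plant_in(s, "AGGTCAGACTGACCT", 1350)
  genome <- make_genome(chr1 = s)
  peaks <- make_peaks("chr1", c(1900L, 400L, 1250L), c(2100L, 600L, 1450L),
                      c("p1", "p2", "p3"))
  hits <- scan_peaks(genome, peaks)
  cls <- classify_sites(peaks, hits)
  expect_equal(unname(cls$counts), c(1L, 1L, 1L))
  expect_equal(cls$per_peak$class, c("zero", "one", "multiple"))
  expect_equal(cls$fraction_with_ere, 2 / 3)
  expect_equal(sum(cls$counts), length(peaks))

  # degenerate empty hit list: everything class zero
  cls0 <- classify_sites(peaks, hits[0, ])
  expect_equal(unname(cls0$counts), c(3L, 0L, 0L))
  expect_equal(cls0$fraction_with_ere, 0)

  bad <- hits; bad$peak_id[1] <- "ghost"
  expect_error(classify_sites(peaks, bad), "unknown peak id.*ghost")
})

test_that("motif reconstruction recovers the consensus and spacer bias", {
  hits1 <- data.frame(match_seq = rep("AGGTCACCGTGACCT", 5))
  rec <- reconstruct_motif(hits1)
  expect_equal(rec$consensus, "AGGTCACCGTGACCT")
  expect_equal(rec$spacer_composition$spacer[1], "CCG")
  expect_equal(rec$spacer_composition$frequency[1], 1)
  expect_equal(unname(colSums(rec$motif$counts)), rep(5, 15))
  expect_error(reconstruct_motif(hits1[0, , drop = FALSE]), "zero hits")

  # self-consistency: hits scanned from planted consensus sites reconstruct
  # a matrix whose per-column argmax is the pattern at fixed positions
  set.seed(9)
  s <- random_dna(3100)
  at <- seq(400, 2700, by = 300)
  for (a in at)
    s <- plant_in(s, paste0("AGGTCA", random_dna(3), "TGACCT"), a)
  genome <- make_genome(chr1 = s)
  peaks <- make_peaks("chr1", at - 80L, at + 120L,
                      sprintf("pk%02d", seq_along(at)))
  hits <- scan_peaks(genome, peaks)
  rec2 <- reconstruct_motif(hits)
  pat <- strsplit("AGGTCAnnnTGACCT", "")[[1]]
  fixed <- pat %in% bases4
  expect_equal(strsplit(rec2$consensus, "")[[1]][fixed], pat[fixed])
})
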