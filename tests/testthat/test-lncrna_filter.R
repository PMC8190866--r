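test_that("longest ORF handles frames, offsets and the empty case", {
  expect_equal(longest_orf("ATGAAATAG"), 9L)
  expect_equal(longest_orf("CCCATGTTTTAA"), 9L)   # frame offset 3
  expect_equal(longest_orf("ATGATGAAATAG"), 12L)  # earliest ATG wins
  expect_equal(longest_orf("AAACCCGGGTTT"), 0L)   # no ORF at all
  expect_equal(longest_orf("ATGAAA"), 0L)         # ATG without a stop
  expect_equal(longest_orf(""), 0L)
})

test_that("longest ORF matches the brute-force ATG..stop oracle", {
  set.seed(31)
  for (i in 1:8) {
    s <- random_dna(sample(500:2000, 1))
    expect_equal(longest_orf(s), orf_oracle(s))
  }
})

lnc_record <- function(id = "t1", exon = 2L, len = 500L, pfam = FALSE,
                       cnci = -0.5, cpc = -0.5, orf = 100L) {
  data.frame(transcript_id = id, exon_count = exon, length = len,
             pfam_hit = pfam, cnci_score = cnci, cpc_score = cpc,
             orf_length = orf, stringsAsFactors = FALSE)
}

test_that("the six-criterion cascade passes and fails at the right boundaries", {
  # boundary case from the criteria as printed: length 200 inclusive,
  # ORF < 300 strict
  ok <- lnc_record(len = 200L, orf = 299L, cnci = -0.1, cpc = -0.1)
  expect_equal(filter_lncrna(ok)$passing, "t1")
  expect_equal(filter_lncrna(lnc_record(orf = 300L))$passing, character(0))
  expect_equal(filter_lncrna(lnc_record(len = 199L))$passing, character(0))
  expect_equal(filter_lncrna(lnc_record(exon = 1L))$passing, character(0))
  expect_equal(filter_lncrna(lnc_record(cnci = 0))$passing, character(0))
  expect_equal(filter_lncrna(lnc_record(cpc = 0))$passing, character(0))
  expect_equal(filter_lncrna(lnc_record(pfam = TRUE))$passing, character(0))

  tr <- filter_lncrna(lnc_record(exon = 1L, pfam = TRUE))$trace
  expect_equal(tr$first_fail, "exon_ge2")  # first criterion in order
  expect_false(tr$pass)
})

test_that("the verdict equals the conjunction of all six criteria", {
  set.seed(32)
  recs <- do.call(rbind, lapply(1:40, function(i)
    lnc_record(id = sprintf("t%02d", i),
               exon = sample(1:5, 1), len = sample(c(150, 250, 500), 1),
               pfam = sample(c(TRUE, FALSE), 1),
               cnci = round(stats::runif(1, -1, 1), 2),
               cpc = round(stats::runif(1, -1, 1), 2),
               orf = sample(c(100, 299, 300, 600), 1))))
  res <- filter_lncrna(recs)
  manual <- recs$exon_count >= 2 & recs$length >= 200 &
    recs$orf_length < 300 & !recs$pfam_hit &
    recs$cnci_score < 0 & recs$cpc_score < 0
  expect_equal(res$trace$pass, manual)
  expect_equal(res$passing, recs$transcript_id[manual])
  expect_equal(rowSums(res$trace[eretarget:::LNC_CRITERIA]) == 6,
               unname(manual))
})

test_that("sequences override the ORF column and missing fields are named", {
  rec <- lnc_record(orf = 600L)   # column says fail ...
  seqs <- c(t1 = paste0("CC", "ATGAAATAG", random_dna(400)))
  expect_equal(filter_lncrna(rec, seqs)$passing, "t1")  # ... sequence says 9

  rec2 <- lnc_record()
  rec2$orf_length <- NULL
  expect_error(filter_lncrna(rec2), "t1: missing field orf_length")
  rec3 <- lnc_record(); rec3$cnci_score <- NA
  expect_error(filter_lncrna(rec3), "t1: missing value in field cnci_score")
})
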