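test_that("FASTA reading uppercases, validates and round-trips", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chrA", "acgtACGTacgt", ">chrB", strrep("GATTACA", 10)), f)
  g <- read_genome_fasta(f)
  expect_named(g, c("chrA", "chrB"))
  expect_equal(as.character(g[["chrA"]]), "ACGTACGTACGT")
  expect_equal(Biostrings::width(g), c(12L, 70L))

  f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f2)
  expect_equal(as.character(read_genome_fasta(f2)),
               as.character(g))

  dupf <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "TTTT"), dupf)
  expect_error(read_genome_fasta(dupf), "duplicate sequence name.*x")

  emptyf <- tempfile(fileext = ".fa")
  writeLines(character(0), emptyf)
  expect_error(read_genome_fasta(emptyf))
})

test_that("GTF parsing applies strand-aware TSS rules and collapses duplicates", {
  f <- tempfile(fileext = ".gtf")
  attrs <- function(g, t, b = "protein_coding")
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";', g, t, b)
  writeLines(c(
    paste("chr1", "src", "gene", 1001, 2000, ".", "-", ".",
          sub('transcript_id "[^"]*"; ', "", attrs("gA", "")), sep = "\t"),
    paste("chr1", "src", "transcript", 1001, 2000, ".", "-", ".",
          attrs("gA", "gA.t1"), sep = "\t"),
    paste("chr1", "src", "gene", 5000, 9000, ".", "+", ".",
          sub('transcript_id "[^"]*"; ', "", attrs("gB", "")), sep = "\t"),
    paste("chr1", "src", "transcript", 5000, 7000, ".", "+", ".",
          attrs("gB", "gB.t1"), sep = "\t"),
    paste("chr1", "src", "transcript", 5000, 9000, ".", "+", ".",
          attrs("gB", "gB.t2"), sep = "\t")), f)
  gm <- read_gtf(f)
  # minus-strand TSS sits at the body end (GTF span 1001..2000 -> TSS 2000,
  # i.e. 0-based 1999)
  expect_equal(gm$tss$tss[gm$tss$gene_id == "gA"], 2000)
  # two isoforms sharing a start collapse to one TSS
  expect_equal(gm$tss$tss[gm$tss$gene_id == "gB"], 5000)
  expect_equal(nrow(gm$genes), 2L)

  # transcript without a parent gene feature
  orphan <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "transcript", 10, 20, ".", "+", ".",
                   attrs("nope", "nope.t1"), sep = "\t"), orphan)
  expect_error(read_gtf(orphan), "without a parent gene")

  bad <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "gene", 500, 100, ".", "+", ".",
                   'gene_id "g";', sep = "\t"), bad)
  expect_error(read_gtf(bad), "line 1: end < start")
})

test_that("GTF writing round-trips through the reader", {
  gm <- gene_models(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       strand = c("+", "-"), start = c(100L, 5000L),
                       end = c(2000L, 9000L),
                       biotype = c("protein_coding", "lncRNA")),
    tss = data.frame(gene_id = c("g1", "g1", "g2"),
                     tss = c(100L, 500L, 9000L)))
  f <- tempfile(fileext = ".gtf")
  write_gtf(gm, f)
  back <- read_gtf(f)
  expect_equal(back$genes, gm$genes)
  expect_equal(back$tss, gm$tss)
})

test_that("BED peaks read 0-based half-open, merge handles overlap and abutting", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tp1", "chr1\t15\t30\tp2", "chr1\t20\t30\tp3",
               "chr2\t0\t100\tp4"), f)
  pk <- read_peaks(f)
  expect_equal(length(pk), 4L)
  expect_equal(GenomicRanges::start(pk)[1], 11L)  # 1-based internal
  expect_equal(GenomicRanges::end(pk)[1], 20L)

  m <- merge_peaks(pk)
  # [10,20)+[15,30) overlap and [20,30) abuts: one interval [10,30)
  expect_equal(length(m), 2L)
  expect_equal(GenomicRanges::start(m), c(11L, 1L))
  expect_equal(GenomicRanges::end(m), c(30L, 100L))
  # idempotent
  m2 <- merge_peaks(m)
  expect_equal(GenomicRanges::ranges(m2), GenomicRanges::ranges(m))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t50\t50"), bad)
  expect_error(read_peaks(bad), "line 2: start >= end")
})

test_that("peak write-back preserves extra BED columns and coordinates", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t301\tpkA\t17\t+", "chr1\t400\t601\tpkB\t3\t-"), f)
  pk <- read_peaks(f)
  out <- tempfile(fileext = ".bed")
  write_peaks(pk, out)
  expect_identical(readLines(out), readLines(f))
  # summit is the interval midpoint
  expect_equal(S4Vectors::mcols(pk)$summit, c(201L, 501L))
})
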