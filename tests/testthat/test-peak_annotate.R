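test_that("upstream distances are signed and strand-aware", {
  gm <- gene_models(
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       start = 10001L, end = 12000L,
                       biotype = "protein_coding"),
    tss = data.frame(gene_id = "g1", tss = 10001L))
  pk <- make_peaks("chr1", 9401L, 9601L, "p", summit = 9501L)
  ann <- annotate_peaks(pk, gm)
  expect_equal(ann$signed_distance, -500)
  expect_equal(ann$category, "upstream_lt2kb")

  # minus-strand gene body [8001, 10000], TSS 10000; summit 10401 is 401 bp
  # upstream in the gene's orientation
  gm2 <- gene_models(
    genes = data.frame(gene_id = "g2", chrom = "chr1", strand = "-",
                       start = 8001L, end = 10000L,
                       biotype = "protein_coding"),
    tss = data.frame(gene_id = "g2", tss = 10000L))
  pk2 <- make_peaks("chr1", 10301L, 10501L, "p", summit = 10401L)
  ann2 <- annotate_peaks(pk2, gm2)
  expect_equal(ann2$signed_distance, -401)
  expect_equal(ann2$category, "upstream_lt2kb")
})

test_that("gene body takes precedence over a nearby foreign TSS", {
  gm <- gene_models(
    genes = data.frame(gene_id = c("host", "nearby"), chrom = "chr1",
                       strand = "+", start = c(5000L, 8000L),
                       end = c(7000L, 9000L), biotype = "protein_coding"),
    tss = data.frame(gene_id = c("host", "nearby"), tss = c(5000L, 8000L)))
  # summit inside host's body, 1500 bp from nearby's TSS
  pk <- make_peaks("chr1", 6401L, 6601L, "p", summit = 6500L)
  expect_equal(annotate_peaks(pk, gm)$category, "gene_body")
})

test_that("downstream and distal categories complete the partition", {
  gm <- gene_models(
    genes = data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                       start = 1000L, end = 2000L,
                       biotype = "protein_coding"),
    tss = data.frame(gene_id = "g", tss = 1000L))
  mk <- function(sm) make_peaks("chr1", sm - 50L, sm + 50L, "p", summit = sm)
  expect_equal(annotate_peaks(mk(2500L), gm)$category, "downstream")
  expect_equal(annotate_peaks(mk(60000L), gm)$category, "distal")
  # upstream bin edges are half-open on the outer edge
  expect_equal(annotate_peaks(mk(1000L - 1999L), gm)$category,
               "upstream_lt2kb")
  expect_equal(annotate_peaks(mk(1000L - 2000L), gm)$category,
               "upstream_2_10kb")
  expect_equal(annotate_peaks(mk(1000L - 10000L), gm)$category,
               "upstream_10_50kb")
})

test_that("localization summary sums to one and rejects empty input", {
  gm <- gene_models(
    genes = data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                       start = 5000L, end = 8000L,
                       biotype = "protein_coding"),
    tss = data.frame(gene_id = "g", tss = 5000L))
  pk <- make_peaks("chr1", c(4401L, 5501L, 6001L, 8501L),
                   c(4601L, 5701L, 6201L, 8701L),
                   sprintf("p%d", 1:4))
  ann <- annotate_peaks(pk, gm)
  ls <- localization_summary(ann)
  expect_equal(sum(ls$fraction), 1)
  expect_equal(sum(ls$count), 4L)
  expect_equal(ls$fraction[ls$category == "gene_body"], 0.5)
  expect_error(localization_summary(ann[0, ]), "no annotations")

  # a chromosome without genes is all distal
  pk2 <- make_peaks("chrEmpty", 100L, 300L, "px")
  expect_equal(annotate_peaks(pk2, gm)$category, "distal")
})

test_that("annotation is invariant under gene order and coordinate mirroring", {
  set.seed(21)
  dir <- shared_bundle_dir()
  gm <- read_gtf(file.path(dir, "genes.gtf"))
  peaks <- read_peaks(file.path(dir, "peaks.bed"))
  ann <- annotate_peaks(peaks, gm)

  perm <- sample(nrow(gm$genes))
  gm_perm <- gene_models(gm$genes[perm, ], gm$tss)
  expect_equal(annotate_peaks(peaks, gm_perm), ann)

  len <- read_ground_truth(dir)$config$genome_length
  ann_mirror <- annotate_peaks(mirror_peaks(peaks, len),
                               mirror_gene_models(gm, len))
  expect_equal(table(ann_mirror$category), table(ann$category))
  expect_equal(ann_mirror$gene_id, ann$gene_id)
})
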