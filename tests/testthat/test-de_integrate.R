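de_row <- function(id, bt, eff, fdr)
  data.frame(gene_id = id, biotype = bt, effect = eff, fdr = fdr,
             stringsAsFactors = FALSE)

test_that("DE calling honours the printed thresholds at their boundaries", {
  de <- rbind(de_row("a", "mRNA", 1.0, 0.05),     # inclusive boundary: up
              de_row("b", "mRNA", 0.99, 0.001),   # below |lfc|: ns
              de_row("c", "mRNA", -1.0, 0.05),    # down
              de_row("d", "mRNA", 2.0, 0.0500001),# fdr above: ns
              de_row("e", "miRNA", 1.5, 0.05),    # up
              de_row("f", "miRNA", 0.667, 0.01),  # down at printed boundary
              de_row("g", "miRNA", 0.668, 0.01),  # just inside: ns
              de_row("h", "lncRNA", -3, 0.01))    # down
  out <- call_de(de)
  expect_equal(out$direction,
               c("up", "ns", "down", "ns", "up", "down", "ns", "down"))
  # calling is idempotent and partitions every record
  expect_equal(call_de(out)$direction, out$direction)
  expect_true(all(out$direction %in% c("up", "down", "ns")))
  expect_error(call_de(de_row("x", "miRNA", -0.5, 0.01)),
               "must be positive")
})

direct_fixture <- function(summit_offsets, plant_ere = TRUE) {
  # one + strand gene with TSS at 100000; peaks at given upstream distances
  gm <- gene_models(
    genes = data.frame(gene_id = "gDE", chrom = "chr1", strand = "+",
                       start = 100000L, end = 105000L, biotype = "protein_coding"),
    tss = data.frame(gene_id = "gDE", tss = 100000L))
  summits <- 100000L - summit_offsets
  peaks <- make_peaks("chr1", summits - 100L, summits + 100L,
                      sprintf("pk%d", seq_along(summits)), summit = summits)
  hits <- if (plant_ere)
    data.frame(peak_id = sprintf("pk%d", seq_along(summits)),
               stringsAsFactors = FALSE)
  else data.frame(peak_id = character(0), stringsAsFactors = FALSE)
  de <- call_de(de_row("gDE", "mRNA", 2, 0.01))
  list(de = de, peaks = peaks, gm = gm, hits = hits)
}

test_that("the direct-target rule is strict at 50 kb and needs an ERE", {
  fx <- direct_fixture(49999L)
  expect_equal(call_direct_targets(fx$de, fx$peaks, fx$gm, fx$hits)$gene_id,
               "gDE")
  expect_equal(call_direct_targets(fx$de, fx$peaks, fx$gm,
                                   fx$hits)$min_upstream_distance, 49999)
  fx2 <- direct_fixture(50000L)
  expect_equal(nrow(call_direct_targets(fx2$de, fx2$peaks, fx2$gm,
                                        fx2$hits)), 0L)
  fx3 <- direct_fixture(50001L)
  expect_equal(nrow(call_direct_targets(fx3$de, fx3$peaks, fx3$gm,
                                        fx3$hits)), 0L)
  # the summit exactly at the TSS qualifies
  fx0 <- direct_fixture(0L)
  expect_equal(nrow(call_direct_targets(fx0$de, fx0$peaks, fx0$gm,
                                        fx0$hits)), 1L)
  # an ERE-free site 1 kb upstream does not support a call ...
  fx4 <- direct_fixture(1000L, plant_ere = FALSE)
  expect_equal(nrow(call_direct_targets(fx4$de, fx4$peaks, fx4$gm,
                                        fx4$hits)), 0L)
  # ... unless the ERE requirement is relaxed
  expect_equal(nrow(call_direct_targets(fx4$de, fx4$peaks, fx4$gm,
                                        fx4$hits, require_ere = FALSE)), 1L)
})

test_that("direct-target calls shrink as max_upstream tightens", {
  fx <- direct_fixture(c(500L, 15000L, 40000L))
  n_at <- function(mu) nrow(call_direct_targets(fx$de, fx$peaks, fx$gm,
                                                fx$hits, max_upstream = mu))
  expect_equal(n_at(50000), 1L)  # one gene, several supporting peaks
  got <- call_direct_targets(fx$de, fx$peaks, fx$gm, fx$hits)
  expect_equal(got$n_peaks, 3L)
  expect_equal(got$min_upstream_distance, 500)
  expect_true(all(diff(vapply(c(100, 1000, 20000, 50000), n_at,
                              integer(1))) >= 0))
})

test_that("direct-target calling validates cross-references", {
  fx <- direct_fixture(1000L)
  expect_error(call_direct_targets(fx$de, fx$peaks, fx$gm,
                                   data.frame(peak_id = "ghost")),
               "unknown peak id")
  de_bad <- call_de(de_row("missing_gene", "mRNA", 2, 0.01))
  expect_error(call_direct_targets(de_bad, fx$peaks, fx$gm, fx$hits),
               "not in the gene models")
  expect_error(call_direct_targets(fx$de["effect"], fx$peaks, fx$gm,
                                   fx$hits), "direction")
})

test_that("fold enrichment follows GeneRatio / BgRatio and the exact tail", {
  term_table <- data.frame(
    term_id = rep("T1", 50),
    gene_id = sprintf("g%03d", 1:50), stringsAsFactors = FALSE)
  universe <- sprintf("g%03d", 1:1000)
  de <- c(sprintf("g%03d", 1:5), sprintf("x%d", 1:5))
  universe <- union(universe, sprintf("x%d", 1:5))
  res <- enrich(de, term_table, universe)
  expect_equal(res$k, 5L)
  expect_equal(res$n, 10L)
  expect_equal(res$K, 50L)
  expect_equal(res$fold_enrichment, (5 / 10) / (50 / res$N))

  # saturation: every DE gene in the term and the term is the universe
  sat <- enrich(sprintf("s%d", 1:4),
                data.frame(term_id = "all", gene_id = sprintf("s%d", 1:4)))
  expect_equal(sat$fold_enrichment, 1.0)
  expect_equal(sat$p_value, 1.0)

  # exhaustive enumeration oracle at N = 20
  tt <- data.frame(term_id = "t", gene_id = sprintf("u%02d", 1:6))
  uni <- sprintf("u%02d", 1:20)
  for (k_needed in 1:3) {
    de_small <- c(sprintf("u%02d", seq_len(k_needed)),
                  sprintf("u%02d", 7:(7 + 5 - k_needed - 1)))
    r <- enrich(de_small, tt, uni)
    expect_equal(r$p_value, hyper_oracle(k_needed, 6, 20, 5),
                 tolerance = 1e-12)
  }

  expect_error(enrich(c("g001", "nope"), term_table, universe),
               "outside the background universe")
  expect_warning(
    enrich("g001", rbind(term_table,
                         data.frame(term_id = "empty", gene_id = "zzz")),
           universe),
    "no gene in the universe")
})

test_that("BH q-values preserve the p-value ordering", {
  set.seed(3)
  terms <- lapply(1:8, function(i)
    data.frame(term_id = sprintf("T%d", i),
               gene_id = sample(sprintf("g%03d", 1:200), 30)))
  res <- enrich(sprintf("g%03d", 1:40), do.call(rbind, terms),
                sprintf("g%03d", 1:200))
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})
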