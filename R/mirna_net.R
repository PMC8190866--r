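#' Consensus miRNA-target pairs across prediction tables
#'
#' A (miRNA, gene) pair is retained iff it is positively predicted by at
#' least \code{min_votes} of the supplied predictor tables (default 2 of 3).
#' Duplicate pairs within one table are collapsed with a warning. Invariant
#' under table order.
#'
#' @param tables named list (>= 2) of data.frames with columns mirna_id and
#'   gene_id.
#' @param min_votes minimum number of supporting predictors.
#' @return data.frame mirna_id, gene_id, votes, sorted.
#' @export
consensus_pairs <- function(tables, min_votes = 2) {
  if (length(tables) < 2) stopf("need at least 2 prediction tables")
  keysets <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    miss <- setdiff(c("mirna_id", "gene_id"), names(t))
    if (length(miss) > 0)
      stopf("prediction table %d missing column(s): %s", i,
            paste(miss, collapse = ", "))
    key <- paste(t$mirna_id, t$gene_id, sep = "\r")
    if (anyDuplicated(key)) {
      warnf("prediction table %s: %d duplicate pair(s) collapsed",
            names(tables)[i] %||% i, sum(duplicated(key)))
      key <- unique(key)
    }
    key
  })
  votes <- table(unlist(keysets))
  keep <- names(votes)[votes >= min_votes]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[`, character(1), 1),
    gene_id = vapply(parts, `[`, character(1), 2),
    votes = as.integer(votes[keep]),
    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the miRNA-mRNA consensus target network
#'
#' Restricts consensus pairs to estrogen-responsive nodes (both the miRNA
#' and the target gene have direction up or down) and returns a bipartite
#' edge list plus a node attribute table carrying directions for rendering.
#' No expression-anticorrelation filter is applied: same-direction pairs are
#' kept.
#'
#' @param pairs data.frame from \code{\link{consensus_pairs}}.
#' @param de a DE table with directions set (\code{\link{call_de}}).
#' @return list with \code{edges} (mirna_id, gene_id, votes,
#'   mirna_direction, gene_direction) and \code{nodes} (node_id, type,
#'   direction).
#' @export
build_network <- function(pairs, de) {
  if (!"direction" %in% names(de))
    stopf("DE table has no direction column; run call_de() first")
  resp <- de[de$direction %in% c("up", "down"), , drop = FALSE]
  mir <- resp[resp$biotype == "miRNA", , drop = FALSE]
  gen <- resp[resp$biotype != "miRNA", , drop = FALSE]
  keep <- pairs$mirna_id %in% mir$gene_id & pairs$gene_id %in% gen$gene_id
  edges <- pairs[keep, , drop = FALSE]
  edges$mirna_direction <- mir$direction[match(edges$mirna_id, mir$gene_id)]
  edges$gene_direction <- gen$direction[match(edges$gene_id, gen$gene_id)]
  rownames(edges) <- NULL
  node_ids <- unique(c(edges$mirna_id, edges$gene_id))
  nodes <- data.frame(
    node_id = node_ids,
    type = ifelse(node_ids %in% mir$gene_id, "miRNA", "gene"),
    direction = resp$direction[match(node_ids, resp$gene_id)],
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Export a consensus network as GraphML
#'
#' @param network a list from \code{\link{build_network}}.
#' @param path output .graphml path.
#' @export
write_network_graphml <- function(network, path) {
  if (nrow(network$edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("mirna_id", "gene_id", "votes")],
      directed = FALSE,
      vertices = network$nodes)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Transcripts-per-million normalization
#'
#' \code{tpm_i = counts_i / sum(counts) * 1e6}; the result sums to 1e6.
#'
#' @param counts non-negative numeric vector with a positive total.
#' @return TPM values, names preserved.
#' @export
tpm_normalize <- function(counts) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stopf("cannot TPM-normalize an all-zero count vector")
  counts / total * 1e6
}
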