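#' Relative expression by the 2^-ddCt method
#'
#' Per sample: dCt = Ct(target) - Ct(reference); ddCt = dCt - mean dCt of the
#' control group; fold = 2^-ddCt. The control-group mean fold is 1 by
#' construction when a single control sample defines the baseline, and the
#' control group's log2 folds always average 0.
#'
#' @param ct data.frame with columns sample_id, group ("treated"/"control"),
#'   ct_target, ct_reference and optionally reference (the reference assay
#'   name, e.g. beta-actin or U6; mixing assay names is an error).
#' @return list with \code{per_sample} (dct, ddct, fold) and \code{group}
#'   (group, n, mean_fold, sem_fold, mean_log2_fold).
#' @export
ddct_fold_change <- function(ct) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0)
    stopf("Ct table missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(ct$group %in% c("treated", "control")))
    stopf("group must be 'treated' or 'control'")
  if (!any(ct$group == "control")) stopf("no control samples")
  if ("reference" %in% names(ct) && length(unique(ct$reference)) > 1)
    stopf("mismatched reference assays: %s",
          paste(unique(ct$reference), collapse = " vs "))
  dct <- ct$ct_target - ct$ct_reference
  baseline <- mean(dct[ct$group == "control"])
  ddct <- dct - baseline
  fold <- 2^(-ddct)
  per_sample <- data.frame(sample_id = ct$sample_id, group = ct$group,
                           dct = dct, ddct = ddct, fold = fold,
                           stringsAsFactors = FALSE)
  grp <- lapply(split(per_sample, per_sample$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               mean_fold = mean(g$fold),
               sem_fold = if (nrow(g) > 1)
                 stats::sd(g$fold) / sqrt(nrow(g)) else NA_real_,
               mean_log2_fold = mean(-g$ddct),
               stringsAsFactors = FALSE))
  group <- do.call(rbind, grp)
  rownames(group) <- NULL
  list(per_sample = per_sample, group = group)
}

#' ChIP-qPCR fold enrichment with percent-input correction
#'
#' dCt(IP) = Ct(IP) - Ct(input) - log2(1/input_fraction), likewise for the
#' IgG control; ddCt = dCt(IP) - dCt(IgG); fold enrichment = 2^-ddCt. The
#' input-fraction term cancels in ddCt but is retained so the per-antibody
#' dCt values are on the percent-input scale (the default 0.2 reflects 20%
#' of starting chromatin kept as input).
#'
#' @param ct_ip,ct_input,ct_igg Ct vectors for the specific antibody, the
#'   input chromatin, and the IgG control.
#' @param input_fraction fraction of chromatin used as input, in (0, 1].
#' @return data.frame dct_ip, dct_igg, ddct, fold_enrichment.
#' @export
chip_fold_enrichment <- function(ct_ip, ct_input, ct_igg,
                                 input_fraction = 0.2) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stopf("input_fraction must lie in (0, 1]")
  adj <- log2(1 / input_fraction)
  dct_ip <- ct_ip - ct_input - adj
  dct_igg <- ct_igg - ct_input - adj
  ddct <- dct_ip - dct_igg
  data.frame(dct_ip = dct_ip, dct_igg = dct_igg, ddct = ddct,
             fold_enrichment = 2^(-ddct))
}
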