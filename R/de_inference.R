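## Differential-expression calling from per-gene posterior summaries:
## Bayesian FDR control by PIP ranking, the Benjamini-Hochberg comparator,
## and evaluation against known truth.

#' Select differentially expressed genes by Bayesian FDR control
#'
#' Genes are ranked by posterior inclusion probability (PIP) in descending
#' order (ties broken by gene id for determinism).  The discovery set is
#' the longest prefix `S_m` of the ranking whose mean posterior
#' false-discovery contribution satisfies `sum(1 - PIP) / m <= alpha_fdr`;
#' an empty set is allowed.
#'
#' @param summaries data.frame with columns `gene_id` and `pip` (e.g. rows
#'   from [posterior_summary()]).
#' @param alpha_fdr target FDR level in (0, 1) (default 0.05).
#' @return object of class `de_result`: the input ranked, with columns
#'   `rank`, `efd` (1 - PIP) and `selected`, plus attributes `m` (number of
#'   discoveries) and `alpha_fdr`.
#' @export
select_de_genes <- function(summaries, alpha_fdr = 0.05) {
  stopifnot(is.data.frame(summaries), all(c("gene_id", "pip") %in% colnames(summaries)),
            alpha_fdr > 0, alpha_fdr < 1,
            all(summaries$pip >= 0), all(summaries$pip <= 1))
  ord <- order(-summaries$pip, summaries$gene_id)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$efd <- 1 - out$pip
  running <- cumsum(out$efd) / seq_len(nrow(out))
  m <- max(c(0L, which(running <= alpha_fdr)))
  out$selected <- out$rank <= m
  rownames(out) <- NULL
  structure(out, m = m, alpha_fdr = alpha_fdr, class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg rejections
#'
#' Standard step-up FDR control for the Gaussian comparator, via
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs treated as 1).
#' @param alpha_fdr target FDR level.
#' @return logical rejection vector aligned with `pvalues`.
#' @export
benjamini_hochberg <- function(pvalues, alpha_fdr = 0.05) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  pvalues[is.na(pvalues)] <- 1
  stats::p.adjust(pvalues, method = "BH") <= alpha_fdr
}

#' Evaluate differential-expression calls against known truth
#'
#' @param calls character vector of called gene ids.
#' @param truth character vector of truly differentially expressed gene
#'   ids.
#' @param all_genes character vector of all tested gene ids (needed for
#'   FPR).
#' @return list with `fdr` (`FP / max(1, FP + TP)`), `tpr` (`NA` when truth
#'   is empty), `fpr`, and the counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_calls <- function(calls, truth, all_genes) {
  stopifnot(all(calls %in% all_genes), all(truth %in% all_genes))
  tp <- length(intersect(calls, truth))
  fp <- length(setdiff(calls, truth))
  fn <- length(setdiff(truth, calls))
  tn <- length(all_genes) - tp - fp - fn
  list(fdr = fp / max(1, fp + tp),
       tpr = if (length(truth) > 0) tp / length(truth) else NA_real_,
       fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Empirical FDR/TPR across a grid of target levels
#'
#' Applies [select_de_genes()] at each target level and evaluates the
#' resulting discovery sets against the truth.  Because the selection rule
#' always takes a prefix of the same PIP ranking, discovery sets are nested
#' and their sizes are monotone nondecreasing in the target level.
#'
#' @param summaries data.frame with `gene_id` and `pip`.
#' @param truth character vector of truly DE gene ids.
#' @param alpha_grid numeric vector of target levels in (0, 1).
#' @return data.frame with columns `alpha`, `n_selected`, `empirical_fdr`,
#'   `tpr`.
#' @export
calibration_curve <- function(summaries, truth,
                              alpha_grid = c(0.05, 0.1, 0.2)) {
  rows <- lapply(alpha_grid, function(a) {
    res <- select_de_genes(summaries, a)
    ev <- evaluate_calls(res$gene_id[res$selected], truth, summaries$gene_id)
    data.frame(alpha = a, n_selected = sum(res$selected),
               empirical_fdr = ev$fdr, tpr = ev$tpr)
  })
  do.call(rbind, rows)
}

#' Write a DE result table
#'
#' @param result a `de_result` (typically with the extra columns carried
#'   over from [posterior_summary()]).
#' @param path output TSV path.
#' @export
write_de_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
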