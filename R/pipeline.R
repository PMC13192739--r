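## Orchestration: prepare -> fit (per gene) -> call -> evaluate.  Each
## gene's chain gets an RNG substream derived from the master seed and a
## hash of the gene id, so results are invariant to processing order and
## resumption.

## Deterministic 31-bit seed from a master seed and a gene id.
gene_seed <- function(master_seed, gene_id) {
  h <- 0
  for (b in utf8ToInt(gene_id)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + master_seed) %% 2147483647)
}

#' Run the ESM pipeline over a set of genes
#'
#' Builds paired data for each gene, applies the eligibility filter, fits
#' the ESM model, and returns posterior summaries together with the
#' FDR-controlled discovery set.  Completed genes found in `outdir` are
#' skipped on rerun (resumability); per-gene failures are recorded and do
#' not stop the run.
#'
#' @param mtx,mgx `stratified_table`s.
#' @param meta a `sample_metadata` data.frame.
#' @param config an [esm_prior_config()]; if its `C` is `NULL`-like the
#'   threshold is computed from the MTX table.
#' @param genes gene ids to process; default: all gene families with taxon
#'   rows in the MTX table.
#' @param groups optional gene x sample matrix of per-gene group variables
#'   (as produced by [build_benchmark()]); overrides `meta$group`.
#' @param alpha_fdr target FDR level for the discovery set.
#' @param seed master seed for per-gene substreams (default 1).
#' @param outdir optional directory for per-gene summary TSVs and the
#'   final results table; `NULL` keeps everything in memory.
#' @param require_nonzero_each_group passed to
#'   [gene_eligibility_filter()].
#' @return list with `summaries` (data.frame, one row per fitted gene),
#'   `result` (a `de_result`), `skipped` (data.frame of ineligible or
#'   failed genes with reasons) and `C`.
#' @export
run_pipeline <- function(mtx, mgx, meta, config, genes = NULL,
                         groups = NULL, alpha_fdr = 0.05, seed = 1,
                         outdir = NULL,
                         require_nonzero_each_group = FALSE) {
  if (is.null(genes)) {
    genes <- unique(mtx$gene_id[mtx$row_kind == "taxon"])
  }
  C <- if (is.null(config$C) || !is.finite(config$C) || config$C <= 0) {
    compute_censor_threshold(mtx)
  } else config$C
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  summaries <- list()
  skipped <- list()
  for (g in genes) {
    cache <- if (!is.null(outdir)) file.path(outdir, paste0(g, "_summary.tsv")) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      summaries[[g]] <- utils::read.delim(cache, stringsAsFactors = FALSE,
                                          check.names = FALSE)
      next
    }
    meta_g <- meta
    if (!is.null(groups)) {
      if (!g %in% rownames(groups)) {
        skipped[[g]] <- "no group assignment"
        next
      }
      meta_g$group <- as.integer(groups[g, match(meta$sample_id, colnames(groups))])
    }
    paired <- pair_and_filter(mtx, mgx, meta_g, g)
    elig <- gene_eligibility_filter(
      paired, require_nonzero_each_group = require_nonzero_each_group)
    if (!elig$eligible) {
      skipped[[g]] <- elig$reason
      next
    }
    cfg <- config
    cfg$C <- C
    cfg$seed <- gene_seed(seed, g)
    sm <- tryCatch({
      fit <- run_gibbs(paired, cfg)
      posterior_summary(fit)
    }, error = function(e) conditionMessage(e))
    if (is.character(sm)) {
      skipped[[g]] <- paste("fit failed:", sm)
      next
    }
    summaries[[g]] <- sm
    if (!is.null(cache)) {
      utils::write.table(sm, cache, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(summaries) == 0) stop("run_pipeline: no gene could be fitted")
  summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  result <- select_de_genes(summaries, alpha_fdr)
  skipped <- if (length(skipped) > 0) {
    data.frame(gene_id = names(skipped), reason = unlist(skipped),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), reason = character(0))
  }
  if (!is.null(outdir)) {
    write_de_result(result, file.path(outdir, "results.tsv"))
    utils::write.table(skipped, file.path(outdir, "skipped.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summaries = summaries, result = result, skipped = skipped, C = C)
}

#' Run the Gaussian comparator over a set of genes
#'
#' Fits [gm_fit()] per gene (semi-strict filtering) and applies
#' Benjamini-Hochberg control to the group-effect p-values.
#'
#' @inheritParams run_pipeline
#' @param pc a [pseudocount_scheme()].
#' @return data.frame with `gene_id`, `estimate`, `p_value`, `rejected`,
#'   `fallback_lm`.
#' @export
run_gm_baseline <- function(mtx, mgx, meta, pc = pseudocount_scheme(),
                            genes = NULL, groups = NULL, alpha_fdr = 0.05) {
  if (is.null(genes)) {
    genes <- unique(mtx$gene_id[mtx$row_kind == "taxon"])
  }
  rows <- lapply(genes, function(g) {
    meta_g <- meta
    if (!is.null(groups)) {
      if (!g %in% rownames(groups)) return(NULL)
      meta_g$group <- as.integer(groups[g, match(meta$sample_id, colnames(groups))])
    }
    paired <- pair_and_filter(mtx, mgx, meta_g, g, filter = "semi_strict")
    if (paired$n_obs == 0) return(NULL)
    fit <- tryCatch(suppressWarnings(gm_fit(paired, pc)), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(gene_id = g, estimate = fit$s_estimate,
               p_value = fit$s_p_value, fallback_lm = fit$fallback_lm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("run_gm_baseline: no gene could be fitted")
  out$rejected <- benjamini_hochberg(out$p_value, alpha_fdr)
  out
}
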