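## Readers, writers and filtering rules for HUMAnN-style stratified
## gene-family abundance tables (rows "GeneFamily|g_Genus.s_Species", an
## aggregate row per gene family, and a "|unclassified" row; columns are
## samples; values are nonnegative CPM).

#' Read a HUMAnN-style stratified abundance table
#'
#' Parses a tab-separated table whose first column holds feature identifiers
#' (any header is accepted; HUMAnN versions vary) and whose remaining
#' columns are samples.  Rows are classified by their identifier: no `"|"`
#' suffix marks the community-level aggregate of a gene family, a suffix of
#' `"g_<Genus>.s_<Species>"` marks a taxon contribution, and `"unclassified"`
#' marks reads without taxonomic assignment.
#'
#' @param path path to a TSV file.
#' @param table_kind label stored with the table, e.g. `"mtx"` or `"mgx"`;
#'   informational only.
#' @return an object of class `stratified_table`: a list with
#'   `feature_id`, `gene_id` (prefix before `"|"`), `suffix` (`NA` for
#'   aggregate rows), `row_kind` (`"aggregate"`, `"taxon"` or
#'   `"unclassified"`), `sample_ids`, and a numeric `values` matrix
#'   (features x samples).
#' @export
read_stratified_table <- function(path, table_kind = "mtx") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 1) stop("read_stratified_table: no columns in ", path)
  feature_id <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (nrow(raw) == 0) {
    values <- matrix(numeric(0), nrow = 0, ncol = length(sample_ids),
                     dimnames = list(NULL, sample_ids))
    return(new_stratified_table(character(0), sample_ids, values, table_kind))
  }
  dup <- duplicated(feature_id)
  if (any(dup)) {
    stop("read_stratified_table: duplicate feature id(s): ",
         paste(utils::head(unique(feature_id[dup]), 3), collapse = ", "))
  }
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  for (k in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[k + 1]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf(
        "read_stratified_table: non-numeric value in row '%s', column '%s'",
        feature_id[bad[1]], sample_ids[k]))
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      stop(sprintf(
        "read_stratified_table: negative value in row '%s', column '%s'",
        feature_id[neg[1]], sample_ids[k]))
    }
    values[, k] <- v
  }
  new_stratified_table(feature_id, sample_ids, values, table_kind)
}

new_stratified_table <- function(feature_id, sample_ids, values, table_kind) {
  ## split on the FIRST "|" only; the full suffix string is kept verbatim and
  ## used for MTX/MGX taxon matching (no taxonomy re-interpretation)
  bar <- regexpr("|", feature_id, fixed = TRUE)
  gene_id <- ifelse(bar > 0, substr(feature_id, 1, bar - 1), feature_id)
  suffix <- ifelse(bar > 0, substring(feature_id, bar + 1), NA_character_)
  row_kind <- ifelse(is.na(suffix), "aggregate",
                     ifelse(suffix == "unclassified", "unclassified", "taxon"))
  dimnames(values) <- list(NULL, sample_ids)
  structure(list(feature_id = feature_id, gene_id = gene_id, suffix = suffix,
                 row_kind = row_kind, sample_ids = sample_ids,
                 values = values, table_kind = table_kind),
            class = "stratified_table")
}

#' @export
print.stratified_table <- function(x, ...) {
  cat(sprintf("stratified_table (%s): %d features (%d gene families), %d samples\n",
              x$table_kind, length(x$feature_id),
              length(unique(x$gene_id)), length(x$sample_ids)))
  invisible(x)
}

#' Write a stratified table to TSV
#'
#' Values are formatted with `%.17g`, which guarantees that
#' `read_stratified_table()` reproduces them bit-identically.
#'
#' @param table a `stratified_table`.
#' @param path output path.
#' @param feature_col header of the first column (default `"# Gene Family"`).
#' @export
write_stratified_table <- function(table, path, feature_col = "# Gene Family") {
  stopifnot(inherits(table, "stratified_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(feature_col, table$sample_ids), collapse = "\t"), con)
  if (length(table$feature_id) > 0) {
    body <- apply(table$values, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(paste(table$feature_id, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Check aggregate rows against their stratified components
#'
#' For every gene family with an aggregate row, computes the per-sample
#' residual `aggregate - (sum of taxon rows + unclassified row)`.  In a
#' well-formed HUMAnN table the aggregate equals that sum up to the rounding
#' of the published values.
#'
#' @param table a `stratified_table`.
#' @param tolerance absolute residual above which a (gene, sample) cell is
#'   flagged (default `1e-3`; published tables round to 5-6 significant
#'   digits).
#' @return data.frame with columns `gene_id`, `sample_id`, `aggregate`,
#'   `component_sum`, `residual`, `flagged`.  Gene families that have taxon
#'   rows but no aggregate row are skipped with a warning.
#' @export
validate_aggregate_consistency <- function(table, tolerance = 1e-3) {
  stopifnot(inherits(table, "stratified_table"))
  agg_genes <- unique(table$gene_id[table$row_kind == "aggregate"])
  strat_genes <- unique(table$gene_id[table$row_kind != "aggregate"])
  if (length(agg_genes) == 0) {
    stop("validate_aggregate_consistency: table contains no aggregate rows")
  }
  orphans <- setdiff(strat_genes, agg_genes)
  if (length(orphans) > 0) {
    warning("gene(s) with taxon rows but no aggregate row skipped: ",
            paste(utils::head(orphans, 3), collapse = ", "))
  }
  out <- lapply(agg_genes, function(g) {
    rows <- table$gene_id == g
    agg <- table$values[rows & table$row_kind == "aggregate", , drop = FALSE]
    comp <- table$values[rows & table$row_kind != "aggregate", , drop = FALSE]
    csum <- if (nrow(comp) > 0) colSums(comp) else rep(0, ncol(agg))
    data.frame(gene_id = g, sample_id = table$sample_ids,
               aggregate = as.numeric(agg[1, ]), component_sum = as.numeric(csum),
               residual = as.numeric(agg[1, ]) - as.numeric(csum),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$flagged <- abs(out$residual) > tolerance
  out
}

#' Global censoring threshold from an MTX table
#'
#' The threshold `C` is the minimum nonzero taxon-level MTX abundance
#' observed across all gene families, interpreted as the minimum detectable
#' abundance in CPM.  It is computed on the raw table, before any gene
#' eligibility filtering (an explicit `C` can be passed to downstream
#' functions to override this choice).
#'
#' @param mtx a `stratified_table` of MTX abundances.
#' @return positive scalar `C`.
#' @export
compute_censor_threshold <- function(mtx) {
  stopifnot(inherits(mtx, "stratified_table"))
  v <- mtx$values[mtx$row_kind == "taxon", , drop = FALSE]
  if (length(v) == 0) v <- mtx$values
  pos <- v[v > 0]
  if (length(pos) == 0) {
    stop("compute_censor_threshold: table has no positive MTX values")
  }
  min(pos)
}

#' Read a per-sample metadata table
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `group`
#'   (binary 0/1, the differential-expression variable, e.g. dysbiosis), and
#'   any number of additional covariate columns.
#' @param covariates character vector naming covariate columns to retain;
#'   default: all remaining columns.
#' @return data.frame of class `sample_metadata`; rows with missing values
#'   in any retained column are dropped (listwise deletion), with a message
#'   giving the count.
#' @export
read_sample_metadata <- function(path, covariates = NULL) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "group")
  missing_cols <- setdiff(required, colnames(meta))
  if (length(missing_cols) > 0) {
    stop("read_sample_metadata: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(colnames(meta), required)
  }
  meta <- meta[, c(required, covariates), drop = FALSE]
  complete <- stats::complete.cases(meta)
  if (any(!complete)) {
    message(sum(!complete), " sample(s) dropped for missing metadata")
    meta <- meta[complete, , drop = FALSE]
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("read_sample_metadata: duplicate sample_id")
  }
  if (!all(meta$group %in% c(0, 1))) {
    stop("read_sample_metadata: group must be binary 0/1")
  }
  attr(meta, "covariates") <- covariates
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Build per-gene paired MTX/MGX observations
#'
#' Extracts the taxon-level rows of one gene family from the MTX and MGX
#' tables, keeps the taxa common to both, matches samples to the metadata,
#' and applies the observation filter.  The default `"mgx_positive"` filter
#' drops every (sample, taxon) pair whose MGX value is zero — this subsumes
#' removal of pairs where both MTX and MGX are zero, and additionally drops
#' apparent RNA expression without detectable gene copies, which is treated
#' as a technical artifact.  The `"semi_strict"` filter (used by the
#' Gaussian comparator) drops only pairs where both values are zero.
#'
#' @param mtx,mgx `stratified_table`s.
#' @param meta a `sample_metadata` data.frame.
#' @param gene_id gene family identifier (prefix before `"|"`).
#' @param filter `"mgx_positive"` (default) or `"semi_strict"`.
#' @return an object of class `paired_gene_data`: observation-level vectors
#'   `y` (MTX), `D` (MGX), `sample` and `taxon` (integer indices re-densified
#'   after filtering), `s`, `X` (observation-level design matrix with
#'   intercept), `subject` (integer index), plus `sample_ids`, `taxon_ids`,
#'   `subject_ids`, `n_samples`, `J` (taxa retained per sample) and
#'   `n_obs`.  If the gene is absent from either table or no observation
#'   survives, a `paired_gene_data` with `n_obs = 0` and a `reason`
#'   attribute is returned.
#' @export
pair_and_filter <- function(mtx, mgx, meta, gene_id,
                            filter = c("mgx_positive", "semi_strict")) {
  filter <- match.arg(filter)
  stopifnot(inherits(mtx, "stratified_table"), inherits(mgx, "stratified_table"))
  empty <- function(reason) {
    structure(list(gene_id = gene_id, y = numeric(0), D = numeric(0),
                   sample = integer(0), taxon = integer(0), s = numeric(0),
                   X = matrix(numeric(0), 0, 0), subject = integer(0),
                   sample_ids = character(0), taxon_ids = character(0),
                   subject_ids = character(0), n_samples = 0L, J = integer(0),
                   n_obs = 0L, filter = filter, reason = reason),
              class = "paired_gene_data")
  }
  rows_mtx <- mtx$gene_id == gene_id & mtx$row_kind == "taxon"
  rows_mgx <- mgx$gene_id == gene_id & mgx$row_kind == "taxon"
  if (!any(rows_mtx) || !any(rows_mgx)) return(empty("gene not paired"))
  taxa <- intersect(mtx$suffix[rows_mtx], mgx$suffix[rows_mgx])
  if (length(taxa) == 0) return(empty("no shared taxa"))
  samples <- intersect(intersect(mtx$sample_ids, mgx$sample_ids),
                       meta$sample_id)
  if (length(samples) == 0) return(empty("no shared samples"))

  ymat <- mtx$values[rows_mtx, samples, drop = FALSE][match(taxa, mtx$suffix[rows_mtx]), , drop = FALSE]
  dmat <- mgx$values[rows_mgx, samples, drop = FALSE][match(taxa, mgx$suffix[rows_mgx]), , drop = FALSE]

  keep <- if (filter == "mgx_positive") dmat > 0 else (ymat > 0 | dmat > 0)
  if (!any(keep)) return(empty("no observations survive filtering"))

  idx <- which(keep, arr.ind = TRUE)   # col 1 = taxon row, col 2 = sample col
  sample_used <- sort(unique(idx[, 2]))
  taxon_used <- sort(unique(idx[, 1]))
  sample_ids <- samples[sample_used]
  taxon_ids <- taxa[taxon_used]
  si <- match(idx[, 2], sample_used)   # re-densified indices
  tj <- match(idx[, 1], taxon_used)

  m <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  covs <- attr(meta, "covariates")
  Xs <- cbind(`(Intercept)` = 1,
              as.matrix(m[, covs, drop = FALSE]))
  storage.mode(Xs) <- "double"
  subject_ids <- unique(m$subject_id)

  ord <- order(si, tj)
  structure(list(
    gene_id = gene_id,
    y = ymat[idx][ord], D = dmat[idx][ord],
    sample = si[ord], taxon = tj[ord],
    s = m$group[si[ord]],
    X = Xs[si[ord], , drop = FALSE],
    subject = match(m$subject_id, subject_ids)[si[ord]],
    sample_ids = sample_ids, taxon_ids = taxon_ids,
    subject_ids = subject_ids,
    n_samples = length(sample_ids),
    J = as.integer(table(factor(si, levels = seq_along(sample_used)))),
    n_obs = length(ord), filter = filter, reason = NA_character_),
    class = "paired_gene_data")
}

#' @export
print.paired_gene_data <- function(x, ...) {
  cat(sprintf("paired_gene_data '%s': %d observations (%d samples, %d taxa, %d subjects); filter=%s\n",
              x$gene_id, x$n_obs, x$n_samples, length(x$taxon_ids),
              length(x$subject_ids), x$filter))
  if (x$n_obs == 0) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Gene eligibility criteria for model fitting
#'
#' A gene is eligible when (i) at least `min_shared_taxa` taxa are shared
#' between its MTX and MGX rows, (ii) after filtering, the group variable
#' and every binary covariate have both categories represented by more than
#' `min_category_n` observations and no binary covariate is identical to the
#' group variable (avoiding perfect collinearity), and optionally (iii) each
#' group level contains at least one nonzero MTX value, so that a log
#' fold-change is well defined.
#'
#' @param paired a `paired_gene_data`.
#' @param min_shared_taxa minimum number of shared taxa (default 2).
#' @param min_category_n minimum observations per category of each binary
#'   variable (default 5, exclusive: categories must have `> 5`).
#' @param require_nonzero_each_group also require a nonzero MTX value in
#'   each group (default `FALSE`).
#' @return list with `eligible` (logical) and `reason` (string, `NA` when
#'   eligible).
#' @export
gene_eligibility_filter <- function(paired, min_shared_taxa = 2,
                                    min_category_n = 5,
                                    require_nonzero_each_group = FALSE) {
  res <- function(ok, reason = NA_character_) list(eligible = ok, reason = reason)
  if (paired$n_obs == 0) return(res(FALSE, paired$reason))
  if (length(paired$taxon_ids) < min_shared_taxa) {
    return(res(FALSE, sprintf("shared_species<%d", min_shared_taxa)))
  }
  binaries <- list(group = paired$s)
  if (ncol(paired$X) > 1) {
    for (k in 2:ncol(paired$X)) {
      xk <- paired$X[, k]
      if (all(xk %in% c(0, 1))) binaries[[colnames(paired$X)[k]]] <- xk
    }
  }
  for (nm in names(binaries)) {
    tab <- table(factor(binaries[[nm]], levels = c(0, 1)))
    if (any(tab <= min_category_n)) {
      return(res(FALSE, sprintf("%s: category with <=%d observations", nm,
                                min_category_n)))
    }
  }
  if (length(binaries) > 1) {
    for (nm in names(binaries)[-1]) {
      b <- binaries[[nm]]
      if (all(b == paired$s) || all(b == 1 - paired$s)) {
        return(res(FALSE, sprintf("%s identical to group (collinear)", nm)))
      }
    }
  }
  if (require_nonzero_each_group) {
    for (lev in c(0, 1)) {
      if (!any(paired$y[paired$s == lev] > 0)) {
        return(res(FALSE, sprintf("no nonzero MTX in group s=%d", lev)))
      }
    }
  }
  res(TRUE)
}
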