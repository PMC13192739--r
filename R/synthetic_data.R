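## Synthetic data generation, two ways:
##  (a) from the ESM generative model itself (parameter recovery, sampler
##      validation), and
##  (b) by signal injection into a backbone abundance table (benchmark
##      replication without external downloads): per gene, samples are split
##      evenly into two groups separately within the zero and nonzero MTX
##      strata, and the MTX values of group s = 1 are multiplied (positive
##      signal) or divided (negative signal) by a signal strength, so the
##      true group coefficient is +/- log(signal).

#' Specification of the ESM generative model
#'
#' Defaults describe a moderately deep study with repeated measures: 300
#' samples from 100 subjects, 3 taxa per sample, MGX abundances spanning
#' several orders of magnitude on the CPM scale, a dominant moderate-
#' precision mixture component and a small-theta component producing excess
#' near-zero abundances that are recorded as censored zeros below `C`.
#'
#' @param n_samples,n_subjects,taxa_per_sample study dimensions.
#' @param alpha MGX (log-DNA) coefficient.
#' @param beta group log fold change (natural log).
#' @param gamma covariate coefficients, first entry the intercept; the
#'   generator supplies one binary and one continuous covariate, so `gamma`
#'   has length 3.
#' @param theta1,theta2,rho inverse-gamma mixture: `U ~ rho IG(theta1+1,
#'   theta1) + (1-rho) IG(theta2+1, theta2)`.
#' @param phi standard deviation of the subject random effects.
#' @param d_meanlog,d_sdlog log-normal law of the MGX values `D`.
#' @param d_zero_prob probability that an MGX value is zero (such
#'   observations are dropped by the MGX-positivity filter, as in real
#'   tables).
#' @param C censoring threshold: generated abundances below `C` are
#'   recorded as zero.
#' @param seed optional integer seed.
#' @return list of class `generative_spec`.
#' @export
generative_spec <- function(n_samples = 300, n_subjects = 100,
                            taxa_per_sample = 3,
                            alpha = 1, beta = log(10),
                            gamma = c(0, 0.5, -0.5),
                            theta1 = 2, theta2 = 0.05, rho = 0.6,
                            phi = 0.5,
                            d_meanlog = 0, d_sdlog = 1.5,
                            d_zero_prob = 0, C = 0.1, seed = NULL) {
  stopifnot(n_subjects <= n_samples, taxa_per_sample >= 1,
            theta1 > 0, theta2 > 0, rho >= 0, rho <= 1, phi >= 0, C > 0,
            d_zero_prob >= 0, d_zero_prob < 1, length(gamma) == 3)
  structure(as.list(environment()), class = "generative_spec")
}

#' Simulate observations from the ESM likelihood at fixed parameters
#'
#' Given a fixed design and parameter values, draws the mixture
#' allocations, auxiliary scales, latent abundances and censored
#' observations exactly as the model specifies: `L` from the mixture
#' weights, `U | L ~ IG(theta_L + 1, theta_L)`, the latent abundance from
#' `Exp(mu U)` (scale parameterization), and `y = 0` where the latent value
#' falls below `C`.
#'
#' @param logD,s,X,subj observation-level design (as in the sampler's model
#'   data): log MGX values, group indicator, design matrix with intercept,
#'   subject index.
#' @param params list with `alpha`, `beta`, `gamma`, `eta`, `theta1`,
#'   `theta2`, `rho`.
#' @param C censoring threshold.
#' @return list with `y` (censored observations), `y_latent` (pre-censoring
#'   abundances), `U`, `L`.
#' @export
esm_simulate_observations <- function(logD, s, X, subj, params, C) {
  nobs <- length(logD)
  L <- 1L + (stats::runif(nobs) >= params$rho)
  th <- c(params$theta1, params$theta2)[L]
  U <- rinvgamma(nobs, shape = th + 1, scale = th)
  lp <- params$alpha * logD + params$beta * s +
    as.numeric(X %*% params$gamma) + params$eta[subj]
  ## clamp to the representable range (relevant only under extreme
  ## parameter draws, e.g. when stress-testing with heavy-tailed priors)
  y_latent <- pmin(pmax(stats::rexp(nobs) * exp(pmin(lp, 690)) * U, 1e-300),
                   1e300)
  y <- ifelse(y_latent < C, 0, y_latent)
  list(y = y, y_latent = y_latent, U = U, L = L)
}

#' Generate one gene from the ESM generative model
#'
#' @param spec a [generative_spec()].
#' @param gene_id identifier stored on the result.
#' @return list with `paired` (a `paired_gene_data` ready for
#'   [run_gibbs()]) and `truth` (the parameter values used, including the
#'   per-subject random effects and per-observation latents).
#' @export
generate_esm_gene <- function(spec, gene_id = "G1") {
  stopifnot(inherits(spec, "generative_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  J <- spec$taxa_per_sample
  subj_of_sample <- sort(rep_len(seq_len(spec$n_subjects), n))
  s_sample <- sample(rep_len(c(0, 1), n))
  x1 <- sample(rep_len(c(0, 1), n))
  x2 <- stats::rnorm(n)
  Xs <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  eta <- stats::rnorm(spec$n_subjects, 0, spec$phi)

  sample_idx <- rep(seq_len(n), each = J)
  taxon_idx <- rep(seq_len(J), times = n)
  D <- stats::rlnorm(n * J, spec$d_meanlog, spec$d_sdlog)
  if (spec$d_zero_prob > 0) {
    D[stats::runif(n * J) < spec$d_zero_prob] <- 0
  }
  keep <- D > 0
  sample_idx <- sample_idx[keep]; taxon_idx <- taxon_idx[keep]; D <- D[keep]

  params <- list(alpha = spec$alpha, beta = spec$beta, gamma = spec$gamma,
                 eta = eta, theta1 = spec$theta1, theta2 = spec$theta2,
                 rho = spec$rho)
  sim <- esm_simulate_observations(log(D), s_sample[sample_idx],
                                   Xs[sample_idx, , drop = FALSE],
                                   subj_of_sample[sample_idx], params, spec$C)
  sample_used <- sort(unique(sample_idx))
  si <- match(sample_idx, sample_used)
  subj_ids <- unique(subj_of_sample[sample_used])
  paired <- structure(list(
    gene_id = gene_id, y = sim$y, D = D,
    sample = si, taxon = taxon_idx,
    s = s_sample[sample_idx],
    X = Xs[sample_idx, , drop = FALSE],
    subject = match(subj_of_sample[sample_idx], subj_ids),
    sample_ids = paste0("S", sample_used),
    taxon_ids = paste0("g_GenusA.s_Taxon_", seq_len(J)),
    subject_ids = paste0("P", subj_ids),
    n_samples = length(sample_used),
    J = as.integer(table(factor(si, levels = seq_along(sample_used)))),
    n_obs = length(sim$y), filter = "mgx_positive", reason = NA_character_),
    class = "paired_gene_data")
  list(paired = paired,
       truth = c(params, list(C = spec$C, U = sim$U, L = sim$L,
                              y_latent = sim$y_latent)))
}

#' Specification of the signal-injection benchmark
#'
#' @param n_genes number of genes (default 100; scaled down from larger
#'   designs so a full benchmark runs on one CPU).
#' @param n_samples number of samples (default 200).
#' @param fraction_de fraction of genes receiving an injected signal
#'   (default 0.40), split evenly between positive (multiplied) and
#'   negative (divided) directions.
#' @param signal multiplicative signal strength (>= 1; default 10, so the
#'   true group coefficient is `log(10)` or `-log(10)`; `signal = 1` makes
#'   every gene effectively null).
#' @param n_subjects,taxa_per_gene backbone dimensions; `n_subjects`
#'   defaults to a quarter of `n_samples` (about four repeated measures
#'   per subject).
#' @param backbone parameters of the generative backbone (a
#'   [generative_spec()] with `beta = 0`); `NULL` for the defaults used by
#'   [build_benchmark()].
#' @param seed integer seed.
#' @return list of class `injection_spec`.
#' @export
injection_spec <- function(n_genes = 100, n_samples = 200,
                           fraction_de = 0.4, signal = 10,
                           n_subjects = NULL, taxa_per_gene = 3,
                           backbone = NULL, seed = 1) {
  stopifnot(fraction_de >= 0, fraction_de <= 1, signal >= 1, n_genes >= 1)
  if (is.null(n_subjects)) n_subjects <- max(1L, n_samples %/% 4L)
  stopifnot(n_subjects <= n_samples)
  structure(as.list(environment()), class = "injection_spec")
}

## Stratified even split of samples into s = 0/1 within the zero and
## nonzero strata of one gene; the extra sample of an odd stratum goes to
## s = 0 (deterministic rule).
split_stratified <- function(zero_stratum) {
  n <- length(zero_stratum)
  s <- integer(n)
  for (lev in c(TRUE, FALSE)) {
    idx <- which(zero_stratum == lev)
    m <- length(idx)
    if (m == 0) next
    n1 <- floor(m / 2)
    pick <- if (n1 > 0) sample(idx, n1) else integer(0)
    s[pick] <- 1L
  }
  s
}

#' Inject multiplicative group signals into an MTX table
#'
#' For each gene a binary group variable is created by splitting samples
#' evenly within the zero and nonzero MTX strata (a sample is in the
#' nonzero stratum when any taxon-level value of the gene is positive);
#' stratifying keeps baseline abundances comparable between groups.  For
#' genes designated positive, taxon-level MTX values of group 1 samples are
#' multiplied by `signal`; for negative genes they are divided.  Zeros are
#' unchanged.  Aggregate and unclassified rows are rescaled consistently.
#'
#' @param mtx a `stratified_table` backbone with at least `spec$n_genes`
#'   gene families.
#' @param spec an [injection_spec()] (its `seed` is NOT applied here; set
#'   the RNG state before calling for reproducibility).
#' @return list with `mtx` (modified table), `groups` (gene x sample 0/1
#'   matrix of the per-gene group variable) and `truth` (data.frame with
#'   `gene_id`, `direction` in {-1, 0, 1}, `true_beta`, `is_de`).
#' @export
inject_signals <- function(mtx, spec) {
  stopifnot(inherits(mtx, "stratified_table"), inherits(spec, "injection_spec"))
  genes <- unique(mtx$gene_id)
  if (length(genes) < spec$n_genes) {
    stop("inject_signals: backbone has fewer genes than spec$n_genes")
  }
  genes <- genes[seq_len(spec$n_genes)]
  n_de <- round(spec$n_genes * spec$fraction_de)
  n_pos <- floor(n_de / 2)
  de_genes <- sample(genes, n_de)
  direction <- stats::setNames(integer(length(genes)), genes)
  direction[de_genes[seq_len(n_pos)]] <- 1L
  if (n_de > n_pos) direction[de_genes[(n_pos + 1):n_de]] <- -1L

  groups <- matrix(0L, nrow = length(genes), ncol = length(mtx$sample_ids),
                   dimnames = list(genes, mtx$sample_ids))
  values <- mtx$values
  for (g in genes) {
    taxon_rows <- which(mtx$gene_id == g & mtx$row_kind == "taxon")
    gene_rows <- which(mtx$gene_id == g)
    nonzero_sample <- colSums(values[taxon_rows, , drop = FALSE] > 0) > 0
    s <- split_stratified(!nonzero_sample)
    groups[g, ] <- s
    if (direction[g] != 0L) {
      fac <- if (direction[g] > 0L) spec$signal else 1 / spec$signal
      cols <- which(s == 1L)
      values[gene_rows, cols] <- values[gene_rows, cols] * fac
    }
  }
  mtx$values <- values
  truth <- data.frame(gene_id = genes, direction = as.integer(direction),
                      true_beta = ifelse(direction == 0, 0,
                                         direction * log(spec$signal)),
                      is_de = direction != 0L,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(mtx = mtx, groups = groups, truth = truth)
}

## Assemble a stratified_table from per-gene taxon matrices.
make_stratified_table <- function(gene_ids, taxon_suffixes, value_list,
                                  sample_ids, table_kind) {
  feats <- character(0)
  rows <- list()
  for (i in seq_along(gene_ids)) {
    v <- value_list[[i]]
    agg <- colSums(v)
    feats <- c(feats, gene_ids[i],
               paste0(gene_ids[i], "|", taxon_suffixes[[i]]),
               paste0(gene_ids[i], "|unclassified"))
    rows[[length(rows) + 1]] <- rbind(agg, v, rep(0, length(sample_ids)))
  }
  values <- do.call(rbind, rows)
  dimnames(values) <- list(NULL, sample_ids)
  new_stratified_table(feats, sample_ids, values, table_kind)
}

#' Build a complete synthetic benchmark bundle
#'
#' Generates a backbone of null genes from the ESM generative model (gene
#' abundances linked to log-normal MGX values, two-component mixture on the
#' auxiliary scale, censored zeros), then injects group signals following
#' the stratified-split design.  The result is fully self-contained: a
#' HUMAnN-format MTX table, the matching MGX table, sample metadata with
#' two covariates and subject identifiers, the per-gene group matrix and
#' the truth labels.
#'
#' @param spec an [injection_spec()].
#' @return list with `mtx`, `mgx` (`stratified_table`s), `meta` (a
#'   `sample_metadata` data.frame), `groups` (gene x sample matrix),
#'   `truth` (data.frame) and `C` (censor threshold of the injected MTX
#'   table).
#' @export
build_benchmark <- function(spec = injection_spec()) {
  stopifnot(inherits(spec, "injection_spec"))
  set.seed(spec$seed)
  bb <- spec$backbone
  if (is.null(bb)) {
    bb <- generative_spec(n_samples = spec$n_samples,
                          n_subjects = spec$n_subjects,
                          taxa_per_sample = spec$taxa_per_gene,
                          alpha = 1, beta = 0, gamma = c(0, 0, 0),
                          theta1 = 1, theta2 = 0.02, rho = 0.35,
                          phi = 0.3, d_meanlog = 1, d_sdlog = 1.5,
                          d_zero_prob = 0.1, C = 0.5)
  }
  n <- bb$n_samples
  J <- bb$taxa_per_sample
  sample_ids <- sprintf("S%03d", seq_len(n))
  subj_of_sample <- sort(rep_len(seq_len(bb$n_subjects), n))
  x_abx <- sample(rep_len(c(0, 1), n))
  x_age <- round(stats::rnorm(n, 30, 10), 1)
  Xs <- cbind(`(Intercept)` = 1, abx = x_abx,
              age = as.numeric(scale(x_age)))

  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  taxon_suffixes <- replicate(spec$n_genes,
                              paste0("g_GenusA.s_Taxon_", seq_len(J)),
                              simplify = FALSE)
  mtx_vals <- vector("list", spec$n_genes)
  mgx_vals <- vector("list", spec$n_genes)
  for (gi in seq_len(spec$n_genes)) {
    eta <- stats::rnorm(bb$n_subjects, 0, bb$phi)
    D <- matrix(stats::rlnorm(J * n, bb$d_meanlog, bb$d_sdlog), nrow = J)
    if (bb$d_zero_prob > 0) {
      D[matrix(stats::runif(J * n) < bb$d_zero_prob, nrow = J)] <- 0
    }
    y <- matrix(0, nrow = J, ncol = n)
    pos <- which(D > 0)
    if (length(pos) > 0) {
      col_of <- ((pos - 1) %/% J) + 1
      params <- list(alpha = bb$alpha, beta = 0, gamma = bb$gamma,
                     eta = eta, theta1 = bb$theta1, theta2 = bb$theta2,
                     rho = bb$rho)
      sim <- esm_simulate_observations(log(D[pos]), rep(0, length(pos)),
                                       Xs[col_of, , drop = FALSE],
                                       subj_of_sample[col_of], params, bb$C)
      y[pos] <- sim$y
    }
    mtx_vals[[gi]] <- y
    mgx_vals[[gi]] <- D
  }
  mtx <- make_stratified_table(gene_ids, taxon_suffixes, mtx_vals,
                               sample_ids, "mtx")
  mgx <- make_stratified_table(gene_ids, taxon_suffixes, mgx_vals,
                               sample_ids, "mgx")
  inj <- inject_signals(mtx, spec)

  meta <- data.frame(sample_id = sample_ids,
                     subject_id = sprintf("P%03d", subj_of_sample),
                     group = 0L, abx = x_abx, age = as.numeric(scale(x_age)),
                     stringsAsFactors = FALSE)
  attr(meta, "covariates") <- c("abx", "age")
  class(meta) <- c("sample_metadata", "data.frame")

  list(mtx = inj$mtx, mgx = mgx, meta = meta, groups = inj$groups,
       truth = inj$truth, C = compute_censor_threshold(inj$mtx))
}

#' Write a benchmark bundle to disk
#'
#' Emits `mtx.tsv`, `mgx.tsv`, `metadata.tsv`, `groups.tsv` and
#' `truth.tsv` under `dir` in the plain-text formats read back by the I/O
#' layer.
#'
#' @param bundle result of [build_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stratified_table(bundle$mtx, file.path(dir, "mtx.tsv"))
  write_stratified_table(bundle$mgx, file.path(dir, "mgx.tsv"))
  utils::write.table(bundle$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gtab <- data.frame(gene_id = rownames(bundle$groups), bundle$groups,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gtab, file.path(dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
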