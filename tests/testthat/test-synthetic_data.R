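test_that("generative draws reproduce the model's censoring probability", {
  ## constant mu = 1: expected zero fraction has a closed form through the
  ## Lomax cdf at the threshold
  spec <- generative_spec(n_samples = 4000, n_subjects = 4000,
                          taxa_per_sample = 1, alpha = 0, beta = 0,
                          gamma = c(0, 0, 0), phi = 0,
                          theta1 = 2, theta2 = 0.05, rho = 0.6,
                          C = 0.3, seed = 91)
  g <- generate_esm_gene(spec)
  p0 <- spec$rho * plomax(spec$C, spec$theta1 + 1, spec$theta1) +
    (1 - spec$rho) * plomax(spec$C, spec$theta2 + 1, spec$theta2)
  zf <- mean(g$paired$y == 0)
  expect_equal(zf, p0, tolerance = 4 * sqrt(p0 * (1 - p0) / 4000) + 0.005)

  ## component-1 pre-censoring draws have mean mu (theta = 5 regime)
  spec2 <- generative_spec(n_samples = 20000, n_subjects = 20000,
                           taxa_per_sample = 1, alpha = 0, beta = 0,
                           gamma = c(0, 0, 0), phi = 0,
                           theta1 = 5, theta2 = 5, rho = 1,
                           C = 1e-6, seed = 92)
  g2 <- generate_esm_gene(spec2)
  y1 <- g2$truth$y_latent[g2$truth$L == 1L]
  expect_lt(abs(mean(y1) - 1), 3 * sd(y1) / sqrt(length(y1)))
})

test_that("a null group effect leaves the group means balanced", {
  spec <- generative_spec(n_samples = 3000, n_subjects = 1000,
                          taxa_per_sample = 2, beta = 0, phi = 0.2,
                          theta1 = 2, theta2 = 2, rho = 1, seed = 93)
  g <- generate_esm_gene(spec)
  ## compare group means of y/mu-free statistic: log(y/D^alpha) on nonzeros
  r <- log(g$paired$y / g$paired$D^spec$alpha)
  nz <- g$paired$y > 0
  m0 <- mean(r[nz & g$paired$s == 0]); m1 <- mean(r[nz & g$paired$s == 1])
  se <- sqrt(var(r[nz]) * (1 / sum(nz & g$paired$s == 0) +
                             1 / sum(nz & g$paired$s == 1)))
  expect_lt(abs(m1 - m0), 4 * se)
})

test_that("generated genes respect the MGX-positivity contract", {
  spec <- generative_spec(n_samples = 200, n_subjects = 50,
                          d_zero_prob = 0.3, seed = 94)
  g <- generate_esm_gene(spec)
  expect_true(all(g$paired$D > 0))
  expect_lt(g$paired$n_obs, spec$n_samples * spec$taxa_per_sample)
  expect_equal(length(g$paired$J), g$paired$n_samples)
  expect_true(all(g$paired$J >= 1))
})

test_that("signal injection splits strata evenly and scales only group 1", {
  set.seed(95)
  b0 <- build_benchmark(injection_spec(n_genes = 20, n_samples = 60,
                                       n_subjects = 20, signal = 10,
                                       seed = 96))
  expect_equal(sum(b0$truth$is_de), 8)           # 40% of 20
  expect_equal(sum(b0$truth$direction == 1), 4)  # half positive
  expect_equal(sum(b0$truth$direction == -1), 4)

  for (g in b0$truth$gene_id) {
    s <- b0$groups[g, ]
    taxon_rows <- b0$mtx$gene_id == g & b0$mtx$row_kind == "taxon"
    v <- b0$mtx$values[taxon_rows, , drop = FALSE]
    dirn <- b0$truth$direction[b0$truth$gene_id == g]
    ## undo the injection to recover the backbone stratum labels
    v0 <- v
    if (dirn != 0) {
      v0[, s == 1] <- v[, s == 1] / ifelse(dirn > 0, 10, 1 / 10)
    }
    zero_sample <- colSums(v0 > 0) == 0
    for (stratum in list(which(zero_sample), which(!zero_sample))) {
      if (length(stratum) == 0) next
      expect_lte(abs(sum(s[stratum] == 1) - sum(s[stratum] == 0)), 1)
    }
    ## zeros remain zeros; nonzero ratio equals the signal
    expect_true(all((v == 0) == (v0 == 0)))
    if (dirn != 0) {
      ratio <- v[v0 > 0 & col(v) %in% which(s == 1)] /
        v0[v0 > 0 & col(v) %in% which(s == 1)]
      expect_equal(unique(round(ratio, 10)),
                   ifelse(dirn > 0, 10, 0.1))
    }
  }
})

test_that("signal = 1 leaves the backbone unchanged", {
  set.seed(97)
  spec <- injection_spec(n_genes = 10, n_samples = 40, n_subjects = 10,
                         signal = 1, seed = 98)
  b <- build_benchmark(spec)
  expect_true(all(b$truth$true_beta == 0))
  ## rebuild the backbone with the same seed but no DE genes
  spec0 <- injection_spec(n_genes = 10, n_samples = 40, n_subjects = 10,
                          signal = 10, fraction_de = 0, seed = 98)
  b0 <- build_benchmark(spec0)
  expect_identical(b$mtx$values, b0$mtx$values)
})

test_that("benchmark bundles are reproducible and round-trip through the I/O layer", {
  spec <- injection_spec(n_genes = 6, n_samples = 30, n_subjects = 10,
                         seed = 99)
  b1 <- build_benchmark(spec)
  b2 <- build_benchmark(spec)
  expect_identical(b1$mtx$values, b2$mtx$values)
  expect_identical(b1$groups, b2$groups)
  expect_identical(b1$truth, b2$truth)

  d <- withr::local_tempdir()
  write_benchmark(b1, d)
  spec_again <- injection_spec(n_genes = 6, n_samples = 30, n_subjects = 10,
                               seed = 99)
  d2 <- withr::local_tempdir()
  write_benchmark(build_benchmark(spec_again), d2)
  for (f in c("mtx.tsv", "mgx.tsv", "metadata.tsv", "groups.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))
  }

  mtx <- read_stratified_table(file.path(d, "mtx.tsv"), "mtx")
  mgx <- read_stratified_table(file.path(d, "mgx.tsv"), "mgx")
  expect_identical(mtx$values[mtx$row_kind == "taxon", ],
                   b1$mtx$values[b1$mtx$row_kind == "taxon", ])
  ## written tables keep aggregate rows consistent
  rep <- validate_aggregate_consistency(mtx)
  expect_false(any(rep$flagged))
  rep2 <- validate_aggregate_consistency(mgx)
  expect_false(any(rep2$flagged))
  ## paired data built from the files matches the in-memory bundle
  meta <- read_sample_metadata(file.path(d, "metadata.tsv"))
  p <- pair_and_filter(mtx, mgx, meta, "G0001")
  expect_gt(p$n_obs, 0)
  expect_true(all(p$D > 0))
})

test_that("injected truth is recoverable from the table itself", {
  set.seed(101)
  b <- build_benchmark(injection_spec(n_genes = 12, n_samples = 100,
                                      n_subjects = 25, seed = 102))
  ## for positive-signal genes the nonzero-mean ratio between groups is
  ## approximately the signal strength (up to sampling noise)
  pos <- b$truth$gene_id[b$truth$direction == 1]
  ratios <- vapply(pos, function(g) {
    s <- b$groups[g, ]
    v <- b$mtx$values[b$mtx$gene_id == g & b$mtx$row_kind == "taxon", ,
                      drop = FALSE]
    v1 <- v[, s == 1, drop = FALSE]; v0 <- v[, s == 0, drop = FALSE]
    mean(v1[v1 > 0]) / mean(v0[v0 > 0])
  }, numeric(1))
  expect_true(all(ratios > 3))
  expect_gt(median(ratios), 5)
})
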