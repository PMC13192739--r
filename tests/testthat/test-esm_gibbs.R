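test_that("prior configuration validates its inputs", {
  cfg <- esm_prior_config(C = 0.5)
  expect_equal(cfg$pi, 0.5)
  expect_equal(cfg$psi, 10)
  expect_equal(cfg$xi, 10)
  expect_error(esm_prior_config(C = -1))
  expect_error(esm_prior_config(C = 1, n_iter = 100, n_burn = 200))
  expect_error(esm_prior_config(C = 1, pi = 1))
})

test_that("censored latents follow a truncated exponential", {
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg <- esm_prior_config(C = 0.8, n_iter = 10, n_burn = 5, seed = 1)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data

  ## fix mu U for the first censored observation and collect repeated draws
  cz <- which(data$censored)
  lam <- exp(st$lp[cz[1]]) * st$U[cz[1]]
  set.seed(42)
  draws <- replicate(4000, esm_update_ytilde(st, data, cfg)$ydot[cz[1]])
  expect_true(all(draws >= 0 & draws < cfg$C))
  ks <- suppressWarnings(stats::ks.test(
    draws, function(q) stats::pexp(q, 1 / lam) / stats::pexp(cfg$C, 1 / lam)))
  expect_gt(ks$p.value, 0.01)

  ## huge scale relative to C: approximately uniform on [0, C)
  st2 <- st; st2$U[] <- 1e9
  set.seed(43)
  u <- replicate(3000, esm_update_ytilde(st2, data, cfg)$ydot[cz[1]])
  ks2 <- suppressWarnings(stats::ks.test(u, "punif", 0, cfg$C))
  expect_gt(ks2$p.value, 0.01)
})

test_that("slice variables satisfy their constraint by construction", {
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg <- esm_prior_config(C = 0.8, n_iter = 10, n_burn = 5, seed = 2)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  st <- esm_update_e(st, data)
  lb <- log(st$ydot) - st$lp - log(st$U)
  expect_true(all(st$loge > lb))
  ## excess over the bound is Exp(1)
  set.seed(44)
  exc <- replicate(3000, {
    s2 <- esm_update_e(st, data)
    exp(s2$loge[3]) - exp(lb[3])
  })
  ks <- suppressWarnings(stats::ks.test(exc, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("coefficient truncation bounds implement the max/min formulas", {
  d <- tiny_design()
  y <- c(0.5, 1, 2, 0.4, 3, 0.2, 1, 0.6, 2, 4)   # no zeros: ydot = y
  cfg <- esm_prior_config(C = 0.1, n_iter = 10, n_burn = 5, seed = 3)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  st <- esm_update_e(st, data)

  ## independent evaluation of the bound formulas from raw state vectors
  cvec <- log(st$ydot) - st$loge - log(st$U)
  for (which in c("alpha", "beta")) {
    z <- if (which == "alpha") data$logD else data$s
    coef <- if (which == "alpha") st$alpha else st$beta
    r <- cvec - (st$lp - coef * z)
    lo <- suppressWarnings(max(r[z > 0] / z[z > 0]))
    hi <- if (any(z < 0)) min(r[z < 0] / z[z < 0]) else Inf
    b <- esm_coefficient_bounds(st, data, which)
    expect_equal(b[1], lo)
    expect_equal(b[2], hi)
  }
  ## binary s never yields a finite upper bound
  expect_equal(esm_coefficient_bounds(st, data, "beta")[2], Inf)
  ## intercept and random effects: z = 1, upper bound is +Inf
  expect_equal(esm_coefficient_bounds(st, data, "gamma", 1)[2], Inf)
  expect_equal(esm_coefficient_bounds(st, data, "eta", 1)[2], Inf)
  ## eta bounds use only the subject's own observations
  r_eta <- cvec - (st$lp - st$eta[data$subj])
  expect_equal(esm_coefficient_bounds(st, data, "eta", 2)[1],
               max(r_eta[data$subj == 2]))
})

test_that("mixture allocation matches the density-ratio oracle", {
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg <- esm_prior_config(C = 0.8, n_iter = 10, n_burn = 5, seed = 4)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  st$theta1 <- 1.4; st$theta2 <- 0.12; st$rho <- 0.35

  ## E[1(L=1)] must equal E[p1(U)] with p1 computed independently from the
  ## two inverse-gamma densities
  set.seed(45)
  ind <- matrix(NA_real_, 2000, data$nobs)
  prb <- matrix(NA_real_, 2000, data$nobs)
  dig <- function(u, th) th^(th + 1) / gamma(th + 1) * u^(-th - 2) * exp(-th / u)
  for (i in seq_len(2000)) {
    s2 <- esm_update_U_L(st, data, cfg)
    ind[i, ] <- s2$L == 1L
    w1 <- st$rho * dig(s2$U, st$theta1)
    w2 <- (1 - st$rho) * dig(s2$U, st$theta2)
    prb[i, ] <- w1 / (w1 + w2)
  }
  diff <- colMeans(ind) - colMeans(prb)
  se <- sqrt(apply(prb * (1 - prb), 2, mean) / 2000 +
               apply(prb, 2, var) / 2000)
  expect_true(all(abs(diff) < 4 * pmax(se, 1e-4)))

  ## theta1 = theta2: allocation probability is exactly rho
  st$theta1 <- st$theta2 <- 0.9
  set.seed(46)
  l1 <- replicate(3000, mean(esm_update_U_L(st, data, cfg)$L == 1L))
  expect_equal(mean(l1), st$rho, tolerance = 3 * sd(l1) / sqrt(3000) + 0.01)
})

test_that("auxiliary scale U follows its conjugate inverse-gamma update", {
  d <- tiny_design()
  y <- c(0.5, 1, 2, 0.4, 3, 0.2, 1, 0.6, 2, 4)
  cfg <- esm_prior_config(C = 0.1, n_iter = 10, n_burn = 5, seed = 5)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  st$L[] <- 1L; st$theta1 <- 1.0
  sh <- st$theta1 + 2
  sc <- st$ydot[1] * exp(-st$lp[1]) + st$theta1
  set.seed(47)
  u <- replicate(4000, esm_update_U_L(st, data, cfg)$U[1])
  ks <- suppressWarnings(stats::ks.test(
    u, function(q) stats::pgamma(1 / q, sh, rate = sc, lower.tail = FALSE)))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixture weight follows Beta(n1 + 1, n2 + 1)", {
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg <- esm_prior_config(C = 0.8, n_iter = 10, n_burn = 5, seed = 6)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state
  st$L <- rep(c(1L, 2L), c(7, 3))
  set.seed(48)
  r <- replicate(4000, esm_update_rho(st)$rho)
  ks <- suppressWarnings(stats::ks.test(r, "pbeta", 8, 4))
  expect_gt(ks$p.value, 0.01)
  ## counts conserved
  expect_equal(sum(st$L == 1L) + sum(st$L == 2L), length(st$L))
})

test_that("spike-and-slab inclusion probability matches brute-force integration", {
  d <- tiny_design()
  y <- c(0.5, 1, 2, 0.4, 3, 0.2, 1, 0.6, 2, 4)
  cfg <- esm_prior_config(C = 0.1, n_iter = 10, n_burn = 5, seed = 7)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  st$tau2 <- 0.5
  st <- esm_update_e(st, data)

  ## brute force over a beta grid: the likelihood factor in beta is
  ## exp(-beta * sum s) times the indicator that all slice constraints hold
  grid <- seq(-6, 6, length.out = 60001)
  h <- vapply(grid, function(b) {
    lp_b <- st$lp + (b - st$beta) * data$s
    ok <- all(st$loge > log(st$ydot) - lp_b - log(st$U))
    if (ok) exp(-b * data$sum_s + stats::dnorm(b, 0, sqrt(st$tau2), log = TRUE))
    else 0
  }, numeric(1))
  int1 <- sum(h) * (grid[2] - grid[1])
  lp_0 <- st$lp - st$beta * data$s
  h0 <- as.numeric(all(st$loge > log(st$ydot) - lp_0 - log(st$U)))
  p1_oracle <- cfg$pi * int1 / ((1 - cfg$pi) * h0 + cfg$pi * int1)

  set.seed(49)
  z <- replicate(4000, esm_update_beta_zeta(st, data, cfg)$zeta)
  se <- sqrt(p1_oracle * (1 - p1_oracle) / 4000)
  expect_equal(mean(z), p1_oracle, tolerance = 4 * se + 0.005)

  ## unbounded symmetric case: probability exactly pi when sum(s) = 0
  st2 <- st
  data2 <- data; data2$s <- rep(0, data$nobs); data2$sum_s <- 0
  set.seed(50)
  z2 <- replicate(3000, esm_update_beta_zeta(st2, data2, cfg)$zeta)
  expect_equal(mean(z2), cfg$pi, tolerance = 0.035)
})

test_that("zeta and beta are coupled: zeta = 0 if and only if beta = 0", {
  spec <- generative_spec(n_samples = 40, n_subjects = 15,
                          taxa_per_sample = 2, seed = 8)
  g <- generate_esm_gene(spec)
  cfg <- esm_prior_config(C = spec$C, n_iter = 120, n_burn = 0, thin = 1,
                          seed = 9)
  fit <- run_gibbs(g$paired, cfg)
  zt <- fit$draws[, "zeta"]; bt <- fit$draws[, "beta"]
  expect_true(all((zt == 0) == (bt == 0)))
})

test_that("variance full conditionals follow their inverse-gamma laws", {
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg <- esm_prior_config(C = 0.8, psi = 2, n_iter = 10, n_burn = 5, seed = 10)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  st$alpha <- 0.7; st$b_sigma2 <- 1.3; st$zeta <- 0L; st$beta <- 0
  set.seed(51)
  draws <- replicate(4000, {
    s2 <- esm_update_variances(st, data, cfg)
    c(s2$sigma2, s2$tau2, s2$phi2)
  })
  ## sigma2 ~ IG(1, alpha^2/2 + 1/b_sigma2)
  sc <- st$alpha^2 / 2 + 1 / st$b_sigma2
  ks <- suppressWarnings(stats::ks.test(
    draws[1, ], function(q) stats::pgamma(1 / q, 1, rate = sc,
                                          lower.tail = FALSE)))
  expect_gt(ks$p.value, 0.01)
  ## zeta = 0: tau2 is drawn from its conditional prior IG(1/2, 1/b_tau2)
  ks2 <- suppressWarnings(stats::ks.test(
    draws[2, ], function(q) stats::pgamma(1 / q, 1 / 2, rate = 1 / st$b_tau2,
                                          lower.tail = FALSE)))
  expect_gt(ks2$p.value, 0.01)
  ## phi2 ~ IG(R/2 + 1/2, sum(eta^2)/2 + 1/b_phi2)
  scp <- sum(st$eta^2) / 2 + 1 / st$b_phi2
  ks3 <- suppressWarnings(stats::ks.test(
    draws[3, ], function(q) stats::pgamma(1 / q, data$R / 2 + 1 / 2,
                                          rate = scp, lower.tail = FALSE)))
  expect_gt(ks3$p.value, 0.01)

  ## the two-level inverse-gamma hierarchy marginalizes to half-Cauchy(psi)
  set.seed(52)
  b <- 1 / rgamma(4e4, 1 / 2, rate = 1 / cfg$psi^2)
  tau <- sqrt(1 / rgamma(4e4, 1 / 2, rate = 1 / b))
  ks4 <- suppressWarnings(stats::ks.test(
    tau, function(q) 2 / pi * atan(q / cfg$psi)))
  expect_gt(ks4$p.value, 0.01)
})

test_that("Metropolis update of theta targets the grid-normalized posterior", {
  ## fixed allocation of U values; oracle density computed from scratch
  set.seed(53)
  U <- rinvgamma(40, 1.6, 1.1)
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg <- esm_prior_config(C = 0.8, xi = 1, n_iter = 10, n_burn = 5, seed = 54,
                          mh_step = 0.5)
  cs <- consistent_state(tiny_paired(y, d), cfg)
  st <- cs$state; data <- cs$data
  ## component 1 carries the fixed U set; component 2 left empty so its
  ## chain explores the prior
  data$nobs <- length(U)
  st$U <- U; st$L <- rep(1L, length(U))

  th_grid <- seq(1e-4, 12, length.out = 24000)
  logpost <- vapply(th_grid, function(th) {
    sum(th * log(th) + log(th) - lgamma(th + 1) - (th + 2) * log(U) - th / U) -
      cfg$xi * th
  }, numeric(1))
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  cdf <- cumsum(w)

  chain <- numeric(12000)
  cur <- st
  for (i in seq_along(chain)) {
    cur <- esm_update_theta(cur, data, cfg)
    chain[i] <- cur$theta1
  }
  chain <- chain[2001:length(chain)]
  for (q in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    oracle_q <- th_grid[which.max(cdf >= q)]
    expect_equal(unname(stats::quantile(chain, q)), oracle_q,
                 tolerance = 0.05 * oracle_q + 0.02)
  }
  ## empty component: chain explores the Exp(xi) prior
  th2 <- numeric(20000)
  cur <- st
  for (i in seq_along(th2)) {
    cur <- esm_update_theta(cur, data, cfg)
    th2[i] <- cur$theta2
  }
  expect_equal(mean(th2[4001:20000]), 1 / cfg$xi, tolerance = 0.12)
})

test_that("theta acceptance rate lands in a healthy band after adaptation", {
  spec <- generative_spec(n_samples = 80, n_subjects = 30, seed = 12)
  g <- generate_esm_gene(spec)
  cfg <- esm_prior_config(C = spec$C, n_iter = 1200, n_burn = 600, seed = 13)
  fit <- run_gibbs(g$paired, cfg)
  expect_true(all(fit$accept_theta >= 0.1 & fit$accept_theta <= 0.65))
})

test_that("slice constraints hold after every sweep and chains are reproducible", {
  spec <- generative_spec(n_samples = 30, n_subjects = 10,
                          taxa_per_sample = 2, seed = 14)
  g <- generate_esm_gene(spec)
  cfg <- esm_prior_config(C = spec$C, n_iter = 10, n_burn = 5, seed = 15)
  data <- esmtx:::esm_model_data(g$paired, cfg)
  set.seed(cfg$seed)
  st <- esmtx:::esm_init_state(data, cfg)
  for (i in 1:40) {
    st <- esm_gibbs_sweep(st, data, cfg)
    expect_true(all(st$loge > log(st$ydot) - st$lp - log(st$U)))
    expect_true(all(st$ydot[data$censored] < cfg$C))
    expect_true(all(st$ydot[!data$censored] == data$y[!data$censored]))
    expect_true(all(st$U > 0) && st$rho > 0 && st$rho < 1 &&
                  st$theta1 > 0 && st$theta2 > 0)
  }

  cfg2 <- esm_prior_config(C = spec$C, n_iter = 200, n_burn = 100, seed = 77)
  f1 <- run_gibbs(g$paired, cfg2)
  f2 <- run_gibbs(g$paired, cfg2)
  expect_identical(f1$draws, f2$draws)
})

test_that("a constant group variable leaves inclusion near the prior", {
  spec <- generative_spec(n_samples = 60, n_subjects = 20, beta = 0, seed = 16)
  g <- generate_esm_gene(spec)
  g$paired$s[] <- 0   # no variation in the group variable
  cfg <- esm_prior_config(C = spec$C, n_iter = 1500, n_burn = 500, seed = 17)
  fit <- run_gibbs(g$paired, cfg)
  expect_lt(abs(fit$pip - cfg$pi), 0.12)
})

test_that("raising the censoring threshold never lowers censored latent means", {
  d <- tiny_design()
  y <- c(0, 1, 2, 0, 3, 0, 1, 0, 2, 4)
  cfg_lo <- esm_prior_config(C = 0.4, n_iter = 10, n_burn = 5, seed = 18)
  cfg_hi <- esm_prior_config(C = 1.6, n_iter = 10, n_burn = 5, seed = 18)
  cs <- consistent_state(tiny_paired(y, d), cfg_lo)
  st <- cs$state; data <- cs$data
  cz <- which(data$censored)
  set.seed(60)
  m_lo <- rowMeans(replicate(3000, esm_update_ytilde(st, data, cfg_lo)$ydot[cz]))
  set.seed(60)
  m_hi <- rowMeans(replicate(3000, esm_update_ytilde(st, data, cfg_hi)$ydot[cz]))
  expect_true(all(m_hi >= m_lo))
})

test_that("an all-censored gene is flagged uninformative", {
  d <- tiny_design()
  y <- rep(0, 10)
  cfg <- esm_prior_config(C = 0.5, n_iter = 60, n_burn = 30, seed = 19)
  expect_warning(fit <- run_gibbs(tiny_paired(y, d), cfg), "censored")
  expect_true(fit$uninformative)
  expect_true(is.finite(fit$pip))
})

test_that("posterior summaries expose conditional and unconditional effects", {
  spec <- generative_spec(n_samples = 60, n_subjects = 20, seed = 20)
  g <- generate_esm_gene(spec)
  cfg <- esm_prior_config(C = spec$C, n_iter = 400, n_burn = 200, seed = 21)
  fit <- run_gibbs(g$paired, cfg)
  sm <- posterior_summary(fit)
  expect_true(sm$pip >= 0 && sm$pip <= 1)
  if (!is.na(sm$beta_mean)) {
    expect_true(sm$beta_ci_low <= sm$beta_mean &&
                  sm$beta_mean <= sm$beta_ci_high)
  }
  expect_named(sm, c("gene_id", "pip", "beta_mean", "beta_ci_low",
                     "beta_ci_high", "beta_mean_all", "beta_sd_all",
                     "alpha_mean", "theta1_mean", "theta2_mean", "rho_mean",
                     "n_obs", "n_censored", "uninformative",
                     "gamma.(Intercept)_mean", "gamma.x1_mean",
                     "gamma.x2_mean"))
})
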