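## Shared builders for the test suite.  Everything is generated in code;
## the only file fixture is the small stratified-table example under
## inst/extdata.

example_mtx_path <- function() {
  system.file("extdata", "example_mtx.tsv", package = "esmtx")
}

## A small fixed design: n samples x J taxa, two subjects, intercept + one
## covariate, mixed-sign log D so both truncation bounds are exercised.
tiny_design <- function() {
  n <- 5; J <- 2
  s_sample <- c(0, 0, 1, 1, 1)
  subj_sample <- c(1, 1, 1, 2, 2)
  x1 <- c(-1, 0.5, 1, -0.5, 0)
  logD <- c(0.3, -0.8, 1.2, -0.2, 0.5, -1.1, 0.9, 0.1, -0.6, 0.7)
  sample_idx <- rep(seq_len(n), each = J)
  list(n = n, J = J, R = 2, K = 2,
       sample_idx = sample_idx,
       X = cbind(`(Intercept)` = 1, x1 = x1)[sample_idx, ],
       s = s_sample[sample_idx],
       subj = subj_sample[sample_idx],
       logD = logD)
}

## Wrap observation-level vectors into a paired_gene_data object.
make_paired <- function(y, D, s, X, subject, sample_idx, taxon_idx = NULL,
                        gene_id = "Gtest") {
  if (is.null(taxon_idx)) taxon_idx <- seq_along(y) - min(seq_along(y)) + 1L
  su <- sort(unique(sample_idx))
  structure(list(
    gene_id = gene_id, y = y, D = D,
    sample = match(sample_idx, su), taxon = taxon_idx,
    s = s, X = X, subject = subject,
    sample_ids = paste0("S", su),
    taxon_ids = paste0("t", sort(unique(taxon_idx))),
    subject_ids = paste0("P", sort(unique(subject))),
    n_samples = length(su),
    J = as.integer(table(factor(sample_idx, levels = su))),
    n_obs = length(y), filter = "mgx_positive", reason = NA_character_),
    class = "paired_gene_data")
}

tiny_paired <- function(y, d) {
  make_paired(y, exp(d$logD), d$s, d$X, d$subj, d$sample_idx,
              rep(seq_len(d$J), d$n))
}

## Draw the full parameter block from the model's prior.
prior_param_draw <- function(cfg, K, R) {
  draw_var <- function() {
    b <- 1 / rgamma(1, 1 / 2, rate = 1 / cfg$psi^2)
    v <- 1 / rgamma(1, 1 / 2, rate = 1 / b)
    c(v, b)
  }
  sv <- draw_var(); tv <- draw_var(); pv <- draw_var()
  vv <- replicate(K, draw_var())
  zeta <- rbinom(1, 1, cfg$pi)
  list(sigma2 = sv[1], b_sigma2 = sv[2], tau2 = tv[1], b_tau2 = tv[2],
       phi2 = pv[1], b_phi2 = pv[2], v2 = vv[1, ], b_v2 = vv[2, ],
       zeta = zeta, beta = if (zeta) rnorm(1, 0, sqrt(tv[1])) else 0,
       alpha = rnorm(1, 0, sqrt(sv[1])),
       gamma = rnorm(K, 0, sqrt(vv[1, ])),
       eta = rnorm(R, 0, sqrt(pv[1])),
       rho = runif(1),
       theta1 = rexp(1, cfg$xi), theta2 = rexp(1, cfg$xi))
}

## One successive-conditional step: redraw data and latents from the model
## at the current parameters, then apply one full Gibbs sweep.
successive_conditional_step <- function(p, d, cfg) {
  sim <- esm_simulate_observations(
    d$logD, d$s, d$X, d$subj,
    list(alpha = p$alpha, beta = p$beta, gamma = p$gamma, eta = p$eta,
         theta1 = p$theta1, theta2 = p$theta2, rho = p$rho), cfg$C)
  paired <- make_paired(sim$y, exp(d$logD), d$s, d$X, d$subj, d$sample_idx,
                        rep(seq_len(d$J), d$n))
  data <- esmtx:::esm_model_data(paired, cfg)
  st <- esmtx:::esm_init_state(data, cfg, init = "null")
  st[names(p)] <- p
  st$U <- sim$U; st$L <- sim$L
  st$ydot <- ifelse(data$censored, sim$y_latent, sim$y)
  st$lp <- esmtx:::esm_linpred(st, data)
  st$loge <- esmtx:::esm_slice_log_draw(
    log(st$ydot) - st$lp - log(st$U), rexp(data$nobs))
  st <- esm_gibbs_sweep(st, data, cfg)
  st[c("sigma2", "b_sigma2", "tau2", "b_tau2", "phi2", "b_phi2", "v2",
       "b_v2", "zeta", "beta", "alpha", "gamma", "eta", "rho",
       "theta1", "theta2")]
}

## A consistent sampler state for a given paired data set and parameter
## block (latents drawn from the model conditionals).
consistent_state <- function(paired, cfg, p = NULL) {
  data <- esmtx:::esm_model_data(paired, cfg)
  st <- esmtx:::esm_init_state(data, cfg, init = "null")
  if (!is.null(p)) {
    st[names(p)] <- p
    st$lp <- esmtx:::esm_linpred(st, data)
  }
  st <- esm_update_ytilde(st, data, cfg)
  st <- esm_update_U_L(st, data, cfg)
  st <- esm_update_e(st, data)
  list(state = st, data = data)
}
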