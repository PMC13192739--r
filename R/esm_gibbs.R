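## Gibbs sampler for the exponential scale-mixture (ESM) model of one gene.
##
## Model (scale parameterization of the exponential throughout):
##   y_ij | U_ij ~ Exp(mu_ij * U_ij),
##   log mu_ij = alpha * log D_ij + beta * s_i + gamma' X_i + eta_g(i),
##   U_ij ~ rho * IG(theta1 + 1, theta1) + (1 - rho) * IG(theta2 + 1, theta2),
##   observed zeros are left-censored: y_ij = 0 iff the latent abundance
##   ytilde_ij < C.
## Priors: alpha ~ N(0, sigma2); beta spike-and-slab with inclusion
## indicator zeta ~ Bern(pi) and slab N(0, tau2); gamma_k ~ N(0, v2_k);
## eta_r ~ N(0, phi2); every standard deviation (sigma, v_k, phi, tau) is
## half-Cauchy(0, psi) via its two-level inverse-gamma representation;
## rho ~ Unif(0,1); theta1, theta2 ~ Exp(rate xi).
##
## Inference uses slice-sampling data augmentation: per observation a slice
## variable e_ij with likelihood contribution
##   1(e_ij > ydot_ij / (mu_ij U_ij)) * exp(-e_ij) / (mu_ij U_ij),
## where ydot is y for uncensored observations and the latent ytilde for
## censored ones.  Conditional on the slices, every regression coefficient
## has a truncated-normal full conditional whose mean carries the
## -(variance * sum of its covariate) term contributed by the 1/(mu U)
## factor.
##
## Sweep order: ytilde -> (U, L) -> rho -> (theta1, theta2 | MH) -> e ->
## alpha -> (beta, zeta) -> gamma -> eta -> variances.  The ytilde and U
## updates use the slice-marginalized conditionals (truncated exponential
## and conjugate inverse-gamma); the slice variables are regenerated
## immediately afterwards, making the scheme a valid partially collapsed
## Gibbs sampler and guaranteeing that every slice constraint holds when
## the coefficient updates read them.

#' Prior and sampler configuration for the ESM model
#'
#' @param pi prior inclusion probability of the group effect (default 0.5,
#'   a balanced prior belief on zero vs nonzero beta).
#' @param psi scale of the half-Cauchy priors on all standard-deviation
#'   parameters (default 10).
#' @param xi rate of the exponential priors on the precision parameters
#'   theta1, theta2 (default 10; prior mean 0.1, favouring the small values
#'   typical of extremely sparse data).
#' @param C left-censoring threshold (positive; typically
#'   [compute_censor_threshold()] applied to the full MTX table).  `NULL`
#'   is accepted by [run_pipeline()], which then computes the threshold
#'   from the MTX table; [run_gibbs()] itself requires a value.
#' @param n_iter,n_burn,thin chain length, burn-in, thinning (defaults
#'   6000 / 2000 / 2).
#' @param mh_step initial random-walk step (on log theta) of the
#'   Metropolis-Hastings update for theta1, theta2 (default 0.3).
#' @param adapt_mh adapt `mh_step` during burn-in toward an acceptance rate
#'   in 0.2-0.5 (default `TRUE`; the step is frozen after burn-in).
#' @param seed optional integer seed for the chain.
#' @return list of class `esm_prior_config`.
#' @export
esm_prior_config <- function(pi = 0.5, psi = 10, xi = 10, C = NULL,
                             n_iter = 6000, n_burn = 2000, thin = 2,
                             mh_step = 0.3, adapt_mh = TRUE, seed = NULL) {
  stopifnot(pi > 0, pi < 1, psi > 0, xi > 0, is.null(C) || C > 0,
            n_iter > n_burn, n_burn >= 0, thin >= 1)
  structure(list(pi = pi, psi = psi, xi = xi, C = C, n_iter = n_iter,
                 n_burn = n_burn, thin = thin, mh_step = mh_step,
                 adapt_mh = adapt_mh, seed = seed),
            class = "esm_prior_config")
}

## Normalize a paired_gene_data object into the flat structure the sampler
## consumes; precomputes the fixed sums appearing in the conditional means.
esm_model_data <- function(paired, config) {
  stopifnot(inherits(paired, "paired_gene_data"))
  if (paired$n_obs == 0) stop("esm_model_data: no observations")
  if (is.null(config$C) || !is.finite(config$C) || config$C <= 0) {
    stop("esm_model_data: config$C must be a positive censoring threshold")
  }
  if (any(paired$D <= 0)) {
    stop("esm_model_data: MGX values must be positive (use filter='mgx_positive')")
  }
  X <- paired$X
  K <- ncol(X)
  R <- length(paired$subject_ids)
  subj <- paired$subject
  list(gene_id = paired$gene_id, y = paired$y, logD = log(paired$D),
       s = as.numeric(paired$s), X = X, subj = subj,
       nobs = paired$n_obs, K = K, R = R,
       censored = paired$y == 0,
       C = config$C,
       sum_logD = sum(log(paired$D)), sum_s = sum(paired$s),
       sum_X = colSums(X),
       m_r = as.integer(tabulate(subj, nbins = R)),
       subj_f = factor(subj, levels = seq_len(R)))
}

## Fresh state at the sampler's initialization.  The default "regression"
## mode seeds the coefficients from an ordinary least-squares fit of
## log(y) on the design over the nonzero observations, which shortens the
## transient of the slice sampler considerably (single-site truncated-
## normal updates move coefficients in small increments); "null" starts
## every coefficient at zero.  Both initializations target the same
## stationary distribution.
esm_init_state <- function(data, config, init = c("regression", "null")) {
  init <- match.arg(init)
  nobs <- data$nobs
  st <- list(alpha = 0, beta = 0, zeta = 0L,
             gamma = numeric(data$K), eta = numeric(data$R),
             sigma2 = 1, b_sigma2 = 1, v2 = rep(1, data$K),
             b_v2 = rep(1, data$K), tau2 = 1, b_tau2 = 1,
             phi2 = 1, b_phi2 = 1,
             U = rep(1, nobs), L = 1L + (stats::runif(nobs) < 0.5),
             rho = 0.5, theta1 = 2, theta2 = 0.1,
             ydot = ifelse(data$censored, config$C / 2, data$y),
             e = numeric(nobs), lp = numeric(nobs),
             mh_step = rep(config$mh_step, 2), mh_accept = c(0, 0),
             mh_n = c(0, 0))
  if (init == "regression") {
    nz <- data$y > 0
    if (sum(nz) > data$K + 3) {
      Z <- cbind(data$X, logD = data$logD, s = data$s)[nz, , drop = FALSE]
      fit <- tryCatch(stats::lm.fit(Z, log(data$y[nz])), error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(stats::coef(fit)[!is.na(stats::coef(fit))]))) {
        cf <- stats::coef(fit)
        cf[is.na(cf)] <- 0
        st$gamma <- unname(cf[seq_len(data$K)])
        st$alpha <- unname(cf["logD"])
        st$beta <- unname(cf["s"])
        st$zeta <- as.integer(st$beta != 0)
      }
    }
  }
  st$lp <- esm_linpred(st, data)
  st$loge <- esm_slice_log_draw(log(st$ydot) - st$lp - log(st$U),
                                rep(1, nobs))
  st
}

esm_linpred <- function(state, data) {
  as.numeric(state$alpha * data$logD + state$beta * data$s +
               data$X %*% state$gamma + state$eta[data$subj])
}

#' @describeIn esm_gibbs_sweep latent abundances for censored zeros:
#'   each `ytilde_ij ~ Exp(mu_ij U_ij)` truncated to `[0, C)`.
#' @export
esm_update_ytilde <- function(state, data, config) {
  cz <- data$censored
  if (any(cz)) {
    ## clamp the scale into the representable range; the truncated draw is
    ## stable at both extremes (~Uniform[0,C) for huge scales, ~0 for tiny)
    lam <- pmin(pmax(exp(state$lp[cz]) * state$U[cz], 1e-300), 1e300)
    state$ydot[cz] <- pmax(rtexp_upper(sum(cz), scale = lam, upper = config$C),
                           1e-300)
  }
  state
}

#' @describeIn esm_gibbs_sweep auxiliary scales and mixture allocations:
#'   `U_ij ~ IG(theta_L + 2, ydot_ij/mu_ij + theta_L)`, then `L_ij` from the
#'   two-point conditional with weights `rho * IG(U | theta1+1, theta1)` and
#'   `(1-rho) * IG(U | theta2+1, theta2)` evaluated in log space.
#' @export
esm_update_U_L <- function(state, data, config) {
  th <- c(state$theta1, state$theta2)[state$L]
  ## ydot/mu computed via logs to dodge 0 * Inf at extreme states
  w <- exp(pmin(log(state$ydot) - state$lp, 690))
  b <- w + th
  state$U <- pmin(pmax(rinvgamma(data$nobs, shape = th + 2, scale = b),
                       1e-300), 1e300)
  lw1 <- log(state$rho) + dinvgamma(state$U, state$theta1 + 1, state$theta1, log = TRUE)
  lw2 <- log1p(-state$rho) + dinvgamma(state$U, state$theta2 + 1, state$theta2, log = TRUE)
  p1 <- 1 / (1 + exp(lw2 - lw1))
  state$L <- 1L + (stats::runif(data$nobs) >= p1)
  state
}

#' @describeIn esm_gibbs_sweep mixture weight `rho ~ Beta(n1 + 1, n2 + 1)`
#'   with `n1`, `n2` the component occupancy counts.
#' @export
esm_update_rho <- function(state, ...) {
  n1 <- sum(state$L == 1L)
  n2 <- length(state$L) - n1
  state$rho <- stats::rbeta(1, n1 + 1, n2 + 1)
  state
}

## log full-conditional density (up to a constant) of theta for one mixture
## component, given sufficient statistics of the U values allocated to it.
esm_theta_logpost <- function(theta, n_c, sum_logU, sum_invU, xi) {
  n_c * ((theta + 1) * log(theta) - lgamma(theta + 1)) -
    (theta + 2) * sum_logU - theta * sum_invU - xi * theta
}

#' @describeIn esm_gibbs_sweep precision parameters `theta1`, `theta2` by
#'   Metropolis-Hastings with a Gaussian random walk on `log theta`
#'   (Jacobian-corrected); the only non-conjugate updates in the model.
#' @export
esm_update_theta <- function(state, data, config, adapting = FALSE) {
  for (cc in 1:2) {
    sel <- state$L == cc
    n_c <- sum(sel)
    sum_logU <- sum(log(state$U[sel]))
    sum_invU <- sum(1 / state$U[sel])
    th <- if (cc == 1) state$theta1 else state$theta2
    prop <- th * exp(stats::rnorm(1, 0, state$mh_step[cc]))
    la <- esm_theta_logpost(prop, n_c, sum_logU, sum_invU, config$xi) -
      esm_theta_logpost(th, n_c, sum_logU, sum_invU, config$xi) +
      log(prop) - log(th)
    state$mh_n[cc] <- state$mh_n[cc] + 1
    if (log(stats::runif(1)) < la) {
      if (cc == 1) state$theta1 <- prop else state$theta2 <- prop
      state$mh_accept[cc] <- state$mh_accept[cc] + 1
    }
    if (adapting && state$mh_n[cc] %% 50 == 0) {
      rate <- state$mh_accept[cc] / state$mh_n[cc]
      if (rate < 0.2) state$mh_step[cc] <- state$mh_step[cc] * 0.8
      if (rate > 0.5) state$mh_step[cc] <- state$mh_step[cc] * 1.25
      state$mh_accept[cc] <- 0
      state$mh_n[cc] <- 0
    }
  }
  state
}

## log(bound + E) computed stably for any magnitude of the bound, given
## log(bound) and the exponential increments E.
esm_slice_log_draw <- function(log_bound, E) {
  small <- log_bound <= 0
  out <- numeric(length(log_bound))
  out[small] <- log(exp(log_bound[small]) + E[small])
  big <- !small
  out[big] <- log_bound[big] + log1p(E[big] * exp(-log_bound[big]))
  out
}

#' @describeIn esm_gibbs_sweep slice variables: `e_ij` = lower bound
#'   `ydot_ij/(mu_ij U_ij)` plus an Exp(1) draw (memorylessness of the
#'   exponential).  The slice variable is carried as its logarithm
#'   (`state$loge`), since only `log e` enters the constraint algebra and
#'   the bound can exceed the double-precision range in extreme states.
#' @export
esm_update_e <- function(state, data, ...) {
  state$loge <- esm_slice_log_draw(log(state$ydot) - state$lp - log(state$U),
                                   stats::rexp(data$nobs))
  state
}

## Per-observation constraint constant: the slice constraint
## e > ydot/(mu U) is equivalent to lp > cvec with
## cvec = -log(e U / ydot) = log(ydot) - log(e) - log(U).
esm_cvec <- function(state) {
  log(state$ydot) - state$loge - log(state$U)
}

#' Truncation bounds for a coefficient's full conditional
#'
#' Every regression coefficient in the ESM model has a truncated-normal full
#' conditional.  For the coefficient with observation-level covariate `z`
#' the slice constraints `lp_ij > c_ij` translate into
#' `lower = max over {z > 0} of r_ij/z_ij` and
#' `upper = min over {z < 0} of r_ij/z_ij`, where
#' `r_ij = c_ij - (lp_ij - coef * z_ij)` is the constraint residual with the
#' target term removed; empty index sets give infinite bounds.  For the
#' random effects and the intercept `z` is identically 1 on the relevant
#' observations, so the upper bound is `+Inf`.
#'
#' @param state,data current sampler state and model data.
#' @param which one of `"alpha"`, `"beta"`, `"gamma"`, `"eta"`.
#' @param index coefficient index for `"gamma"` (1 = intercept) or subject
#'   index for `"eta"`.
#' @return `c(lower, upper)`; errors if `lower >= upper`, which signals a
#'   corrupted state (the slice constraints always admit the current value).
#' @export
esm_coefficient_bounds <- function(state, data, which, index = NULL) {
  cvec <- esm_cvec(state)
  z_sel <- switch(which,
                  alpha = list(z = data$logD, sel = NULL, coef = state$alpha),
                  beta = list(z = data$s, sel = NULL, coef = state$beta),
                  gamma = list(z = data$X[, index], sel = NULL,
                               coef = state$gamma[index]),
                  eta = list(z = rep(1, data$nobs), sel = data$subj == index,
                             coef = state$eta[index]),
                  stop("unknown coefficient: ", which))
  z <- z_sel$z
  r <- cvec - (state$lp - z_sel$coef * z)
  sel <- if (is.null(z_sel$sel)) rep(TRUE, data$nobs) else z_sel$sel
  pos <- sel & z > 0
  neg <- sel & z < 0
  lower <- if (any(pos)) max(r[pos] / z[pos]) else -Inf
  upper <- if (any(neg)) min(r[neg] / z[neg]) else Inf
  if (lower >= upper) {
    stop(sprintf("esm_coefficient_bounds(%s): empty interval [%g, %g] - corrupted state",
                 which, lower, upper))
  }
  c(lower, upper)
}

## Truncated-normal draw used by all coefficient updates; guards the
## measure-zero case where clamping has made the interval degenerate.
esm_draw_coef <- function(mean, sd, lower, upper) {
  if (!(lower < upper)) return(lower)
  rtnorm(1, mean, sd, lower, upper)
}

#' @describeIn esm_gibbs_sweep MGX coefficient:
#'   `alpha ~ N(-sigma2 * sum(log D), sigma2)` truncated to its slice bounds.
#' @export
esm_update_alpha <- function(state, data, ...) {
  b <- esm_coefficient_bounds(state, data, "alpha")
  new <- esm_draw_coef(-state$sigma2 * data$sum_logD, sqrt(state$sigma2),
                       b[1], b[2])
  state$lp <- state$lp + (new - state$alpha) * data$logD
  state$alpha <- new
  state
}

#' @describeIn esm_gibbs_sweep spike-and-slab update of `(beta, zeta)`.
#'   `beta` is integrated out: with `h0` the indicator that all slice
#'   constraints hold at `beta = 0` and
#'   `log h1 = tau2 * (sum s)^2 / 2 + log integral over [LB, UB] of
#'   N(beta | -tau2 * sum s, tau2)`, the inclusion indicator is Bernoulli
#'   with success probability `pi h1 / ((1 - pi) h0 + pi h1)` (log-space);
#'   if `zeta = 1`, `beta` is drawn from the truncated slab, else set to 0.
#' @export
esm_update_beta_zeta <- function(state, data, config) {
  b <- esm_coefficient_bounds(state, data, "beta")
  lb <- b[1]; ub <- b[2]
  h0 <- (lb < 0) && (ub > 0)   # constraints at beta = 0
  m <- -state$tau2 * data$sum_s
  sd <- sqrt(state$tau2)
  log_h1 <- state$tau2 * data$sum_s^2 / 2 + log_tnorm_prob(m, sd, lb, ub)
  l1 <- log(config$pi) + log_h1
  l0 <- if (h0) log1p(-config$pi) else -Inf
  if (is.infinite(l0) && is.infinite(log_h1) && log_h1 < 0) {
    stop("esm_update_beta_zeta: h0 = 0 and h1 underflowed - inconsistent state")
  }
  p1 <- 1 / (1 + exp(l0 - l1))
  zeta <- as.integer(stats::runif(1) < p1)
  new <- if (zeta == 1L) esm_draw_coef(m, sd, lb, ub) else 0
  state$lp <- state$lp + (new - state$beta) * data$s
  state$beta <- new
  state$zeta <- zeta
  state
}

#' @describeIn esm_gibbs_sweep covariate coefficients:
#'   `gamma_k ~ N(-v2_k * sum(X_k), v2_k)` truncated to its slice bounds,
#'   updated sequentially over k (intercept first).
#' @export
esm_update_gamma <- function(state, data, ...) {
  for (k in seq_len(data$K)) {
    b <- esm_coefficient_bounds(state, data, "gamma", k)
    new <- esm_draw_coef(-state$v2[k] * data$sum_X[k], sqrt(state$v2[k]),
                         b[1], b[2])
    state$lp <- state$lp + (new - state$gamma[k]) * data$X[, k]
    state$gamma[k] <- new
  }
  state
}

#' @describeIn esm_gibbs_sweep subject random effects:
#'   `eta_r ~ N(-phi2 * m_r, phi2)` with only a lower truncation bound
#'   (its indicator covariate is +1 on the subject's observations); all
#'   subjects are updated jointly since their conditionals are independent
#'   given the rest.
#' @export
esm_update_eta <- function(state, data, ...) {
  cvec <- esm_cvec(state)
  r <- cvec - (state$lp - state$eta[data$subj])
  lower <- rep(-Inf, data$R)
  grp_max <- tapply(r, data$subj_f, max)
  has <- !is.na(grp_max)
  lower[has] <- grp_max[has]
  new <- rtnorm(data$R, mean = -state$phi2 * data$m_r,
                sd = sqrt(state$phi2), lower = lower, upper = Inf)
  state$lp <- state$lp + (new - state$eta)[data$subj]
  state$eta <- new
  state
}

#' @describeIn esm_gibbs_sweep likelihood-invariant translation moves.
#'   The truncated-normal coefficient updates move in small increments
#'   because the slice constraints pin each coefficient near its current
#'   value.  To traverse the posterior efficiently, each coefficient `c`
#'   with covariate `z` gets an additional Metropolis move proposing
#'   `c -> c + delta` together with `U_ij -> U_ij * exp(-delta z_ij)`,
#'   which leaves every `mu_ij U_ij` - and hence the entire augmented
#'   likelihood, including all slice constraints - unchanged.  The
#'   acceptance ratio involves only the inverse-gamma mixture prior of
#'   `U`, the coefficient's normal prior, and the Jacobian
#'   `exp(-delta * sum z)`.  For `beta` the move applies only when
#'   `zeta = 1`.
#' @export
esm_update_translations <- function(state, data, config, step = 0.25) {
  th <- c(state$theta1, state$theta2)[state$L]
  propose <- function(coef, z, pvar) {
    delta <- stats::rnorm(1, 0, step)
    sel <- z != 0
    Us <- state$U[sel]; ths <- th[sel]; zs <- z[sel]
    Unew <- Us * exp(-delta * zs)
    lr <- sum(dinvgamma(Unew, ths + 1, ths, log = TRUE) -
                dinvgamma(Us, ths + 1, ths, log = TRUE)) -
      delta * sum(zs) +
      (coef^2 - (coef + delta)^2) / (2 * pvar)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      list(coef = coef + delta, U = Unew, sel = sel, delta = delta)
    } else NULL
  }
  apply_move <- function(state, mv, z) {
    state$U[mv$sel] <- pmin(pmax(mv$U, 1e-300), 1e300)
    state$lp <- state$lp + mv$delta * z
    state
  }
  mv <- propose(state$alpha, data$logD, state$sigma2)
  if (!is.null(mv)) { state <- apply_move(state, mv, data$logD); state$alpha <- mv$coef }
  if (state$zeta == 1L) {
    mv <- propose(state$beta, data$s, state$tau2)
    if (!is.null(mv)) { state <- apply_move(state, mv, data$s); state$beta <- mv$coef }
  }
  for (k in seq_len(data$K)) {
    mv <- propose(state$gamma[k], data$X[, k], state$v2[k])
    if (!is.null(mv)) { state <- apply_move(state, mv, data$X[, k]); state$gamma[k] <- mv$coef }
  }
  ## eta moves touch disjoint observation sets, so all R proposals can be
  ## drawn and accepted jointly in one vectorized pass
  delta_r <- stats::rnorm(data$R, 0, step)
  d_obs <- delta_r[data$subj]
  Unew <- state$U * exp(-d_obs)
  lr_obs <- dinvgamma(Unew, th + 1, th, log = TRUE) -
    dinvgamma(state$U, th + 1, th, log = TRUE) - d_obs
  sums <- numeric(data$R)
  rs <- rowsum(lr_obs, data$subj)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  lr_r <- sums +
    (state$eta^2 - (state$eta + delta_r)^2) / (2 * state$phi2)
  lr_r[is.na(lr_r) | !is.finite(lr_r)] <- -Inf
  acc <- log(stats::runif(data$R)) < lr_r
  if (any(acc)) {
    acc_obs <- acc[data$subj]
    state$U[acc_obs] <- pmin(pmax(Unew[acc_obs], 1e-300), 1e300)
    state$eta[acc] <- state$eta[acc] + delta_r[acc]
    state$lp <- state$lp + (delta_r * acc)[data$subj]
  }
  state
}

#' @describeIn esm_gibbs_sweep variance parameters and their half-Cauchy
#'   auxiliaries, all conjugate inverse-gamma: e.g.
#'   `sigma2 ~ IG(1, alpha^2/2 + 1/b_sigma2)` and
#'   `b_sigma2 ~ IG(1, 1/sigma2 + 1/psi^2)`; when `zeta = 0`, `tau2` is
#'   drawn from its conditional prior `IG(1/2, 1/b_tau2)`.
#' @export
esm_update_variances <- function(state, data, config) {
  psi2 <- config$psi^2
  state$sigma2 <- rinvgamma(1, 1, state$alpha^2 / 2 + 1 / state$b_sigma2)
  state$b_sigma2 <- rinvgamma(1, 1, 1 / state$sigma2 + 1 / psi2)
  state$v2 <- rinvgamma(data$K, 1, state$gamma^2 / 2 + 1 / state$b_v2)
  state$b_v2 <- rinvgamma(data$K, 1, 1 / state$v2 + 1 / psi2)
  if (state$zeta == 1L) {
    state$tau2 <- rinvgamma(1, 1, state$beta^2 / 2 + 1 / state$b_tau2)
  } else {
    state$tau2 <- rinvgamma(1, 1 / 2, 1 / state$b_tau2)
  }
  state$b_tau2 <- rinvgamma(1, 1, 1 / state$tau2 + 1 / psi2)
  state$phi2 <- rinvgamma(1, data$R / 2 + 1 / 2,
                          sum(state$eta^2) / 2 + 1 / state$b_phi2)
  state$b_phi2 <- rinvgamma(1, 1, 1 / state$phi2 + 1 / psi2)
  state
}

#' One full Gibbs sweep over all latent quantities and parameters
#'
#' Applies, in order: censored latent abundances, auxiliary scales and
#' mixture allocations, mixture weight, precision parameters (MH), slice
#' variables, then the truncated-normal coefficient updates (alpha; beta
#' and zeta jointly; gamma; eta) and the conjugate variance updates.  After
#' a sweep every slice constraint `e_ij > ydot_ij/(mu_ij U_ij)` holds.
#'
#' @param state sampler state as produced by the update functions.
#' @param data model data (internal flat form of a `paired_gene_data`).
#' @param config an [esm_prior_config()].
#' @param adapting logical; adapt the MH step (burn-in only).
#' @return updated state.
#' @export
esm_gibbs_sweep <- function(state, data, config, adapting = FALSE) {
  state <- esm_update_ytilde(state, data, config)
  state <- esm_update_U_L(state, data, config)
  state <- esm_update_rho(state)
  state <- esm_update_theta(state, data, config, adapting)
  state <- esm_update_e(state, data)
  state <- esm_update_alpha(state, data)
  state <- esm_update_beta_zeta(state, data, config)
  state <- esm_update_gamma(state, data)
  state <- esm_update_eta(state, data)
  state <- esm_update_translations(state, data, config)
  state <- esm_update_variances(state, data, config)
  state
}

#' Fit the ESM model to one gene by Gibbs sampling
#'
#' Runs the full sampler on a gene's paired MTX/MGX observations and stores
#' thinned post-burn-in draws of the interpretable parameters.  `beta` is
#' the natural-log fold change of the group effect; its posterior inclusion
#' probability (the mean of `zeta`) is the differential-expression evidence
#' used downstream.
#'
#' @param paired a `paired_gene_data` (all MGX values positive).
#' @param config an [esm_prior_config()]; `config$C` is the censoring
#'   threshold.
#' @param init `"regression"` (default; coefficients seeded from a least-
#'   squares fit on the nonzero observations) or `"null"` (all zeros).
#' @return object of class `esm_fit`: `draws` (matrix with columns `alpha`,
#'   `beta`, `zeta`, `gamma.*`, `theta1`, `theta2`, `rho`, `sigma2`,
#'   `tau2`, `phi2`), `pip`, `accept_theta`, `uninformative` flag (all
#'   observations censored), the config, and data dimensions.
#' @export
run_gibbs <- function(paired, config, init = c("regression", "null")) {
  stopifnot(inherits(config, "esm_prior_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  data <- esm_model_data(paired, config)
  state <- esm_init_state(data, config, init = init)
  keep_iters <- seq.int(config$n_burn + 1, config$n_iter)
  keep_iters <- keep_iters[(seq_along(keep_iters) - 1) %% config$thin == 0]
  cn <- c("alpha", "beta", "zeta",
          paste0("gamma.", colnames(data$X)),
          "theta1", "theta2", "rho", "sigma2", "tau2", "phi2")
  draws <- matrix(NA_real_, nrow = length(keep_iters), ncol = length(cn),
                  dimnames = list(NULL, cn))
  row <- 0L
  for (it in seq_len(config$n_iter)) {
    state <- esm_gibbs_sweep(state, data, config,
                             adapting = config$adapt_mh && it <= config$n_burn)
    if (it %% 200 == 0 && !all(is.finite(state$lp))) {
      bad <- which(!is.finite(state$lp))[1]
      stop(sprintf("run_gibbs: non-finite state at iteration %d, observation %d (gene %s)",
                   it, bad, data$gene_id))
    }
    if (row < length(keep_iters) && it == keep_iters[row + 1L]) {
      row <- row + 1L
      draws[row, ] <- c(state$alpha, state$beta, state$zeta, state$gamma,
                        state$theta1, state$theta2, state$rho,
                        state$sigma2, state$tau2, state$phi2)
    }
  }
  uninformative <- all(data$censored)
  if (uninformative) {
    warning(sprintf("gene %s: all observations censored; posterior is prior-dominated",
                    data$gene_id))
  }
  structure(list(gene_id = data$gene_id, draws = draws,
                 pip = mean(draws[, "zeta"]),
                 accept_theta = state$mh_accept / pmax(state$mh_n, 1),
                 mh_step = state$mh_step,
                 uninformative = uninformative,
                 n_obs = data$nobs, n_samples = max(0, length(unique(paired$sample))),
                 n_censored = sum(data$censored),
                 config = config),
            class = "esm_fit")
}

#' @export
print.esm_fit <- function(x, ...) {
  cat(sprintf("esm_fit '%s': %d draws; PIP = %.3f; beta (slab mean) = %.3f\n",
              x$gene_id, nrow(x$draws), x$pip,
              mean(x$draws[x$draws[, "zeta"] == 1, "beta"])))
  invisible(x)
}

#' Posterior summary of an ESM fit
#'
#' @param fit an `esm_fit`.
#' @param prob credible-interval mass (default 0.95).
#' @return one-row data.frame with the gene id, PIP, the conditional log
#'   fold change `beta_mean` (posterior mean of beta over inclusion draws;
#'   `NA` when no draw has `zeta = 1`), the unconditional mean
#'   `beta_mean_all`, credible bounds, and posterior means of the remaining
#'   parameters.
#' @export
posterior_summary <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "esm_fit"))
  d <- fit$draws
  inc <- d[, "zeta"] == 1
  qs <- c((1 - prob) / 2, 1 - (1 - prob) / 2)
  beta_inc <- d[inc, "beta"]
  gcols <- grep("^gamma\\.", colnames(d), value = TRUE)
  out <- data.frame(
    gene_id = fit$gene_id,
    pip = mean(d[, "zeta"]),
    beta_mean = if (any(inc)) mean(beta_inc) else NA_real_,
    beta_ci_low = if (any(inc)) unname(stats::quantile(beta_inc, qs[1])) else NA_real_,
    beta_ci_high = if (any(inc)) unname(stats::quantile(beta_inc, qs[2])) else NA_real_,
    beta_mean_all = mean(d[, "beta"]),
    beta_sd_all = stats::sd(d[, "beta"]),
    alpha_mean = mean(d[, "alpha"]),
    theta1_mean = mean(d[, "theta1"]),
    theta2_mean = mean(d[, "theta2"]),
    rho_mean = mean(d[, "rho"]),
    n_obs = fit$n_obs, n_censored = fit$n_censored,
    uninformative = fit$uninformative,
    stringsAsFactors = FALSE)
  for (g in gcols) out[[paste0(g, "_mean")]] <- mean(d[, g])
  out
}
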