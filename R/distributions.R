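## Distribution primitives underlying the exponential scale-mixture (ESM) model.
##
## Conventions used throughout the package:
##  * Exponential distributions are parameterized by SCALE (= mean), never by
##    rate.  Exp(lambda) has density exp(-y/lambda)/lambda.
##  * IG(a, b) is the inverse-gamma distribution with shape a and scale b,
##    i.e. density b^a/Gamma(a) * x^(-a-1) * exp(-b/x), mean b/(a-1) for a > 1.
##  * Lo(a, b) is the Lomax (Pareto type II) distribution with shape a and
##    scale b: pdf (a/b)(1 + y/b)^(-a-1) on y >= 0.

#' Lomax (Pareto type II) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Lomax distribution with shape `shape` (> 0) and scale `scale`
#' (> 0).  The Lomax distribution arises in the ESM model as the marginal of
#' an exponential observation whose scale is mixed over an inverse-gamma
#' auxiliary variable: if `U ~ IG(theta + 1, theta)` and
#' `y | U ~ Exp(mu * U)` (scale parameterization) then marginally
#' `y ~ Lo(theta + 1, mu * theta)`, with mean `mu` and variance
#' `mu^2 (theta + 1)/(theta - 1)` for `theta > 1`.
#'
#' @param x,q vector of nonnegative quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param shape shape parameter `a > 0`; the survival function decays as
#'   `(1 + y/b)^(-a)`, so `a` is the polynomial tail index.
#' @param scale scale parameter `b > 0`.
#' @param log,log.p logical; return log density / log probability.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   `P(X <= x)`.
#' @return `dlomax` the density, `plomax` the distribution function,
#'   `qlomax` the quantile function, `rlomax` a vector of draws.
#' @examples
#' plomax(1, shape = 2, scale = 1)   # 0.75
#' mean(rlomax(1e4, shape = 3, scale = 6))  # close to 3
#' @export
dlomax <- function(x, shape, scale, log = FALSE) {
  stopifnot(all(shape > 0), all(scale > 0))
  if (any(x < 0)) stop("dlomax: x must be nonnegative")
  ld <- log(shape) - log(scale) - (shape + 1) * log1p(x / scale)
  if (log) ld else exp(ld)
}

#' @rdname dlomax
#' @export
plomax <- function(q, shape, scale, lower.tail = TRUE, log.p = FALSE) {
  stopifnot(all(shape > 0), all(scale > 0))
  if (any(q < 0)) stop("plomax: q must be nonnegative")
  lsurv <- -shape * log1p(q / scale)
  if (lower.tail) {
    p <- -expm1(lsurv)
    if (log.p) log(p) else p
  } else {
    if (log.p) lsurv else exp(lsurv)
  }
}

#' @rdname dlomax
#' @export
qlomax <- function(p, shape, scale, lower.tail = TRUE, log.p = FALSE) {
  stopifnot(all(shape > 0), all(scale > 0))
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  stopifnot(all(p >= 0), all(p <= 1))
  scale * expm1(-log1p(-p) / shape)
}

#' @rdname dlomax
#' @export
rlomax <- function(n, shape, scale) {
  ## inverse-cdf: y = b * ((1-u)^(-1/a) - 1); exact, no rejection
  stopifnot(all(shape > 0), all(scale > 0))
  u <- stats::runif(n)
  scale * expm1(-log1p(-u) / shape)
}

#' Inverse-gamma distribution
#'
#' Density and random generation for the inverse-gamma distribution with
#' shape `shape` and scale `scale` (the `b` in `IG(a, b)`; mean `b/(a-1)`
#' for `a > 1`).  `rinvgamma` draws are obtained as the reciprocal of gamma
#' draws with rate `scale`.
#'
#' @param x vector of positive quantiles.
#' @param n number of draws.
#' @param shape,scale positive parameters.
#' @param log logical; return log density.
#' @export
dinvgamma <- function(x, shape, scale, log = FALSE) {
  stopifnot(all(shape > 0), all(scale > 0))
  ld <- shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dinvgamma
#' @export
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

#' Truncated exponential draws
#'
#' `rtexp_upper` draws from Exp(scale) truncated to `[0, upper)` by inverse
#' cdf.  `rtexp_lower` draws from Exp(scale) truncated to `(lower, Inf)`: by
#' memorylessness this is `lower + Exp(scale)`, and it is implemented that
#' way.
#'
#' @param n number of draws.
#' @param scale exponential scale (= mean); vectorized.
#' @param upper,lower truncation bound; vectorized.
#' @return vector of draws.
#' @export
rtexp_upper <- function(n, scale, upper) {
  if (any(upper <= 0)) stop("rtexp_upper: upper bound must be positive")
  stopifnot(all(scale > 0))
  u <- stats::runif(n)
  ## F(y)/F(upper) inverted: y = -scale * log(1 - u * (1 - exp(-upper/scale)))
  -scale * log1p(u * expm1(-upper / scale))
}

#' @rdname rtexp_upper
#' @export
rtexp_lower <- function(n, scale, lower) {
  stopifnot(all(scale > 0))
  lower + stats::rexp(n) * scale
}

## log(1 - exp(x)) for x < 0, stable near both ends (Maechler 2012)
log1mexp <- function(x) {
  out <- ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
  out[x >= 0] <- NaN
  out
}

## log(exp(lx) - exp(ly)) for lx >= ly
logspace_sub <- function(lx, ly) {
  ifelse(is.infinite(ly) & ly < 0, lx, lx + log1mexp(ly - lx))
}

#' Log probability mass of a normal distribution on an interval
#'
#' Computes `log(pnorm(upper, mean, sd) - pnorm(lower, mean, sd))` stably,
#' including when the interval lies far in either tail (standardized bounds
#' of hundreds are handled; the computation moves to whichever tail carries
#' the smaller mass and works with `pnorm(..., log.p = TRUE)`).
#'
#' @param mean,sd normal parameters (`sd > 0`).
#' @param lower,upper interval bounds, `-Inf`/`Inf` allowed; `lower < upper`.
#' @return log of the interval probability (possibly very negative, never
#'   `NaN` for valid input).
#' @export
log_tnorm_prob <- function(mean, sd, lower, upper) {
  stopifnot(sd > 0)
  if (lower >= upper) stop("log_tnorm_prob: lower must be < upper")
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  if (a >= 0) {
    ## both bounds in the upper tail: survival-function difference
    la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b, lower.tail = FALSE, log.p = TRUE)
    logspace_sub(la, lb)
  } else if (b <= 0) {
    la <- stats::pnorm(a, log.p = TRUE)
    lb <- stats::pnorm(b, log.p = TRUE)
    logspace_sub(lb, la)
  } else {
    ## straddles the mean: mass is not tiny, direct difference is safe
    log(stats::pnorm(b) - stats::pnorm(a))
  }
}

#' Truncated normal draws, stable in far tails
#'
#' Draws from N(`mean`, `sd`^2) restricted to `(lower, upper)` by inversion
#' of the cdf carried out on the log scale in the tail containing the
#' interval.  Remains accurate when the interval lies hundreds of standard
#' deviations from the mean, which routinely happens for the slice-sampler
#' full conditionals of the ESM Gibbs sampler (their means contain terms
#' like `-sigma^2 * sum(log D)`).
#'
#' All arguments are recycled to length `n`.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds (`-Inf`, `Inf` allowed).
#' @return vector of `n` draws, each inside its interval.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(sd <= 0)) stop("rtnorm: sd must be positive")
  if (any(lower >= upper)) stop("rtnorm: lower >= upper")
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- numeric(n)
  u <- stats::runif(n)

  ## reflect lower-tail intervals so every one-sided case is an upper tail
  neg <- b <= 0
  if (any(neg)) {
    tmp <- a[neg]; a[neg] <- -b[neg]; b[neg] <- -tmp
  }
  tail_case <- a >= 0
  if (any(tail_case)) {
    la <- stats::pnorm(a[tail_case], lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b[tail_case], lower.tail = FALSE, log.p = TRUE)
    ## interpolate tail probabilities: p = exp(la) * (1 + u*(exp(lb-la) - 1))
    lp <- la + log1p(u[tail_case] * expm1(lb - la))
    zt <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
    ## guard against degenerate zero-width intervals at double precision
    zt <- pmin(pmax(zt, a[tail_case]), b[tail_case])
    z[tail_case] <- zt
  }
  mid <- !tail_case
  if (any(mid)) {
    pa <- stats::pnorm(a[mid])
    pb <- stats::pnorm(b[mid])
    zm <- stats::qnorm(pa + u[mid] * (pb - pa))
    zm <- pmin(pmax(zm, a[mid]), b[mid])
    z[mid] <- zm
  }
  z[neg] <- -z[neg]
  mean + sd * z
}

#' Monte-Carlo check of the scale-mixture / Lomax identity
#'
#' Draws `n` auxiliary variables `U ~ IG(theta + 1, theta)` and then
#' `y | U ~ Exp(mu * U)` (scale parameterization), and compares the draws
#' against the closed-form Lomax cdf `Lo(theta + 1, mu * theta)` with a
#' one-sample Kolmogorov-Smirnov test.  Under the scale-mixture identity the
#' two agree for every `theta, mu > 0`.
#'
#' @param theta precision parameter of the inverse-gamma mixing law (> 0).
#' @param mu mean of the marginal distribution (> 0).
#' @param n number of Monte-Carlo draws (>= 1).
#' @param seed optional integer seed.
#' @return the `htest` object from [stats::ks.test()] against the Lomax cdf.
#' @export
esm_marginal_equivalence_check <- function(theta, mu, n = 1e5, seed = NULL) {
  stopifnot(theta > 0, mu > 0)
  if (n < 1) stop("esm_marginal_equivalence_check: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  U <- rinvgamma(n, shape = theta + 1, scale = theta)
  y <- stats::rexp(n) * (mu * U)
  stats::ks.test(y, function(q) plomax(q, shape = theta + 1, scale = mu * theta))
}

#' Empirical tail index of heavy-tailed samples
#'
#' Estimates the polynomial tail index by regressing the log empirical
#' survival function on `log(1 + y/scale)`.  For Lomax samples
#' `Lo(a, scale)` the log survival is exactly `-a * log(1 + y/scale)`, so
#' the fitted slope estimates `-a` (= `-(theta + 1)` in the model
#' parameterization).
#'
#' @param samples numeric vector of nonnegative draws (>= 100 recommended).
#' @param scale the Lomax scale used to form the regressor.
#' @param upper_frac fraction of the largest order statistics used for the
#'   fit (default 0.5; the relation is global for exact Lomax data, but the
#'   upper half emphasises tail behaviour for near-Lomax samples).
#' @return fitted slope (negative for heavy-tailed data).
#' @export
tail_index_estimate <- function(samples, scale, upper_frac = 0.5) {
  n <- length(samples)
  if (n < 100) stop("tail_index_estimate: need at least 100 samples")
  ys <- sort(samples)
  surv <- 1 - seq_len(n) / (n + 1)
  keep <- seq.int(from = floor(n * (1 - upper_frac)) + 1, to = n)
  x <- log1p(ys[keep] / scale)
  unname(stats::coef(stats::lm(log(surv[keep]) ~ x))[2])
}
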