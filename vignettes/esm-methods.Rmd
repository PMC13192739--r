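---
title: "Exponential scale-mixture models for metatranscriptomic differential expression"
author: "esmtx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential scale-mixture models for metatranscriptomic differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmtx)
```

## The problem

Metatranscriptomic (MTX) pipelines such as HUMAnN report gene-family
abundances as depth- and length-normalized CPM values, not raw counts, so
count-based RNA-seq machinery does not apply. The data are also extreme:
for most gene families the vast majority of sample-taxon measurements are
exactly zero, and the nonzero values are heavy-tailed. Gaussian approaches
fit `log(y + pseudocount)` with a linear mixed model; the zeros then form
their own residual mode whose location is an artifact of the pseudocount,
and both the gene lists and the effect sizes move when the pseudocount
changes. `residual_density_report()` reproduces that diagnostic on any
gene.

`esmtx` instead models the CPM values directly on the nonnegative half
line, per gene family, at the (sample `i`, taxon `j`) level:

$$
y_{ij} \mid U_{ij} \sim \mathrm{Exp}(\mu_{ij} U_{ij}), \qquad
\log \mu_{ij} = \alpha \log D_{ij} + \beta s_i + \gamma' X_i + \eta_{g(i)},
$$

where the exponential is parameterized by its **scale** (= mean)
throughout the package, `D` is the paired metagenomic (MGX) abundance
adjusting for gene-copy potential, `s` is the binary group of interest
(e.g. dysbiosis), `X` holds an intercept and covariates, and `eta` is a
subject random effect for repeated sampling. The auxiliary scale follows a
two-component inverse-gamma mixture,

$$
U_{ij} \sim \rho\, \mathrm{IG}(\theta_1 + 1, \theta_1) +
        (1 - \rho)\, \mathrm{IG}(\theta_2 + 1, \theta_2).
$$

Marginally over a single IG component, `y` is Lomax with shape
`theta + 1`, scale `mu * theta`, mean `mu` (any `theta > 0`) and variance
`mu^2 (theta + 1)/(theta - 1)` for `theta > 1` — a polynomial tail of
index `theta + 1`. Small `theta` concentrates mass at zero *and* fattens
the tail, which is exactly the shape sparse MTX data demand; the second,
small-`theta` component absorbs the excess zeros that even a single Lomax
cannot. All of these identities are verified by Monte-Carlo tests in the
suite (`esm_marginal_equivalence_check()`, `tail_index_estimate()`).

Zeros are treated as left-censored: `y = 0` is observed when the latent
abundance falls below a threshold `C`, taken as the minimum nonzero
taxon-level MTX value across the whole table
(`compute_censor_threshold()`), i.e. the minimum detectable abundance.
Observations with `D = 0` are removed entirely (RNA signal without
detectable gene copies is treated as a technical artifact); observations
with `y = 0, D > 0` are retained as censored. Coefficients are natural-log
fold changes of the mean.

## Inference

Posterior sampling is a Gibbs sampler with slice-sampling data
augmentation. Censored observations get latent abundances
`ytilde ~ Exp(mu U)` truncated to `[0, C)`; a per-observation slice
variable `e` with likelihood contribution
`1(e > ydot/(mu U)) exp(-e) / (mu U)` turns every coefficient conditional
into a truncated normal whose mean carries a `-variance * sum(covariate)`
term and whose bounds are max/min ratios of constraint residuals
(`esm_coefficient_bounds()`). The group effect gets a spike-and-slab prior
(`delta_0` vs `N(0, tau^2)`, inclusion probability `pi`); its indicator is
updated with `beta` integrated out, in log space. All standard deviations
(`sigma`, `v_k`, `phi`, `tau`) carry half-Cauchy(`psi`) priors through the
two-level inverse-gamma representation, giving conjugate variance updates;
`U` is conjugate inverse-gamma; the mixture allocation, weight and the
`theta` Metropolis step (random walk on `log theta`, adapted during
burn-in to a 0.2–0.5 acceptance rate) complete the sweep.

Three implementation choices deserve explanation:

* **Sweep order.** The latent-abundance and `U` conditionals are the
  slice-marginalized ones (truncated exponential; conjugate
  inverse-gamma). A marginalized update is only valid if the marginalized
  variable is redrawn from its exact conditional before anything
  conditions on it again, so the sweep runs
  `ytilde -> (U, L) -> rho -> theta -> e -> coefficients -> variances`.
  This partially collapsed ordering guarantees that every slice constraint
  holds when the coefficient updates read them — an invariant the test
  suite asserts after every sweep.

* **Translation moves.** The truncated-normal updates move each
  coefficient only in small increments because the slice constraints pin
  it near its current value; alone they need extremely long chains.  Each
  sweep therefore adds a Metropolis move per coefficient that proposes a
  shift `c -> c + delta` together with the compensating rescale
  `U_ij -> U_ij exp(-delta z_ij)`. The product `mu U` — and with it the
  entire augmented likelihood, censoring terms and slice constraints — is
  unchanged, so the acceptance ratio involves only the `U` mixture prior,
  the coefficient's normal prior and the Jacobian. These moves do not
  alter the stationary distribution (the suite's successive-conditional
  test covers them) and cut the effective mixing time by orders of
  magnitude.

* **Initialization.** By default the regression coefficients start at a
  least-squares fit of `log y` on the design over the nonzero
  observations (`init = "regression"`); `init = "null"` starts everything
  at zero. Both target the same posterior; the default merely shortens the
  transient.

Numerical policy: inclusion and allocation probabilities are computed with
log-sum-exp; truncated-normal tail draws and interval masses use
`pnorm`/`qnorm` on the log scale and remain accurate hundreds of standard
deviations out (`rtnorm()`, `log_tnorm_prob()`); the slice variable is
carried as its logarithm; latent quantities are clamped to
`[1e-300, 1e300]`, which only matters in stress tests that push
heavy-tailed prior states to the limits of double precision. A gene whose
observations are all censored still runs but is flagged
`uninformative`. If slice bounds ever cross (impossible in a consistent
state), the sampler aborts rather than continuing silently.

## Defaults and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pi` | 0.5 | prior inclusion probability of the group effect (balanced prior belief) |
| `psi` | 10 | half-Cauchy scale of all standard-deviation priors |
| `xi` | 10 | **rate** of the Exp prior on `theta1`, `theta2` (prior mean 0.1) |
| `C` | min nonzero MTX | censoring threshold, CPM |
| `n_iter / n_burn / thin` | 6000 / 2000 / 2 | chain settings |
| `alpha_fdr` | 0.05 | target Bayesian FDR level |

The `xi` convention needs a note: the exponential prior on the precision
parameters is parameterized by **rate**, so larger `xi` favours smaller
`theta` — the reading under which "`xi = 10` favours small nonnegative
values" is coherent. Both `psi` and `xi` are plain arguments of
`esm_prior_config()` for sensitivity analysis.

## Differential-expression calls

Evidence for a gene is the posterior inclusion probability (PIP), the
posterior mean of the spike-and-slab indicator. Genes are ranked by
descending PIP (ties broken by gene id) and the discovery list is the
longest prefix whose mean posterior false-discovery contribution
`mean(1 - PIP)` stays below the target level (`select_de_genes()`); the
resulting sets are nested across target levels. Two effect summaries are
reported: the conditional posterior mean of `beta` over inclusion draws
(the headline log fold change) and the unconditional mean over all draws.
The Gaussian comparator (`gm_fit()`, `run_gm_baseline()`) uses
`lmerTest::lmer()` on `log(y + pc) ~ log(D + pc) + s + covariates +
(1 | subject)` with Benjamini–Hochberg control, natural logs throughout so
effect scales are comparable, and a fixed-effects fallback when the mixed
fit fails. Pseudocounts replace zeros by default (`add_all` is available);
the half-minimum scheme computes the pseudocount separately for the MTX
and MGX vectors.

## What the synthetic data emulate

Two generators back the tests and benchmarks:

* `generate_esm_gene()` draws from the model itself: log-normal MGX
  values spanning several orders of magnitude (optionally with a zero
  fraction, which the MGX filter then removes), subject random effects,
  the two-component mixture, and censoring at `C`. The default setting —
  300 samples, 100 subjects, 3 taxa, `alpha = 1`, `beta = log 10`,
  `theta1 = 2`, `theta2 = 0.05`, `rho = 0.6`, `C = 0.1` — is the
  parameter-recovery design: a strong but realistic 10-fold signal in a
  repeated-measures study, with roughly a fifth of observations censored.

* `build_benchmark()` mimics a signal-injection evaluation without any
  external download. A backbone of null genes is generated
  (`theta1 = 1`, `theta2 = 0.02`, `rho = 0.35`, `C = 0.5`, 10% MGX
  zeros), then for each gene the samples are split evenly into two groups
  *separately within the zero and nonzero strata* — keeping baseline
  abundances comparable between groups — and the group-1 MTX values of
  40% of genes are multiplied (half) or divided (half) by 10, so the true
  group coefficient is `±log 10`. The backbone's ~70–75% zero fraction
  matches analysis-eligible genes (which pass the ≥2-shared-taxa and
  category-count filters and are necessarily less sparse than the
  full-table median of ~0.996), not the full table.

What passing these benchmarks does **not** show: the generative backbone
uses a fixed taxa-per-sample count and model-consistent heavy tails,
whereas real tables have gene-specific taxa structure, cross-gene
dependence, and compositional artifacts; absolute TPR/FDR numbers here
therefore do not transfer to any particular cohort. Directional claims
(calibration of the PIP-based FDR rule; power and effect-size accuracy
relative to pseudocount-based Gaussian fits) are the transferable content.
A real HUMAnN table can be substituted as the backbone via the I/O layer
to rerun the same comparison on cohort data.

## Problem sizes used by the checks

The suite's heavy checks run at sizes chosen to make their statistical
claims sharp while staying comfortable on one CPU: the
successive-conditional (Geweke-style) sampler test uses a 10-observation
design with 20 independent chains of 2000 sweeps, each started exactly at
stationarity, with across-chain standard errors (heavy-tailed half-Cauchy
states make single-chain batch means untrustworthy); parameter recovery
uses 50 replicates of the n = 300 design at 1600 sweeps; the benchmark
uses 100 genes x 200 samples at 2000 sweeps per gene. The acceptance
script mirrors these sizes (30 recovery replicates).

## Known limitations

* The intercept, subject effects and the mixture's location trade off;
  only their combination is sharply identified (half-Cauchy shrinkage
  regularizes the split). Interpret `gamma_0` and individual `eta_r`
  cautiously.
* The mixture components are exchangeable a priori; `theta1`/`theta2`
  summaries are subject to label switching and should be read jointly
  with `rho`.
* PIPs from very short chains are biased toward their initialization;
  the defaults (6000 sweeps) are conservative for routine use, and the
  scaled-down settings used in the tests were validated against the
  calibration criteria above.
* Genes with all observations censored, or failing the eligibility
  filter (shared taxa, category counts, collinearity), are reported as
  skipped rather than fitted.
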