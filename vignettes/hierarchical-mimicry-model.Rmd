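---
title: "Hierarchical beta-binomial modelling of visitation to mimic flowers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical beta-binomial modelling of visitation to mimic flowers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicbayes)
```

## The scientific problem

Monoecious plants with a self-mimicry pollination system carry two floral
morphs on the same individual: rewarding male flowers (the "models") and
rewardless female flowers that resemble them (the "mimics"). The system
works only insofar as pollinators are *duped* into visiting female
flowers. Field observations reduce each insect's visit sequence — a
*trail* — to a pair of counts: `z`, the visits to female flowers, out of
`n` total visits. Treatments manipulate the male:female sex ratio
(e.g. an even 1:1 control, a 3:1 male-biased array, a 1:3 female-biased
array), and the question is whether the mimic:model ratio changes how
often insects are duped.

## The model

For insect `j` in treatment `e`:

$$z_{je} \sim \mathrm{Binomial}(n_{je},\ \theta_{je}), \qquad
\theta_{je} \sim \mathrm{Beta}\!\left(\mu_e \kappa_{(e)},\ (1-\mu_e)\kappa_{(e)}\right)$$

`theta_je` is the insect's duping probability; `mu_e` the treatment's
mean duping probability (so `1 - mu_e` is the group's discrimination
ability); and `kappa` the concentration — how tightly individual insects
cluster around the group mean. The Beta layer makes the trail counts
beta-binomial, i.e. overdispersed relative to a common-`theta` binomial,
which is what heterogeneous insects produce.

Three families differ only in the concentration structure:

* **A1** — one `kappa` shared by every treatment, `kappa ~ Gamma(1.0, 0.1)`.
* **A2** — an independent `kappa_e` per treatment, each with that same
  fixed Gamma prior (the "naive" hierarchical model: treatments do not
  inform one another about spread).
* **B** — `kappa_e ~ Gamma(mean = mu_gamma, sd = sd_gamma)` with uniform
  hyperpriors on `mu_gamma` and `sd_gamma`, so the treatments mutually
  inform the concentration scale.

Two prior conditions cover the group means: **C1**, an informative
`mu_e ~ Beta(4, 1)` elicited from a prior mean mimicry success of
`m = 0.80` held with the weight of `n = 5` visits (`a = mn = 4`,
`b = (1 - m)n = 1`); and **C2**, the open-minded uniform `Beta(1, 1)`.
The Gamma prior is always stated in moment form and converted with
`gamma_shape_rate_from_mean_sd()`: mean 10, SD 10 gives shape 1.0 and
rate 0.1.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `mu_e` | mean duping probability per treatment (unitless probability) | prior C1/C2 | the scientific quantity of interest |
| `kappa` | concentration of insects around `mu_e` | prior mean 10, SD 10 | weakly informative; allows strong insect heterogeneity |
| family B bounds | uniform hyperprior interval for `mu_gamma`, `sd_gamma` | (0.01, 100) | "a positive interval" is otherwise unspecified; wide enough to cover plausible posterior concentrations, configurable |
| chains/iterations | 4 × 50,000, burn-in 10,000 (A1/A2); 4 × 100,000, burn-in 40,000 (B) | study protocol | family B's hyperparameters mix slowly |

A practical caveat worth stating explicitly: once `kappa` exceeds the
typical trail length the likelihood is nearly flat in it (the
beta-binomial collapses to the binomial), so under family B the upper
tail of the `kappa_e` and `mu_gamma` posteriors is governed largely by
the hyperprior bounds. Fits under family B should therefore be read with
the bound choice in mind; families A1/A2, whose Gamma(1.0, 0.1) prior has
an exponential right tail, are much less sensitive.

## Sampling

The paper-of-record for this class of model used JAGS; the sampler here
is our own Metropolis-within-Gibbs scheme, with only the target density
shared:

1. every `theta_je` has a conjugate Beta full conditional,
   `Beta(z + mu kappa, n - z + (1 - mu) kappa)`, drawn exactly;
2. each `mu_e` is updated by random-walk Metropolis on the logit scale,
   `kappa` on the log scale, and (family B) `mu_gamma`/`sd_gamma` on the
   log scale, each with the change-of-variable Jacobian;
3. proposal scales adapt toward a 0.25–0.5 acceptance rate in windows of
   50 iterations, **only during burn-in**, so the retained chain is a
   fixed-kernel Markov chain with the correct stationary law;
4. chain `c` runs under `set.seed(master_seed + c)`; identical inputs
   give bitwise-identical chains.

Convergence is monitored with the Gelman–Rubin potential scale reduction
factor (between/within-chain variance form; warn threshold 1.1 by
default, configurable — the source protocol names no number) and an
initial-positive-sequence effective sample size. A prior-recovery mode
(`likelihood = FALSE`) drops the data terms so the sampler can be
validated against the analytic prior moments; this is an explicit engine
flag because the data model deliberately rejects empty trails.

## Summaries

Intervals are 95% highest density intervals: the shortest contiguous
window of the sorted pooled draws containing `ceiling(0.95 n)` of them,
ties broken at the lowest start. The matching equal-tailed 2.5/97.5%
quantile interval is reported alongside, since the two coincide only for
symmetric marginals and the source conflated them in its description.
Central tendency is the mean plus a KDE mode (Silverman bandwidth) for
skewed marginals. Treatment contrasts (`difference_samples()`) are formed
within iteration on the pooled chains — never across shuffled draws — to
preserve the joint posterior correlation; `proportion_exceeding()` uses a
strict inequality. Chains are pooled before computing exceedance
proportions.

Model comparison uses Spiegelhalter's DIC with the plug-in deviance
evaluated at the posterior mean of `theta` (the likelihood depends on the
parameters only through `theta`, so this is the theta-focused conditional
deviance, the same focus a JAGS deviance monitor uses). Other penalty
variants are deliberately not implemented; DIC values can therefore
differ from other software by a few units on identical data.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` draws trail lengths from a zero-truncated Poisson
(a trail is defined by at least one visit), then follows the fitted
hierarchy exactly. The `paper_like_design()` preset states the study's
world: 51/36/31 trails in CT/MMT/MFT, mean trail lengths fixed so the
expected visit totals are 442/189/182, and generating values
`mu = (0.11, 0.07, 0.17)`, `kappa = (24.53, 13.34, 17.72)` — the
best-model posterior means. Per-trail length *distributions* were never
published, only totals, so the zero-truncated Poisson is a modelling
choice; an empirical length list can be supplied instead by building a
custom design. The generator fills the taxon column with the dominant
visitor (honeybee) by default; taxon is carried as metadata, not a model
covariate. It does not emulate spatial patch structure, within-trail
sequence order, or community context (competing rewarding species).

Consequently, a green parameter-recovery test establishes that the
sampler recovers the generating hierarchy at the study's sample sizes —
it does **not** establish that the field data satisfied the hierarchy,
nor reproduce the published posterior tables, which would require the
unpublished trail-level counts.

## Numerical choices

* All densities are evaluated in log space; states outside the support
  return `-Inf` rather than being clamped.
* Initial states: empirical proportions `(z + 0.5)/(n + 1)` for `theta`,
  pooled treatment shares (clamped to [0.02, 0.98]) for `mu`, prior means
  for `kappa` and the hypers.
* The HDI tie-break (lowest start index) makes the sample HDI a
  deterministic function of the draws.
* A constant chain's effective sample size is defined as the total draw
  count (there is no autocorrelation structure to discount); this is a
  documented convention, not an estimate.
* Degenerate frequentist inputs fail loudly (zero variance everywhere in
  an ANOVA is an error), except the two-sample t test of two identical
  constant samples, which returns `t = 0, p = 1`.
* The companion ANOVA treats per-plant fruit set (fruits/flowers marked)
  as the unit, matching a 3 × 10-plant design's (2, 27) degrees of
  freedom; the t test defaults to the pooled (Student) form, consistent
  with the published df rule; Welch is a flag.
* The chi-square routine is exposed generically (observed counts vs
  expected proportions); the published sex-ratio test's df = 9 likely
  arises from 10 patches as cells, but per-patch counts are unpublished,
  so no acceptance claim is tied to that construction.

## Design choices where the design was open

* **Shared-kappa prior in A1.** The fixed Gamma(1.0, 0.1) prior is stated
  only for the per-treatment concentrations; A1's single shared `kappa`
  reuses it, since no other prior is given and the families are presented
  side by side.
* **Run-length scaling in tests.** The acceptance-grade recovery
  experiment keeps the stated 10,000/2,000 iterations and 50 replicates
  but uses 2 chains per fit; chain count is not part of the stated
  protocol and the coverage target concerns the HDI, not between-chain
  diagnostics.
* **Serialization.** Specs and designs round-trip through JSON.
* **Exit codes.** The CLI returns 0 on success, 2 on validation errors,
  and 3 when `--strict` escalates a convergence warning.

## Known limitations

* Family B's concentration posteriors are hyperprior-bound sensitive
  (see above); report the bounds with any family-B fit.
* DIC is the only model-selection criterion; WAIC/LOO are out of scope.
* The sampler is single-machine, pure R; a study-protocol fit of family
  B takes a few minutes, and no parallelisation is attempted.
* Sequence order within trails is discarded by design; questions about
  within-trail learning cannot be asked of this likelihood.
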