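# mimicbayes

Hierarchical Bayesian analysis of insect visitation in floral
self-mimicry pollination systems.

## The problem

In monoecious plants whose rewardless female flowers mimic the rewarding
male flowers of the same individual, pollination of the females depends
on insects being *duped*. Field experiments manipulate the male:female
sex ratio (an even 1:1 control plus male- and female-biased arrays) and
record each insect's visit sequence as a *trail*, reduced to the number
of female-flower visits `z` out of `n` total visits. `mimicbayes` is for
pollination ecologists and biostatisticians who want to ask, with full
uncertainty accounting, whether the mimic:model ratio changes how often
insects are duped.

## The model

For insect *j* in treatment *e*:

```
z_je ~ Binomial(n_je, theta_je)
theta_je ~ Beta(mu_e * kappa_(e), (1 - mu_e) * kappa_(e))
mu_e ~ Beta(a_mu, b_mu)
```

`theta_je` is the insect's duping probability, `mu_e` the treatment mean
(`1 - mu_e` = the group's discrimination ability), and `kappa` the
concentration of insects around that mean. Three families differ in the
concentration structure — **A1** (one shared `kappa`), **A2**
(independent `kappa_e` per treatment, each `~ Gamma(1.0, 0.1)`, i.e.
mean 10, SD 10), **B** (`kappa_e` drawn from an overarching Gamma whose
mean/SD get uniform hyperpriors) — crossed with two priors on `mu_e`:
**C1**, the informative `Beta(4, 1)` elicited from `m = 0.80`, `n = 5`
(`a = mn`, `b = (1 - m)n`), and **C2**, the flat `Beta(1, 1)`.

Inference is by a custom Metropolis-within-Gibbs sampler (exact conjugate
draws for every `theta_je`; adaptive logit/log random-walk updates for
the group parameters, adaptation confined to burn-in), with Gelman–Rubin
and effective-sample-size diagnostics, 95% highest-density-interval
summaries, within-iteration posterior differences, and DIC model
comparison. A synthetic trail generator reproduces the study design for
parameter-recovery experiments, and companion frequentist routines
(one-way ANOVA, Tukey HSD, two-sample t, chi-square goodness of fit)
cover fruit-set and fruit-weight analyses.

## Worked example

```r
library(mimicbayes)

# a study-scale synthetic dataset: 51/36/31 trails in CT/MMT/MFT
d <- simulate_dataset(paper_like_design(), seed = 42)
dataset_summary(d)
#>   treatment n_trails total_visits female_visits female_share
#> 1        CT       51          490            48   0.09795918
#> 2       MMT       36          164             7   0.04268293
#> 3       MFT       31          172            29   0.16860465

fit <- run_mcmc(model_spec("A2", "C2"), d,
                mcmc_config(n_chains = 4, n_iter = 20000, burn_in = 5000,
                            master_seed = 1))
summarize_chains(fit)[, c("param", "mean", "hdi_lower", "hdi_upper")]
#>        param        mean   hdi_lower   hdi_upper
#> 1     mu[CT]  0.10528498  0.07531388  0.13601824
#> 2    mu[MMT]  0.05559277  0.01976325  0.09536624
#> 3    mu[MFT]  0.16880485  0.10385508  0.23807288
#> 4  kappa[CT] 32.09439721 10.06106933 60.54599515
#> 5 kappa[MMT] 18.67189308  1.59606958 41.93565246
#> 6 kappa[MFT] 12.94247991  1.80631308 30.42807964

dic(fit, d)
#> DIC = 230.70  (Dbar = 205.81, Dhat = 180.93, pD = 24.88)

dd <- difference_samples(fit, "mu[MFT]", "mu[CT]")
c(mean = mean(dd), p_above_zero = proportion_exceeding(dd, 0))
#>         mean p_above_zero
#>        0.064        0.961
```

Reading: even in the female-biased array, insects visit female flowers
on fewer than ~17% of visits — they discriminate against the mimics
regardless of sex ratio. The `mu[MFT] - mu[CT]` posterior mean of 0.064
with 96% of its mass above zero says the female-biased array raises the
duping rate slightly, but its 95% HDI still brushes zero. `kappa` means
well above the prior mean of 10 indicate insects behave similarly within
each treatment (strong shrinkage of individual `theta_je` toward
`mu_e`).

## Command line

```sh
Rscript inst/cli/mimicbayes.R simulate --out sim --seed 42
Rscript inst/cli/mimicbayes.R fit --trails sim/trails.csv --out fit_a2 --family A2 --prior C2
Rscript inst/cli/mimicbayes.R compare --fits fit_a2,fit_b
Rscript inst/cli/mimicbayes.R recover --out recov --replicates 50
Rscript inst/cli/mimicbayes.R repro-stats --fruit inst/extdata/synthetic_fruit_set.csv --out repro
```

Every output directory gets a `manifest.json` (inputs, seeds, versions)
sufficient to re-run the command. Exit codes: 0 success, 2 validation
error, 3 convergence warning under `--strict`.

## Files

* `R/` — implementation; `tests/testthat/` — unit, property and
  acceptance tests; `vignettes/hierarchical-mimicry-model.Rmd` — model,
  assumptions, numerical choices and limitations.
* `inst/extdata/` — small plain-text fixtures; files prefixed
  `synthetic_` are constructed stand-ins, not field data.
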