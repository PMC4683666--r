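---
title: "Mapping the genetic components of heterosis in partial NCII designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the genetic components of heterosis in partial NCII designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nciimap)
```

## The design and the four dependent variables

A North Carolina II (NCII) mating design crosses `a` maternal with `b`
paternal inbred lines; a *partial* design evaluates only a subset of the
factorial, which is how hybrid breeding programmes actually operate (each
sterile line crossed with a couple of restorers). `partial_ncii(a, b, t,
extra)` builds the rotation schedule in which maternal line *i* meets
paternal lines *i, ..., i+t-1* (wrapped), plus `extra` padding crosses.
The published rosters for one maternal line crossed with 1, 2, 3, 4, 5, 6,
7 and 15 paternal lines are reproduced by
`(a, t, extra) = (80,1,0), (60,2,0), (48,3,0), (40,4,0), (34,5,2),
(30,6,0), (26,7,6), (15,15,0)`; the exact identity of the padding crosses
is not recoverable from the published account, and only their count enters
any statistic, so the rotation is simply continued from maternal line 1.

Four dependent variables can be mapped. GCA is a parent's mean hybrid
performance minus the grand mean, computed over the *observed* crosses
(maternal and paternal ledgers are kept separate — the design is
asymmetric, and reciprocal crosses are distinct). SCA is the per-cross
residual after removing both GCAs. MPH is the percentage deviation of the
hybrid from its mid-parent. GCA maps onto the parental genotypes; trait,
SCA and MPH map onto the F1 genotypes. In the simulation experiments the
complete factorial is simulated so that GCA/SCA are the textbook
quantities, and the mapping population is then the stated subset. MPH is
not mean-centred before mapping; the model fits an intercept, which
absorbs the mean.

## The genetic model

Every marker is treated as a putative QTL. With dosage codings
`w = dosage - 1` and `v = [dosage == 1]` (uncorrelated at the F1 genotype
frequencies 1/4 : 1/2 : 1/4), the design holds `2m` main-effect columns
and four interaction columns (`aa`, `ad`, `da`, `dd`) per marker pair —
the element-wise products of the main columns. With two environments the
environment code (+1/-1) joins the *unpenalized* block together with the
intercept and any Q-matrix columns, and one environment-interaction copy
of every genetic effect joins the penalized block, reproducing the
published dimension accounting (901 columns for 15 markers in two
environments; 84,050 for 205 markers in one). Environment-interaction
terms are penalized exactly like the main terms. Constant columns (sample
variance below 1e-12) are flagged and excluded from estimation — in an
all-inbred population every dominance-bearing column is constant zero,
which is the structural reason why dominance and `dd` effects are
undetectable from GCA. Missing genotypes are mean-imputed per column by
default (`missing = "drop"` removes the observations instead).

## The estimator

`eblasso()` maximizes the marginal likelihood of the three-level hierarchy

* `beta_j ~ N(0, sigma_j^2)`,
* `sigma_j^2 ~ Exp(lambda)` (density `lambda exp(-lambda sigma_j^2)`),
* `lambda ~ Gamma(a_gamma, b_gamma)` (rate parameterization),

profiling out each `sigma_j^2` in closed form. For candidate `j`, with
`S_j = x_j' C_-j^{-1} x_j` and `Q_j = x_j' C_-j^{-1} y` computed on the
response residualized against the unpenalized block, the per-effect
objective `0.5[ -log(1 + s S_j) + Q_j^2 s / (1 + s S_j) ] - lambda s` has
its maximum at `s* = (u - 1)/S_j` with
`u = (-S_j + sqrt(S_j^2 + 8 lambda Q_j^2)) / (4 lambda)`; the maximum is
positive exactly when `Q_j^2 > S_j + 2 lambda`, which is the retention
criterion, and as `lambda -> 0` the update collapses to the fast
relevance-vector-machine rule `s* = (Q_j^2 - S_j)/S_j^2`. Both closed
forms are verified against a numeric maximizer in the test suite.

The inner iteration greedily applies the add / re-estimate / delete action
with the largest objective gain, using rank-one updates of the posterior
and of all candidate statistics (an exact refresh anchors every sweep, and
a pure-R reference engine cross-checks the compiled core). When
re-estimation is the best action, the in-model prior variances are brought
to stationarity by monotone Gauss-Seidel passes — every coordinate step is
an exact maximization, so the penalized marginal likelihood never
decreases within a sweep, which the tests assert.

The outer iteration re-estimates the noise variance
(`sigma_0^2 = RSS / (n - sum gamma_j)`, `gamma_j = 1 - Sigma_jj /
sigma_j^2`) and the penalty
(`lambda = (M_ret - 1 + a_gamma) / (sum sigma_j^2 + b_gamma)`, floored at
zero). Numerical choices that matter:

* **Damping.** The raw `lambda` update can oscillate between a ballooning
  model (`lambda` huge) and an empty one (`lambda` 0) when the response is
  noise-dominated and candidates are plentiful; the implementation steps
  half-way in log scale (`lambda <- sqrt(lambda * raw)`), which adapts
  across orders of magnitude in a few iterations and settles.
* **Burn-in truncation.** The first sweeps are truncated (at `30 *
  outer_it` actions) so the hyperparameters are re-estimated from a
  partial model before the permissive initial penalty can flood the model.
* **Freeze schedule.** After 25 adaptive outer iterations the
  hyperparameters are frozen and the sweep is run to exact convergence
  under the fixed values; the greedy/EM feedback loop can otherwise cycle
  indefinitely on borderline effects. The reported state is always
  consistent with the reported hyperparameters, so the retention criterion
  holds exactly on converged fits.
* **Model-size cap** at `n - 2` retained effects (the posterior t-test
  needs residual degrees of freedom).
* Convergence: inner — no add/delete and every `|delta sigma_j^2| <
  1e-6`; outer — relative changes of `sigma_0^2` and `lambda` below
  `1e-4`, with a stationarity fallback when `lambda` merely jitters at the
  percent level over five consecutive iterations.

Defaults `a_gamma = 1, b_gamma = 0.01` make the hyperprior an essentially
flat exponential on `lambda` (the update is then its maximum-likelihood
value, `M_ret / sum sigma_j^2`, starting from `lambda = a_gamma / b_gamma
= 100`): sparse behaviour in the `M >> n` regime without committing to an
informative prior. `cv_eblasso()` chooses `(a_gamma, b_gamma)` by k-fold
cross-validated prediction error over the standard grid (ties toward
larger `b_gamma`, then larger `a_gamma`), which is how the hyperprior is
meant to be set on real data.

Retained effects are tested with `t_j = mu_j / sqrt(Sigma_jj)` against a t
distribution. The residual degrees of freedom, `n - retained -
unpenalized`, are a design choice (no published prescription exists);
`alpha = 0.05`, unadjusted, declares significance.

## The synthetic-data generator

`simulate_parents()` draws each inbred parent as a doubled haplotype from
a first-order Markov chain along each chromosome: the allele is retained
across an interval of `d` cM with probability `1 - 2c` and redrawn from
Bernoulli(`p`) otherwise, with `c` the Haldane fraction
`(1 - exp(-2d/100))/2`. This keeps the marginal frequency at `p` at every
marker and gives allele correlation `exp(-2d/100)` (at `p = 0.5` it is the
classic "switch with probability c" chain). F1 genotypes are deduced as
the union of the parental homozygotes.

Effect sizes are calibrated from heritabilities: `sigma_P^2 = sigma_e^2 /
(1 - sum h2)`, and each term's squared effect times the centred variance
of its coded column (in the F1 population at allele frequency 1/2) equals
`h2 sigma_P^2`. Those variances are `1/2` (additive), `1/4` (dominance),
`1/4` (`aa`, independent of linkage), `(1 - rho^2)/4` (`ad`/`da`) and
`(1 + rho^2)/4 - ((1 + rho^2)/4)^2` (`dd`), with `rho = exp(-2d/100)` the
parental allele correlation of a linked pair. Dominance-degree presets
(`d/a` = 0.5, 1, 2) calibrate `a` and `d` jointly. The baseline mean and
residual variance are not part of the published account; the defaults
`mu = 100`, `sigma_e^2 = 1` are fixed and documented because MPH is a
percentage of the mid-parent and therefore scale-dependent (power results
are invariant to `mu`; doubling `mu` halves every |MPH|). Where the six
QTL pairs take heritabilities "two each at 0.05, 0.10, 0.15", the listed
pair order receives 0.05, 0.05, 0.10, 0.10, 0.15, 0.15.

The generator emulates inbred parents, partial cross sets, biallelic
SSR-like markers on a cM map and an optional second environment. It does
not emulate genotyping error, multi-allelic markers, segregation
distortion, or heterozygous parents — passing tests say nothing about
those features of real data.

## The Monte Carlo experiments

`run_power_study()` counts, over replicates, how often the *true* effect
term (correct type, correct marker or pair) is significant; a relaxed
tally (correct type within 10 cM) is reported alongside because the
published attribution rule is unstated. `run_mph_ranking()` simulates the
complete factorial plus parents under nine architectures and reports mean
|MPH|. `run_proportion_study()` maps parents and F1s together, as the
published mating-proportion experiment does. All drivers spawn
per-replicate seeds deterministically from one master seed. The package's
own checks run the power studies at 100 replicates and the ranking at 10
replicates of the 14,400-hybrid factorial — sizes at which the binomial
error of a power estimate is about 3 percentage points.

## Known limitations

* Under the calibration above, the mean |MPH| ranking comes out
  dominance > over-dominance > dd > complete dominance > partial
  dominance: at equal heritability the `dd` predictor (`v_k v_s`,
  centred variance 3/16) cannot shift the hybrid mean more than an
  over-dominant locus does. Published accounts that place `dd` above
  over-dominance evidently used a larger `dd` effect scale; since the
  epistatic calibration convention is not stated there, this package
  keeps the variance-partition rule throughout and treats only the
  dominance-degree part of the ranking as reproducible.
* The LD score regression reports whatever OLS gives — the association
  statistic is the Armitage trend form `n r^2`, a choice, since the
  statistic behind the published intercepts is unstated.
* Exactly two environments are supported (the +1/-1 coding matches the
  published dimension accounting); more require a different coding and
  are out of scope.
* GCA/SCA require every parent to appear in at least one cross; SCA is
  rejected for designs in which no parent has two crosses.
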