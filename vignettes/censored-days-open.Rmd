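---
title: "Genetic evaluation of days open under right-censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of days open under right-censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Days open (DO) — the interval in days from a calving to the subsequent
conception — is the fertility trait most directly tied to the economics of a
dairy herd. Its field records are messy in a specific way: at the moment a
dataset is extracted, a fraction of cows has calved but has no confirmed
subsequent conception. For those records the true DO is only known to exceed
the days accumulated so far; they are right-censored. Deleting them is the
simplest treatment but discards exactly the cows with the longest intervals,
which can bias a genetic evaluation; `daysopen` implements that deletion and
two imputation-based alternatives so the three can be compared on equal
footing.

# The model

All three treatments build on the repeatability animal model

$$ y = X\beta + Zu + W_{pe}\,pe + e $$

where $y$ holds the DO records across the first three parities, the fixed
effects $\beta$ are the herd–year–season contemporary group (HYS), parity,
and two linear covariates (age at calving and days in milk at first
insemination), $u \sim N(0, A\sigma^2_u)$ is the additive genetic effect of
every animal in the pedigree with $A$ the numerator relationship matrix,
$pe \sim N(0, I\sigma^2_{pe})$ is the permanent-environment effect repeated
across a cow's lactations, and $e \sim N(0, I\sigma^2_e)$. Heritability is
$h^2 = \sigma^2_u / (\sigma^2_u + \sigma^2_{pe} + \sigma^2_e)$ — the
denominator includes the permanent-environment component.

The three censoring treatments are:

* **LM** — fit the Gaussian model after dropping every censored record.
* **PLM** — impute each censored record as the *maximum uncensored DO in its
  HYS group plus 21 days* (one estrous cycle: a cow not yet confirmed
  pregnant is assumed to conceive given one more cycle), then fit the same
  Gaussian model on the completed data.
* **PTM** — a bivariate threshold-linear model: trait one is DO with the
  same penalty-imputed values for censored rows; trait two is the
  censorship status, modelled through a latent Gaussian liability $l$ with
  threshold 0 ($l > 0$ exactly when the record is censored). Both traits
  share the fixed-effect structure and carry additive and
  permanent-environment effects with unstructured $2\times2$ covariance
  matrices, so the genetic association between DO and the probability of
  being censored is estimated rather than ignored.

# Pedigree algebra

`read_pedigree()` renumbers animals densely in topological order using an
iterative Kahn sort (no recursion, so pedigree depth is unbounded), treats
unknown parents as unrelated non-inbred base animals, and rejects duplicate
ids and cycles. Inbreeding coefficients come from the Meuwissen–Luo
path-tracing algorithm; `build_A()` offers the dense tabular matrix as a
debugging and oracle path (guarded at 5,000 animals), while all model
fitting uses the sparse inverse from Henderson's rules with the
inbreeding-adjusted Mendelian-sampling variances
$d_i = 0.5 - 0.25(F_s + F_d)$.

# Data editing

`edit_records()` applies, in a fixed documented order: parity 1–3; missing
calving dates and duplicated (cow, calving date) rows; removal of cows
calving first before 530 days of age; covariate outliers beyond mean + 3 SD;
uncensored DO below 20 days; uncensored DO outside mean ± 3 SD within
parity; and finally removal of HYS groups with fewer than three records.
Each rule reports its removal count in a ledger so order effects are
auditable. Two choices deserve comment:

* Outlier thresholds are computed *once* on the data entering each step and
  returned in the result; re-editing with those frozen statistics is exactly
  idempotent. Recomputing them iteratively would shrink the thresholds on
  every pass.
* Censored records are exempt from both DO filters: their value is a lower
  bound, not an observation, and the censoring models re-impute it. They do
  count toward HYS group sizes (they need a group maximum for the penalty).
* The source data dialect has no abortion-date field, so the
  duplicate-date rule is implemented as dropping duplicated
  (cow, calving date) rows.

# Gibbs samplers

Both samplers use single-site updates of all location effects in C++,
followed by variance-component draws:

* Gaussian model: scaled inverse chi-square full conditionals with prior
  $(\nu, S)$ per component. The defaults $\nu = -2, S = 0$ are flat on the
  variances, the common default in animal-breeding software; they are
  configurable through `variance_priors()`.
* PTM: the liability of every record is redrawn each iteration from its
  truncated-normal full conditional (bulk draws by rejection, tail draws by
  a translated-exponential scheme that is stable for arbitrarily extreme
  means). Genetic and permanent-environment $2\times2$ covariance matrices
  are drawn from inverse-Wishart full conditionals (flat prior,
  $\nu_0 = -3$). The residual covariance is parameterized as
  $e_{DO} = b\,e_l + \varepsilon$ with $\mathrm{var}(e_l) = 1$ fixed — the
  standard threshold-model identifiability constraint — and $b$,
  $\mathrm{var}(\varepsilon)$ sampled by conjugate updates; this is
  equivalent to sampling the constrained residual matrix directly.
* The penalty-imputed DO values of censored records are held fixed by
  default (they are *calculated* values, identical to PLM's); setting
  `resample_censored = TRUE` in `fit_ptm()` instead redraws them from a
  normal truncated above the recorded lower bound.

Starting values are a 20/20/60 split of the phenotypic variance; fixed
effects start at zero. A numerical floor keeps the variance ratios finite
when a component chain visits values near zero. Degenerate inputs fail
loudly: a burn-in at or above the iteration count, a PTM without both
censored and uncensored records, or a divergent (non-finite) variance all
raise errors rather than producing silent nonsense.

The central correctness property is that with variances held fixed the
sampler's stationary distribution is centred exactly on the solutions of
Henderson's mixed-model equations; `solve_mme()` provides that deterministic
reference, and the test suite asserts the equivalence through the
Monte-Carlo-error-scaled difference per effect. Because that per-effect
z-statistic is itself standard normal under exactness, the suite applies the
joint form of the check (tail fraction, gross-error cap, and mean squared z)
rather than a strict maximum that a perfect sampler would fail with
appreciable probability across hundreds of effects.

Convergence diagnostics follow single-chain practice: `geweke_z()` compares
early and late chain segments with AR-model spectral variance estimates,
`autocorrelation()` informs the thinning choice, and `plot()` gives trace
plots. Multi-chain statistics (R-hat) are deliberately out of scope — a
documented limitation, as all fits use one chain.

Chains default to 20,000 iterations, 4,000 burn-in, thinning 10. These
desk-scale settings keep roughly 1,600 draws and let a full three-model
evaluation run in minutes on the bundled synthetic data; production-scale
settings (say 500,000/100,000/50) are reached by passing a different
`chain_config()`.

# LR-method validation

`lr_validate()` compares whole-data and partial-data evaluations over a
validation set of phenotyped cows born in 2020 or later (about the youngest
third of the default synthetic population):

* accuracy
  $\widehat{ACC}_{LR} = \sqrt{\mathrm{cov}(\hat u_w, \hat u_p) /
  ((1-\bar F)\sigma^2_a)}$ — the square root follows the LR method's
  definition; since typography of the published ratio is ambiguous in parts
  of the literature, the unrooted variant is exposed as `acc_lr_squared()`;
* bias $\overline{\hat u_p} - \overline{\hat u_w}$ (days);
* dispersion, the slope of $\hat u_w$ on $\hat u_p$;
* Spearman rank correlations and the percentage of common animals in the
  top 20%, computed on the whole-data EBVs of the validation animals. For
  DO a *smaller* EBV is favourable, so the top of the list is the smallest
  values (flip with `lower_is_better = FALSE`).

$\sigma^2_a$ is each model's own posterior-mean genetic variance, and
$\bar F$ is the mean inbreeding of the validation animals. Top-list size is
`ceiling(fraction * n)` with boundary ties broken by animal id, so results
are deterministic.

# The synthetic generator

No public dataset accompanies this class of evaluation, so
`simulate_dataset()` generates populations with known ground truth. The
defaults describe the conditions the package is designed around: ~2,500
pedigree animals in non-overlapping generations, ~1,450 cows with 1–3
lactations (about 2,100 records) in four herds with 2017–2023 calvings,
true components (437.64, 705.76, 11932.0) days², i.e. $h^2 = 0.0335$, HYS
effects with SD 30 days, parity effects (0, 1, 4) days, covariate slopes
0.005 (age) and 0.8 (days to first AI), and a 14.51% censoring target.
Breeding values descend the pedigree with Mendelian-sampling variance
$d_i\,\sigma^2_u$ shrunk by parental inbreeding.

Three censoring mechanisms are available. The default, `value_dependent`,
censors records above the within-HYS 85th percentile of latent DO with a
four-fold elevated probability calibrated to the target rate — mirroring
real right-censoring, where the cows with the longest intervals are the
ones not yet confirmed pregnant at extraction. `random` censors
independently of everything (useful to isolate treatment effects), and
`liability_correlated` drives censorship through a second breeding-value
vector with configurable genetic correlation to DO, matching the PTM's
generative assumption. Censored records carry a uniformly drawn fraction
(35–90%) of their latent DO as the accumulated lower bound.

What the generator does *not* emulate: insemination-event sequences, heat
detection, seasonal fertility physiology, or the bookkeeping consistency
between a dam's calving dates and her progeny's birth dates. Latent DO is
Gaussian given the effects and floored at 20 days, so roughly a tenth of
records sit at the floor — a heavier lower tail than field data show; an
optional log-normal residual provides a right-skewed stress test instead.
Passing recovery tests on these data therefore demonstrates correctness of
the estimation machinery under the model's own assumptions, not robustness
to every pathology of field recording.

# Problem sizes and tolerances in the test suite

The suite fits desk-scale models so a full run stays in the minutes range:
parameter recovery uses 20 replicates of the default population with
20,000-iteration chains (95% posterior intervals for $h^2$ cover the truth
in at least 17 of 20); sampler-vs-BLUP equivalence uses three systems of
40–80 founders with 24,000 iterations; the truncated-normal moment check
uses $10^5$ draws against the half-normal mean $-\sqrt{2/\pi}$; Geweke
calibration uses 200 iid chains of length 1,500. Matrix identities
($A A^{-1} = I$) are asserted to $10^{-8}$ on pedigrees up to 200 animals.

# Worked example

```{r, eval = FALSE}
library(daysopen)

sim <- simulate_dataset(sim_config(seed = 11))
edited <- edit_records(sim$records)

fits <- fit_models(edited$records, sim$pedigree,
                   models = c("LM", "PLM", "PTM"),
                   config = chain_config(seed = 7))
fits$PLM            # posterior means and SDs of the variance components

report <- lr_validate(edited$records, sim$pedigree,
                      config = chain_config(seed = 7))
report              # accuracy / bias / dispersion and rank agreement
```

# Known limitations

* Single-chain inference only, as discussed above.
* The PTM holds penalty-imputed values fixed by default; full data
  augmentation of the censored DO is available but slower to mix.
* The LR accuracy is undefined (returned as `NaN` with a warning) when the
  whole/partial EBV covariance is negative, which happens on very
  low-information validation sets.
* Editing assumes ISO-8601 dates and refuses anything else by design.
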