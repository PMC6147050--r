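---
title: "Multilevel multinomial behaviour models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel multinomial behaviour models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmbm)
```

## The scientific problem

Behavioural observation of social groups by instantaneous scan sampling
produces long sequences of categorical records: every few minutes, each
individual is scored as doing one of a small set of behaviours. A recurring
question for cooperatively breeding species is whether nonreproductive
helpers *specialize*: does an individual that does a lot of one cooperative
task (say, work/digging) systematically do less of another (food carrying,
nest building), as in insect castes, or do helpers simply vary in overall
helpfulness? The observable signature of specialization is a *negative
within-individual correlation* between cooperative behaviours, after
accounting for age, body mass and group context.

This package implements that analysis chain for six-category scan data
(active nonhelping, eating, food carrying, nest building, resting, working)
of nonreproductive individuals: covariate construction, three nested
Bayesian multinomial models per sex, WAIC comparison, random-effect
correlation summaries with a credible-interval significance rule, fixed-
effects predicted-probability curves, and posterior contrasts for pup
presence. A synthetic-data generator emulating a captive Damaraland
mole-rat study design (35 groups, 60 nonreproductive females and 56 males,
10 twelve-hour scans per individual at 4-minute intervals, i.e. 180 events
per scan) makes every stage testable without any field data.

## The model

Each sampling event is a draw from a six-category multinomial. With resting
as the reference category, the linear predictor of non-reference category
$k$ for an event of individual $i$ in scan $s$ is

$$\eta_k = \alpha_k + \mathbf{x}'\boldsymbol\beta_k
  + u_{i,k} + v_{s,k} + w_{\ell,k} + z_{g,k}, \qquad
  \eta_{\text{rest}} \equiv 0,$$

and category probabilities follow the multinomial logit
$p_k = e^{\eta_k} / (1 + \sum_{k'} e^{\eta_{k'}})$, evaluated with
log-sum-exp throughout. The three variants are nested:

* **Model 1**: intercepts + correlated individual-level random effects
  only. Its 5x5 individual-level correlation matrix is the object of the
  specialization test.
* **Model 2**: adds the fixed covariates (age as a 1st-3rd order
  polynomial, group size as a 1st-2nd order polynomial, pup presence,
  relative mass).
* **Model 3**: adds random effects at the scan, litter and group level;
  it refines the fixed effects but changes the meaning of the individual
  level, so the specialization test is read from Models 1-2.

Sexes are always fitted separately; no pooled model with a sex covariate is
offered.

Random effects at every correlated level use the noncentred Cholesky
parameterization $u = \mathrm{diag}(\sigma) L \zeta$ with
$\zeta \sim N(0, I)$ and $LL'$ the correlation matrix, which is both the
reported quantity (correlations are taken directly from the draw-wise
matrices) and the geometry the sampler works in. $L$ itself is parameterized
by canonical partial correlations (tanh of unconstrained values), so every
draw is exactly unit-diagonal and positive semi-definite.

### Priors

The priors are weakly informative on the scale of z-scored covariates:
intercepts $N(0,5)$, slopes $N(0,2)$, random-effect SDs
$\mathrm{Exponential}(1)$, correlation matrices $\mathrm{LKJ}(2)$. All four
are configurable through `prior_config()` and are recorded in the fit. A
prior-only check (cells with zero observed events) is part of the test
suite: the sampler then reproduces these marginals to Kolmogorov-Smirnov
accuracy.

### Sampling

The posterior is explored by the No-U-Turn variant of Hamiltonian Monte
Carlo implemented in the package's compiled code: analytic gradients of the
full log posterior (including the backpropagated Cholesky transform and its
Jacobian), slice-based trajectory selection, dual-averaging step-size
adaptation toward a target acceptance statistic (default 0.9 in
`mmbm_spec()`, 0.85 in the reduced test settings), and a diagonal mass
matrix estimated in a mid-warmup window. The headline settings are 3 chains
of 1000 iterations with half allocated to warmup; every fit records
split-$\hat R$ for all non-innovation parameters and the post-warmup
divergence count, and warns (rather than errors) when $\hat R > 1.05$ or
divergences occur. Events are aggregated into (individual, scan) cells of
multinomial counts before fitting, which leaves the likelihood unchanged
but makes its cost independent of the number of events per scan.

## Covariate construction

* **Age**: days between birth date and scan date. Age and group size are
  z-scored (sample SD, $n-1$) within the sex-specific dataset *before*
  taking powers, and the powers are raw powers of the z-scored value
  (`age_z2 = age_z^2`). They are not re-orthogonalized, so the linear term
  keeps its interpretation; the polynomial basis is only mildly collinear
  over the observed range.
* **Group size**: all living group members including the breeding pair
  (the generator adds 2 for the breeders). Whether breeders are counted is
  configurable in the sense that the covariate is whatever the scan table
  carries; the package documents the choice rather than hiding it.
* **Pup presence**: true when any group member is under 40 days old on the
  scan date (`derive_pups_present()`).
* **Relative mass**: the conditional residual of a sex-specific linear
  mixed model $\log(\text{mass}) = a + b\log(\text{age}) + u_{group} +
  \varepsilon$ (REML by default, via lme4), evaluated at the mass record
  nearest in time to the scan, ties resolved to the earlier record.
  *Conditional* (group effect subtracted) rather than marginal residuals
  are used because the covariate is meant to express mass relative to
  same-sex, same-age group mates; with a single group the fitter falls
  back to ordinary least squares with a warning.

All continuous covariates, including relative mass, are z-scored in the
same pass, so fixed-effect coefficients live on comparable scales and the
prediction grid maps back to original units through the recorded scaling
constants.

## The synthetic-data generator

`truth_config()` + `simulate_dataset()` generate populations and events
from a fully known truth. Design defaults emulate the captive study: 35
groups with unequal sizes (gamma-weighted multinomial allocation of 116
nonbreeders), litters nested in groups with shared birth dates, first-scan
ages near 136 days (SD 15), roughly 64-day scan spacing so last-scan ages
land near 716 days, fortnightly mass records from the log-log growth model
(defaults $a = 1.6$, $b = 0.5$, $\sigma_{group} = 0.1$,
$\sigma_{resid} = 0.05$, giving masses growing from roughly 60 g to 140 g
over the observed ages), and pup litters arriving at mean 133-day
intervals so that roughly 30% of scans have pups present.

Events are drawn independently per sampling event given the random
effects, mirroring the model's own assumption. Real scan data are
autocorrelated within a session (a resting animal tends to still be
resting 4 minutes later); neither the model nor the generator represents
this, so passing recovery tests demonstrates correctness of the inference
machinery, not robustness to behavioural autocorrelation. Similarly the
generator holds group composition fixed (no births, deaths or dispersal)
and emulates inter-scan spacing only through its mean and SD.

Scenario presets encode the qualitative typology of helper variation as
generating truths: `no_specialization` (all pairwise individual-level
correlations +0.4, shared hump-shaped age effects — the generalist
pattern), `temporal_caste` (crossing age trajectories, independent random
effects), `permanent_caste` (work vs food carrying at $-0.8$, mild
negative correlations with nest building, chosen to keep the matrix
comfortably positive definite), and `null` (all zeros, for calibrating
the significance rule). Default random-effect SDs (0.5 individual, 0.2-0.3
for the other levels) sit in the range typically reported for this kind
of data; they are generator defaults, not empirical claims.

The scan-level random effect is drawn per (individual x scan) by default,
with a `group_scan` mode sharing one effect across all individuals
observed in the same group scan; observation protocols differ on which
grain is appropriate, so it is exposed as a switch in both the generator
and `mmbm_spec()`.

## Derived quantities

* **WAIC**: $-2(\mathrm{lppd} - p_{WAIC})$ with pointwise log-likelihood
  stored in compressed (cell x category, weighted) form; the expansion is
  exact because events in the same cell and category have identical
  likelihood contributions.
* **Correlation summaries**: posterior mean, SD and equal-tailed 95%
  credible interval per unordered pair of non-reference categories,
  significance = interval excluding zero. Equal-tailed percentile
  intervals are used throughout (95% for significance, 89% for curve
  bands); highest-density intervals would differ only for markedly skewed
  posteriors. Point estimates are means of the correlation draws taken
  directly from the draw-wise matrices — correlating per-unit median
  intercepts instead is known to inflate the values. No multiple-testing
  correction is applied across the 10 pairs.
* **Specialization verdict**: "specialization detected" iff any of the
  three cooperative pairs (work, food carrying, nest building) is
  significantly negative; "no specialization; generalist helpers" when
  all three are significantly positive.
* **Predicted-probability curves**: fixed effects only, other covariates
  at their sample mean (0 on the z-scale) and pups absent, 50 grid points
  over the observed covariate range reported on the original scale, 89%
  percentile bands.
* **Pup-presence contrast**: draw-wise difference of fixed-effects
  predicted probabilities between pups present and absent; judged by the
  contrast distribution, not by overlap of prediction intervals, which
  would import uncertainty from the other covariates.

## Numerical and design notes

* The canonical-partial-correlation transform is clamped at
  $1 - s \ge 10^{-12}$ to keep square roots finite for extreme draws.
* Divergent trajectories are flagged at an energy error of 1000 (the
  conventional threshold); step-size search and mass adaptation guard
  against non-finite joint densities.
* `select_scans()` breaks date ties by scan id, making the chronological
  extremes deterministic; the interior subsample is reproducible through
  an isolated RNG stream that leaves the caller's seed untouched.
* Equidistant mass records resolve to the earlier record, on the view
  that pre-scan mass is the better proxy for state during the scan.
* Z-scoring refuses zero-variance covariates rather than emitting NaN
  columns; a dataset with constant group size is a design problem the
  user should see immediately.
* With a single unit at some random-effect level (e.g. one litter) the
  fit proceeds with a warning that the variance is weakly identified.

## Problem sizes used in the tests

The test suite runs everything at reduced scale as the package's own
choice of simulation design: parameter recovery uses 20 replicates of 40
individuals x 400 events with 2 chains x 600 iterations (Model 2);
specialization power uses 20 replicates of 60 individuals x 1800 events
(Model 1, 2 x 500); calibration uses 4 null replicates (40 pair-tests);
the WAIC ordering check uses 10 replicates of 20 individuals with true
scan/litter/group structure, comparing Model 1 against Model 3 with the
non-individual levels collapsed to diagonal covariance (an option provided
precisely because those levels carry few units). Coverage is assessed per
parameter class (intercepts, slopes, SDs, correlations) as the fraction of
(parameter, replicate) combinations whose 95% interval covers the truth,
with a 0.9 threshold.

## Known limitations

* No temporal dependence between successive events within a scan (in
  model or generator); estimated scan-level variances absorb some of it.
* Rare behaviours are not well served by multinomial random-effect
  models; extremely rare categories (such as pup carrying in the emulated
  study, which excluded it) should be dropped or merged before modelling.
* WAIC is reported as a general indicator, not a model-selection rule;
  no cross-validation variant is provided.
* The ethogram collapse from raw observation codes onto the six modelled
  categories is user-supplied (`collapse_ethogram()`); the package checks
  surjectivity but cannot validate the biology of a mapping.
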