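---
title: "Bayesian network meta-analysis of checkpoint-inhibitor regimens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian network meta-analysis of checkpoint-inhibitor regimens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Randomized trials of immune-checkpoint-inhibitor (ICI) regimens for
advanced melanoma rarely compare the same two treatments: most randomize
a new regimen against chemotherapy or against ipilimumab. A network
meta-analysis (mixed treatment comparison) pools the whole evidence
network at once, combining direct within-trial contrasts with indirect
paths through common comparators, and yields a coherent set of pooled
effects for *every* pair of regimens plus a probabilistic ranking.

`melnma` implements that analysis end to end for the melanoma ICI
network: ten treatment strategies (chemotherapy `CHE`, ipilimumab `IPI`,
tremelimumab `TRE`, nivolumab `NIV`, pembrolizumab `PEM`, and five
ipilimumab combinations) plus the gp100 vaccine, which appears only as a
control arm and is handled as an auxiliary, non-reportable node. The
shipped evidence table (`melnma_example()`) transcribes the published
trial roster: 12 randomized trials, of which 10 report a
progression-free-survival (PFS) hazard ratio with a 95% CI.

## Models

### Contrast level (PFS / OS)

Each trial contributes its published log hazard ratios against the
trial's own reference arm. With `y_i` the observed log HR of contrast
`i` and `se_i` its standard error recovered from the CI
(`se = (log(U) - log(L)) / (2 z)`, `z` the normal quantile at the
coverage, computed rather than rounded to 1.96),

* fixed effects: `y_i ~ Normal(d[t_i] - d[b_i], se_i^2)`,
* random effects: `y_i ~ Normal(delta_i, se_i^2)` with trial effects
  `delta` drawn around the consistency contrasts with between-trial
  standard deviation `tau`; within a multi-arm trial the `delta`s share
  the standard `0.5 tau^2` correlation, implemented by sequential
  conditionals (the `j`-th contrast of a trial has conditional mean
  `d-contrast + (1/j) * sum of previous residuals` and variance
  `tau^2 (j+1) / (2j)`).

The `d[t]` are *basic parameters*: log effects of each treatment versus
the network reference (chemotherapy, the best-connected node). Every
other comparison is the difference of two basic parameters, so
consistency holds by construction, draw by draw.

One modelling caveat is inherited from the published data themselves:
the two contrasts of a three-arm trial are built from published
per-contrast CIs only, so their *observation-level* correlation (they
share the baseline arm) is unrecoverable and the likelihood treats them
as independent. The random-effects `delta`s still carry the proper
multi-arm correlation. This is a documented approximation, not a choice
we can test against the unpublished arm-level data.

### Arm level (adverse events)

Where per-arm event counts exist, a binomial likelihood is used
instead: `r_ik ~ Binomial(n_ik, p_ik)` with
`logit(p_ik) = mu_i + delta_ik`, trial baselines `mu_i` and `delta`
defined as above (zero for the baseline arm). The published paper does
not print its per-arm adverse-event counts, so this code path is
exercised and calibrated on synthetic networks only; the shipped table
carries empty count columns.

## Priors and tunable parameters

The published analysis does not state its priors, so the package uses
conventional vague mixed-treatment-comparison defaults, all adjustable
through `nma()`:

* `prior_sd_d = 15`: `d` and `mu ~ Normal(0, 15^2)` on the log scale —
  effectively flat over any plausible hazard or odds ratio.
* `prior_tau_upper`: `tau ~ Uniform(0, 2)` for log hazard ratios,
  `Uniform(0, 5)` for log odds (between-trial standard deviations on
  these scales realistically sit well below 1).
* A prior-dominance test in the suite re-fits the evidence table with
  `prior_sd_d` ten times larger and checks that league-table medians
  move by less than 0.01 on the log scale.

## Sampling

The posterior is explored by an adaptive random-walk
Metropolis-within-Gibbs sampler written in C++ (one scalar proposal per
parameter per sweep; blocks `d`, `tau`, `delta`, `mu`). Step sizes
adapt toward a 44% acceptance rate during the burn-in only and are
frozen afterwards, so the retained chain uses a fixed kernel and
detailed balance holds. The model is small (at most a few dozen
parameters), where this sampler is entirely adequate; no Hamiltonian
machinery is needed.

The default schedule mirrors the published one: 3 chains, a
10,000-iteration adaptation/burn-in phase, and 10,000 retained draws
per chain at a thinning interval of 50 (the published "30,000
iterations (10,000 per chain)" with thinning 50 is read as retained
draws, which is also what the package's own reporting invariant — at
least 500 retained draws per chain — requires). Convergence is checked
with the Gelman–Rubin potential scale reduction factor
(`PSRF = sqrt(((n-1)/n W + B/n) / W)`); any reported parameter above
1.05 flags the fit as non-converged with a warning — the fit is still
returned for inspection, never silently discarded. Identical seeds give
identical draws.

Model fit is summarized by the deviance information criterion,
`DIC = Dbar + pD` with `pD = Dbar - D(posterior mean)`. Following the
published analysis, `run_analysis()` reports the fixed-effects model
when its DIC is within 3 of (or below) the random-effects DIC, and the
random-effects model otherwise.

## Reports

* **League table** (`league_table()`): posterior median and 2.5/97.5
  percentiles of `exp(d_col - d_row)` for every ordered pair of
  reportable treatments, column-versus-row orientation (ratios below 1
  favor the column treatment). Medians are exactly antisymmetric
  because the median of a monotone transform is the transform of the
  median.
* **Rankograms** (`rank_probabilities()`): per draw, treatments are
  ordered by their `d` (direction `lower_better` for hazards and
  adverse events); the empirical rank frequencies form a doubly
  stochastic matrix. Ties — impossible for continuous posteriors, but
  reachable in degenerate tests — are broken by a seeded uniform
  permutation from the module's own tiny Lehmer generator so the global
  RNG stream is untouched. `cumulative_rank_score()` condenses a
  rankogram into a SUCRA-style score in [0, 1]. The PFS ranking covers
  the nine reportable treatments with PFS evidence (the
  ipilimumab-plus-budesonide trial reports no usable HR, and gp100 is
  auxiliary).
* **Pairwise meta-analysis** (`pairwise_all()`): classical
  inverse-variance fixed-effect and DerSimonian–Laird random-effects
  pools per direct comparison, with `Q`, `I^2` and `tau^2`; severe
  heterogeneity is flagged at `I^2 > 50%` or `p_Q < 0.10`. Multi-arm
  trials enter each comparison once, through their baseline-anchored
  contrast.
* **Consistency** (`consistency_table()`): each direct pooled estimate
  set against the corresponding network estimate with an
  interval-overlap flag and the log difference — the direct-versus-
  network comparison the published analysis used, rather than a formal
  node-splitting model.
* **Funnel diagnostics** (`funnel_points()`): each contrast centered on
  the fixed-effect direct pool of its own comparison
  (comparison-adjusted funnel), since a raw funnel across heterogeneous
  comparisons is uninterpretable. Whether the published figure centered
  its effects is unstated; the centered version is the defensible
  default, and the uncentered effects remain available as `y`.

## Arm-handling policies

Two transcription ambiguities in the evidence table are resolved by
explicit, switchable policies:

* `merge_dose_arms()`: two trials randomized two pembrolizumab dose
  groups against one control, while the network treats pembrolizumab as
  one node. The default `pool` combines the two same-baseline contrasts
  by fixed-effect inverse variance (enrolments summed); `keep_first`
  and `keep_all_as_distinct` exist for sensitivity checks.
* `resolve_auxiliary_nodes()`: the three-arm ipilimumab/gp100 trial
  anchors its contrasts on gp100 alone, a regimen outside the reported
  network. The default `aux_node` keeps gp100 as a likelihood-only node,
  preserving the trial's within-trial randomization;
  `rebase_independent` differences the two contrasts instead (treating
  them as independent, which overstates the variance slightly) and
  drops the arm.

The sensitivity analysis (`filter_low_risk()`) restricts to trials
flagged low-risk-of-bias. The publication states that three trials
showed masking bias without naming them; the shipped flag file is
therefore a synthetic stand-in (named accordingly) that flags the three
open-label chemotherapy-comparator trials. A restriction that
disconnects the network is an error naming the separated components,
never a silent fit.

## Synthetic data and calibration

`sim_truth()` fixes a ground truth: treatments, true basic parameters,
between-trial sd, and a trial layout whose default geometry mirrors the
real network (a chemotherapy hub with two-arm spokes, an ipilimumab
hub, one three-arm loop; contrast standard errors 0.11–0.28 and arm
sizes 47–556, the ranges observed in the real table; baseline
adverse-event log odds `Normal(-1, 0.5^2)`, i.e. event rates around
27%). `simulate_contrast_network()` draws trial effects with the
`0.5 tau^2` multi-arm correlation and observed contrasts around them;
`simulate_ae_network()` draws binomial arm counts. One root seed spawns
an independent sub-seed per replicate, so any replicate is reproducible
in isolation.

`recovery_report()` wraps the calibration loop: at the package's test
sizes (200 contrast-level and 50 arm-level replicates, each fitted with
2 chains × 1,500 retained draws after a 3,000-iteration burn-in,
thinning 3), per-parameter 95% credible-interval coverage lands inside
[91%, 98%] and bias is indistinguishable from zero at two Monte-Carlo
standard errors. What the generator does *not* emulate — censoring
patterns, non-proportional hazards, dose heterogeneity within a node,
correlated published contrasts — bounds what these calibrations can
say about real data: they validate the estimation machinery under the
model's own assumptions, not the assumptions themselves.

## Numerical choices and degenerate inputs

* `z`-quantiles are computed from `qnorm` at the stated coverage, never
  hard-coded.
* `tau` proposals outside the uniform prior support score `-Inf` and
  are rejected; they are not errors.
* Constant identical chains give `PSRF = 1` by convention (the `W = 0`
  limit).
* A continuity correction of 0.5 is added to all four cells of an
  adverse-event 2×2 table only when a zero cell exists
  (Haldane–Anscombe); `correction = 0` rejects degenerate tables.
* Median-based hazard-ratio reconstruction
  (`hr_from_medians`, exponential-survival approximation) returns a
  point estimate only — no variance is recoverable from two medians —
  and is never fed to the likelihood unless the caller attaches a
  standard error.
* Rows of the evidence table with a missing hazard ratio contribute
  arms (enrolment, any adverse-event counts) but no contrast; the
  reference arm is the row with `hr = 1` and no CI.

## Known limitations

* The published analysis's own league table is not perfectly internally
  consistent (its combination-versus-nivolumab entry differs from the
  ratio of its other printed entries by ~15%); a consistency model
  cannot reproduce mutually incompatible numbers, and the package's
  estimate for that single comparison tracks the direct trial evidence
  instead.
* Observation-level correlation of multi-arm contrasts is ignored (see
  above).
* Overall-survival and adverse-event inputs are not printed in the
  publication, so those pipelines are validated on synthetic data only.
* The sampler is single-site Metropolis: adequate here, but it would
  mix poorly on models with hundreds of parameters or near-degenerate
  posteriors (e.g. a random-effects model with `tau` forced to ~0).
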