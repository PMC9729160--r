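---
title: "Methods: censoring-aware horizon prediction from islet autoantibody levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censoring-aware horizon prediction from islet autoantibody levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The estimation problem

`iabhorizon` predicts whether a seroconverted child will be diagnosed with
type 1 diabetes within a fixed follow-up period $T$ (years) after a
prediction start time $t_0$, from islet autoantibody (IAb) measurements —
IAA, GADA and IA-2A levels in multiples of the upper limit of normal (mULN),
log-transformed — plus optional baseline covariates. The difficulty is
right-censoring: children who leave observation event-free before $t_0 + T$
have an unknown horizon outcome. Discarding them biases the model towards
fast progressors; keeping them as non-events biases it the other way. The
package uses inverse probability of censoring weighting (IPCW) throughout,
both for fitting (weighted logistic regression) and for evaluation (the
IPCW concordance index).

## Outcome construction

For each child, $X$ is the time from $t_0$ to $\min(\text{diagnosis},
\text{last contact})$ and $\delta$ the diagnosis indicator. The follow-up
window is the half-open interval $(t_0, t_0 + T]$:

* diagnosis at or before $t_0$: the child is **excluded** (the strict
  "diagnosed before time 0" rule; the boundary case
  $\text{diagnosis} = t_0$ is treated as excluded);
* last contact before $t_0$ without diagnosis: **excluded** — the child's
  state at $t_0$ is unobservable;
* diagnosis with $X \le T$: label 1 (a diagnosis exactly at $t_0 + T$
  counts as within the window);
* $X > T$ (diagnosed later, or event-free past the horizon): label 0 —
  a diagnosis after the follow-up period is "not diagnosed within $T$";
* event-free with $X \le T$: **censored**.

These conventions are fixed in `label_outcome()` and asserted by the
partition and monotonicity property tests (raising $T$ can never demote a
label-1 child).

## The censoring model and the weights

$G(t) = P(C > t)$ is estimated by the Kaplan–Meier product-limit estimator
with the roles of event and censoring reversed (`fit_censoring_km()`). Two
conventions are deliberately pinned down rather than inherited from a
library default:

* **Left limits.** An event at time $X$ is weighted by $1/G(X^-)$, the
  probability of being uncensored *just before* its own event time, so a
  censoring jump at exactly $X$ never contributes to the subject's own
  weight.
* **Ties.** When a diagnosis and a censoring occur at the same recorded
  time, the default removes the diagnosis from the risk set first
  (`ties = "diagnosis_first"`); the conventional reversed-role estimator
  (`"censoring_first"`, which matches `survival::survfit` on flipped
  indicators) is available and is used as the independent oracle in the
  test suite on tie-free data, where the two coincide.

Weights are $1/G(X^-)$ for events within the horizon, $1/G(T)$ for children
known event-free through the horizon, and 0 for censored children. Weights
are capped at `weight_cap = 20` (configurable) with a warning: when $G$
approaches zero near the horizon the uncapped weight of a single child can
dominate the fit, and a bounded-variance estimate was judged preferable to
an unbiased but unstable one. The identity $\sum_i w_i \approx n$
(the weighted sample reconstructs the uncensored cohort) is property-tested.

## Weighted logistic regression

`ipcw_glm()` maximises the weighted Bernoulli log-likelihood by iteratively
reweighted least squares, with convergence declared when no coefficient
moves more than $10^{-8}$ (at most 100 iterations). Numerical choices:

* the weighted log-likelihood is checked to be nondecreasing at every
  iteration, with step halving as a safeguard — a violated ascent aborts
  with a warning rather than silently returning a non-optimum;
* fitted probabilities are clamped away from 0/1 only inside the working
  weights ($\ge 10^{-12}$), never in the likelihood itself;
* complete separation is detected (degenerate fitted probabilities with
  runaway coefficients) and reported, not penalised away: the package
  deliberately fits the classical unregularised model because the analysis
  reports classical Wald inference;
* constant design columns (e.g. an absent factor level after subsetting)
  are dropped with a warning naming them.

**Variance estimation.** The natural first choice, the inverse of the
weighted information matrix, is *anticonservative* under IPCW: the weights
are heteroscedastic marks, and in simulations under the exactly-specified
generating model the model-based standard errors underestimated the true
sampling spread by 15–20%, giving ~90% coverage for nominal 95% intervals.
The sandwich estimator
$\hat V = I^{-1}\left(\sum_i w_i^2 s_i s_i'\right) I^{-1}$ restored
coverage to 0.955 over 1000 replicates, and is therefore the default
(`vcov_type = "robust"`); the model-based variance remains available for
comparison. This is the one place where the package's implementation
experience overrode the simpler textbook recipe.

**Coding.** Treatment (dummy) coding with fixed reference levels: data
source DIPP (the largest source), HLA risk group B (the largest group; the
highest-risk group A then appears as a positive effect), sex F. Missing HLA
is an explicit indicator level so the affected children stay in the cohort.
Ages and log-levels enter untouched — no standardisation — so that a
coefficient is per year or per log-unit and converts directly to a
fold-change odds ratio $\mathrm{OR}(n) = \exp(\beta \ln n)$
(`fold_change_or()`, exactly multiplicative by construction).

## The IPCW concordance index

`ipcw_c_index()` implements the truncated Uno-type estimator: comparable
pairs $(i, j)$ require $\delta_i = 1$, $X_i < X_j$ and $X_i < \tau$; each
pair carries weight $1/G(X_i^-)^2$; score ties count half. It equals the
classical concordance when censoring is absent and is invariant under
strictly monotone score transforms (both property-tested), and it is
verified against an exhaustive double-loop pair sum to $10^{-12}$ on
randomly generated instances. When no pair is comparable the result is `NA`
with a warning — never a silent 0.5.

## Evaluation protocol

`cross_validate()` does 10-fold cross-validation with *child-level* fold
assignment; the censoring model and the regression are fitted on the
training folds only, and the held-out fold is scored with the training
censoring model (fitting $G$ on the full data is available as an option
since either choice is defensible). The reported statistic is the mean of
the fold concordances, not a pooled-prediction concordance. Confidence
intervals are percentile bootstrap resampling *children*, never visits:
`ci = "full"` re-runs the entire cross-validation on each of $B = 1000$
resamples (the default contract), while `ci = "fold"` resamples the ten
fold values — far cheaper, flagged in the output, and used by the
experiment drivers and the acceptance script where hundreds of model
configurations are evaluated.

The three experiment drivers mirror the standard designs:
`covariate_battery()` (nine covariate sets at $T = 10$, time 0 at the
confirmatory visit), `t_sweep()` ($T = 1..15$, two models), and `tw_grid()`
($15 \times 9 = 135$ cells over follow-up period $T$ and test interval $W$,
three-log-level model at the third-test visit). For $W > 0$, time 0 moves
to $\text{confirmatory} + W$ and the features come from the visit
immediately at or before time 0 — the confirmatory visit itself when no
later visit exists (flagged `third_is_confirm` for audit); children
diagnosed or lost before the new time 0 leave the cell's cohort, which is
why cell sizes are nonincreasing in $W$ (a tested invariant).

## Seroconversion rules and their open edges

Per antibody, seroconversion is the first pair of *literally adjacent*
recorded visits both above the positivity threshold (strict mULN > 1 —
1 mULN is by construction the upper limit of *normal*), regardless of the
time gap. Where multiple antibodies confirm, the child-level anchor is the
antibody with the earliest **confirmatory** visit, with ties broken by
earliest initial visit and then the fixed order IAA, GADA, IA-2A. This
tie-break is a package decision — the source analyses do not state one —
and it is deterministic so that the whole pipeline is reproducible.
Children with no confirmed pair before diagnosis, or with a missing level
for any of the three antibodies at either anchor visit, are excluded,
mirroring the complete-measurements selection rule of the motivating study.
A positive–missing–positive sequence does not count as consecutive.

Zeros are handled in the log transform by a fixed floor,
$\ln(\max(\text{mULN}, 0.01))$: the transform must be defined at 0 and the
floor value is configuration, not code.

# The synthetic cohort generator

The motivating consortium data are access-restricted, so validation runs on
synthetic cohorts (`generate_cohort()`) built to have the statistical
structure the analysis assumes — not to be immunologically realistic.

**Longitudinal mode** (the default) emulates the published cohort's
marginals: ~1400–1500 seroconverted children, source mix
(BABYDIAB/DAISY/DEW-IT/DiPiS/DIPP at 11/13/12/5/59%), 55.5% male, HLA
groups A–D at 24/48/13/16% with a 0.2% missing rate, seroconversion ages
lognormal (meanlog 1.45, sdlog 0.70, truncated to 0.3–23.3 y; mean ≈ 5.6,
SD ≈ 4.2), visits every 0.45 y, exponential dropout at 0.05/y, and
administrative end of observation 16 y after the initial visit — slightly
past the 15-year maximum horizon so that the $T = 15$ cell still contains
children observably event-free through the horizon. Log-mULN trajectories
are child-specific intercept + linear drift + noise, with pre-conversion
levels centred below $\ln 1$; per-antibody conversion probabilities
(0.56/0.62/0.30) follow the published positivity mix, and at least one
antibody converts per child. Onset times are drawn from a piecewise-constant
hazard $\exp(\eta)$ between visits, with $\eta$ linear in the *current*
(most recent visit) log-levels plus the HLA effect — matching the fact that
the analysis only ever sees visit-time levels. The default coefficients
(IAA 0.50, GADA 0.30, IA-2A 0.45 per log-unit; HLA A +0.5, C −0.3, D −0.5
against B; intercept −3.65) were calibrated once, at design time, so that
the defaults reproduce the published cohort's ~37% progressor fraction and
the qualitative finding structure (baseline < positivity < levels in
cross-validated concordance; declining concordance with longer horizons;
informative post-seroconversion drift). They are configuration values, not
hidden constants.

**Logistic-direct mode** draws one feature row per child and the event
directly as $\text{Bernoulli}(\text{logit}^{-1}(\eta))$, with event times
uniform inside the horizon, event-free times past it, and independent
exponential censoring (dropout 0.05/y gives ~30% censoring at $T = 10$).
Under this mode the IPCW logistic model is *exactly* well specified, which
is what makes clean parameter-recovery and coverage testing possible: the
fitted per-log-unit coefficients must approach the generating ones, and
they do (±0.15 at $n = 5000$; 95% CI coverage 0.95 within Monte-Carlo
error over 200 replicates).

What the generator does **not** emulate — and hence what passing tests do
not establish about real cohorts: epitope spreading and affinity
maturation, assay batch effects and residual harmonisation bias,
informative (covariate-dependent) censoring, visit-schedule differences
between studies, ZnT8A, and any HLA structure below the four-group level.
Absolute concordance values on synthetic cohorts (~0.70–0.77 for
level-based models) are therefore qualitative analogues, not reproductions,
of the published values.

## Determinism and problem sizes

Every stochastic step takes an explicit integer seed, and per-task streams
are derived from it by a fixed hash, so the full pipeline —
generation, preprocessing, all three experiment drivers, bootstrap —
is byte-identical under repeated runs (`test-acceptance.R` asserts this).
The shipped tests and the acceptance script use cohorts of 150–1500
children (5000 for recovery), 200 replicates for coverage, and fold-level
bootstrap for batch evaluations; these sizes were chosen so the entire
validation runs in minutes on a single CPU while keeping Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* Censoring is modelled marginally (Kaplan–Meier); covariate-dependent
  censoring would require Cox-based weights, which are out of scope.
* The weight cap trades a small bias for bounded variance; analyses with
  very heavy late-horizon censoring should check the capped-weight warnings.
* The bootstrap treats the cross-validation split as part of the statistic;
  fold-level intervals in particular understate between-split variability.
* One instance per child and time 0: landmark super-models pooling multiple
  time 0s and time-varying-covariate hazard models are deliberately not
  implemented.
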