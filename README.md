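# iabhorizon

Censoring-aware fixed-horizon prediction of type 1 diabetes onset from islet
autoantibody (IAb) levels in seroconverted children.

## The problem

Children at genetic or familial risk of type 1 diabetes are followed in birth
cohorts with periodic blood draws measuring autoantibodies against insulin
(IAA), glutamic acid decarboxylase (GADA) and insulinoma-associated antigen-2
(IA-2A), each harmonised to multiples of the assay's upper limit of normal
(mULN; a value above 1 is a positive test). *Seroconversion* is the first
appearance of a positive result for the same antibody in two consecutive
samples — the *initial* and *confirmatory* visits. The clinical question is
how well the quantitative levels (not just the positive/negative status)
measured at and after seroconversion predict diagnosis within a fixed
follow-up period *T*, given that many children leave observation before
either converting or reaching the horizon.

`iabhorizon` is for biostatisticians and epidemiologists who want this
analysis as tested, reusable components: it implements the estimators, the
cohort-construction rules, the three standard experiment designs, and a
synthetic longitudinal cohort generator for validating the whole pipeline by
parameter recovery (the motivating consortium data are access-restricted).

## The model

The outcome is `Y = 1{diagnosis within (t0, t0 + T]}` with prediction start
time `t0` at the confirmatory visit, or at a landmark `t0 = confirmatory + W`
using the antibody levels from the visit immediately before `t0`. Children
event-free but last seen at or before `t0 + T` have unknown `Y`; they are
handled by inverse probability of censoring weighting (IPCW). With
`G(t) = P(C > t)` the Kaplan–Meier estimate of the censoring survival
function (censoring treated as the event), each subject with follow-up time
`X` gets

- an event at `X ≤ T`: weight `1 / G(X⁻)`,
- known event-free through `T` (`X > T`): weight `1 / G(T)`,
- censored inside the horizon: weight `0`,

and the weighted Bernoulli likelihood of the logistic model
`logit P(Y = 1 | x) = β'x` is maximised by iteratively reweighted least
squares (covariates `x`: natural-log levels `ln(mULN)`, positivity
indicators, and/or baseline covariates — data source, sex, family history,
HLA risk group, ages at the seroconversion visits). Standard errors are
sandwich (robust) by default, which simulation shows is required for
calibrated Wald intervals under heteroscedastic IPCW weights.

Discrimination is measured by the IPCW (Uno-type) concordance index:
comparable pairs `(i, j)` have `δᵢ = 1`, `Xᵢ < Xⱼ`, `Xᵢ < T`, weight
`1 / G(Xᵢ⁻)²`, and the index is the weighted fraction of pairs ranked
correctly by the risk score (ties count half). A per-log-unit coefficient
`β` converts to the odds ratio for an `n`-fold level increase as
`OR(n) = exp(β · ln n)`.

## Worked example

```r
library(iabhorizon)

coh <- generate_cohort(cohort_config(n_children = 800, seed = 42))
coh
#> Synthetic IAb cohort (longitudinal mode): 800 children, 15651 visits
#>   progressors: 305 (38.1%)

inst <- build_instances(coh, horizon = 10)       # time 0 = confirmatory visit
fit <- ipcw_glm(~ ln_iaa_conf + ln_gada_conf + ln_ia2a_conf, inst, horizon = 10)
summary(fit)
#> IPCW logistic regression (horizon T = 10 y, robust SEs)
#>   n = 478 (242 events), 213 censored dropped, sum(w) = 691.0; converged in 5 iter
#>              estimate      se       z p.value     OR  OR_lo  OR_hi
#> (Intercept)   -0.4019  0.1145 -3.5092   4e-04 0.6690 0.5345 0.8374
#> ln_iaa_conf    0.4606  0.0676  6.8095   0e+00 1.5851 1.3882 1.8098
#> ln_gada_conf   0.1778  0.0524  3.3948   7e-04 1.1946 1.0781 1.3238
#> ln_ia2a_conf   0.5144  0.0723  7.1109   0e+00 1.6727 1.4515 1.9275

cross_validate(inst, covariate_sets()$levels_confirm, horizon = 10,
               seed = 1, ci = "fold", B = 500)
#> Cross-validated IPCW C index (T = 10 y, 10 folds used of 10)
#>   mean C = 0.706 (95% CI 0.677, 0.736; fold bootstrap, B = 500)
#>   n = 691 instances, 242 events, 213 censored
```

Reading this: of 800 simulated children, 691 have confirmed seroconversion
and are under observation at time 0; 242 are diagnosed within 10 years, 213
are censored first (their information enters through the weights — note
`sum(w) ≈ 691` reconstructs the full cohort size). Each log-unit of IAA at
the confirmatory visit multiplies the 10-year odds of diabetes by about
1.59, and the three levels alone rank children with concordance ≈ 0.71.
A 5-fold rise in IA-2A corresponds to `fold_change_or(fit, 5)`, OR ≈ 2.3.

The three experiment drivers are `covariate_battery()` (nine covariate sets
at `T = 10`), `t_sweep()` (`T = 1..15`), and `tw_grid()` (135 `T × W` cells
using the three levels at the third-test visit; `fit_tw_cell()` exposes any
cell's coefficients). `run_cli()` wires the same steps to file-based
workflows (`simulate`, `preprocess`, `battery`, `t-sweep`, `tw-grid`,
`report`).

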