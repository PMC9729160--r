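make_eval_cohort <- function(n = 500, seed = 62) {
  generate_cohort(cohort_config(n_children = n, seed = seed))
}

test_that("cross-validation is deterministic and anchored at 0.5 for no signal", {
  coh <- make_eval_cohort()
  inst <- build_instances(coh, horizon = 10)
  # intercept-only model: constant risk score, all pairs tie
  ev0 <- cross_validate(inst, ~ 1, horizon = 10, seed = 5, ci = "none")
  expect_lt(abs(ev0$mean_c - 0.5), 0.02)
  # same seed twice: identical result
  f <- covariate_sets()$levels_confirm
  e1 <- cross_validate(inst, f, horizon = 10, seed = 9, ci = "fold", B = 50)
  e2 <- cross_validate(inst, f, horizon = 10, seed = 9, ci = "fold", B = 50)
  expect_identical(e1, e2)
  # different fold seed: different (but finite) result
  e3 <- cross_validate(inst, f, horizon = 10, seed = 10, ci = "none")
  expect_false(identical(e1$fold_c, e3$fold_c))
  expect_true(all(e1$fold_c >= 0 & e1$fold_c <= 1, na.rm = TRUE))
  expect_equal(e1$n_folds_used, 10)
  expect_output(print(e1), "mean C")
})

test_that("an informative model scores above the intercept-only anchor", {
  coh <- make_eval_cohort()
  inst <- build_instances(coh, horizon = 10)
  ev <- cross_validate(inst, covariate_sets()$levels_confirm, horizon = 10,
                       seed = 3, ci = "none")
  expect_gt(ev$mean_c, 0.6)
})

test_that("the child bootstrap brackets the exhaustive resample distribution", {
  # mean of {1, 2, 3}: all 27 equally likely child resamples enumerable
  inst <- data.frame(child_id = c("a", "b", "c"), v = c(1, 2, 3))
  stat <- function(d) mean(d$v)
  grid <- expand.grid(1:3, 1:3, 1:3)
  exact <- apply(grid, 1, function(ix) mean(c(1, 2, 3)[ix]))
  bs <- bootstrap_ci(stat, inst, B = 10000, seed = 77)
  # replicate distribution matches the 27 equally likely resamples
  for (v in unique(exact)) {
    p <- mean(exact == v)
    expect_lt(abs(mean(abs(bs$replicates - v) < 1e-12) - p),
              4 * sqrt(p * (1 - p) / length(bs$replicates)))
  }
  # percentile bounds land within one atom (1/3) of the exhaustive quantiles
  expect_lt(abs(bs$lo - quantile(exact, 0.025, type = 1)), 1/3 + 1e-9)
  expect_lt(abs(bs$hi - quantile(exact, 0.975, type = 1)), 1/3 + 1e-9)
  # constant statistic: degenerate interval at the constant
  bs0 <- bootstrap_ci(function(d) 42, inst, B = 50, seed = 1)
  expect_equal(c(bs0$lo, bs0$hi), c(42, 42))
  # determinism
  bs1 <- bootstrap_ci(stat, inst, B = 200, seed = 5)
  bs2 <- bootstrap_ci(stat, inst, B = 200, seed = 5)
  expect_identical(bs1, bs2)
  expect_error(bootstrap_ci(stat, inst, B = 0), "B")
})

test_that("bootstrap intervals tighten as the cohort grows", {
  widths <- sapply(c(200, 800, 3200), function(n) {
    withr::with_seed(n, {
      inst <- data.frame(child_id = seq_len(n), v = rnorm(n))
      bs <- bootstrap_ci(function(d) mean(d$v), inst, B = 200, seed = 3)
      bs$hi - bs$lo
    })
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the battery evaluates all nine covariate sets", {
  coh <- make_eval_cohort(600, seed = 63)
  bat <- covariate_battery(coh, horizon = 10, seed = 4, ci = "fold", B = 200)
  expect_equal(nrow(bat), 9)
  expect_equal(bat$set_id, 1:9)
  expect_true(all(bat$mean_c > 0 & bat$mean_c < 1))
  expect_true(all(bat$n == bat$n[1]))  # same cohort for every set
  # interval sanity: lo <= mean <= hi (violations would be logged upstream)
  ok <- !is.na(bat$ci_lo)
  expect_true(all(bat$ci_lo[ok] <= bat$mean_c[ok] + 1e-9))
  expect_true(all(bat$ci_hi[ok] >= bat$mean_c[ok] - 1e-9))
  # full-cohort determinism
  bat2 <- covariate_battery(coh, horizon = 10, seed = 4, ci = "fold", B = 200)
  expect_identical(bat, bat2)
})

test_that("the follow-up sweep relabels the cohort for every T", {
  coh <- make_eval_cohort(600, seed = 64)
  ts <- t_sweep(coh, T_list = c(2, 6, 12), seed = 2, ci = "none")
  expect_equal(nrow(ts), 6)  # 3 horizons x 2 models
  expect_setequal(unique(ts$set_name), c("levels_confirm", "baseline_levels_both"))
  expect_error(t_sweep(coh, T_list = 2, models = "nope"), "nope")
})

test_that("the T-by-W grid has one cell per pair with nested cohorts", {
  coh <- make_eval_cohort(600, seed = 65)
  gw <- tw_grid(coh, T_list = c(5, 10), W_list = c(0.25, 1, 3), seed = 2,
                ci = "none")
  expect_equal(nrow(gw), 6)
  for (tt in c(5, 10)) {
    ncol_t <- gw$n[gw$T == tt][order(gw$W[gw$T == tt])]
    expect_true(all(diff(ncol_t) <= 0))
  }
  m <- grid_matrix(gw)
  expect_equal(dim(m), c(3, 2))
  expect_equal(m["W=1", "T=10"], gw$mean_c[gw$T == 10 & gw$W == 1])
  # full-data cell fit exposes the three log-level coefficients
  fit <- fit_tw_cell(coh, horizon = 5, W = 1)
  expect_setequal(names(coef(fit)),
                  c("(Intercept)", "ln_iaa_t0", "ln_gada_t0", "ln_ia2a_t0"))
  ors <- fold_change_or(fit, n = c(1, 2, 5, 10))
  expect_equal(nrow(ors), 12)
  expect_true(all(ors$OR[ors$fold == 1] == 1))
})
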