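#' The nine covariate sets of the seroconversion battery
#'
#' Set 1 is the baseline model (data source, sex, diabetes family history,
#' HLA risk group, ages at initial and confirmatory visits); sets 2-4 use IAb
#' positivity indicators from the initial, confirmatory or both visits;
#' sets 5-7 use the log IAb levels instead; sets 8-9 add the baseline
#' covariates to the both-visit indicator/level sets. The extra entry
#' `levels_third` (three log-levels at the third-test visit) is the model
#' used on the follow-up-period-by-test-interval grid.
#'
#' @return Named list of one-sided formulas over [build_instances()] columns.
#' @export
covariate_sets <- function() {
  pos_i <- "pos_iaa_init + pos_gada_init + pos_ia2a_init"
  pos_c <- "pos_iaa_conf + pos_gada_conf + pos_ia2a_conf"
  lev_i <- "ln_iaa_init + ln_gada_init + ln_ia2a_init"
  lev_c <- "ln_iaa_conf + ln_gada_conf + ln_ia2a_conf"
  base <- "source + sex + family_history + hla_group + age_initial + age_confirm"
  f <- function(s) stats::as.formula(paste("~", s), env = baseenv())
  list(
    baseline = f(base),
    pos_initial = f(pos_i),
    pos_confirm = f(pos_c),
    pos_both = f(paste(pos_i, "+", pos_c)),
    levels_initial = f(lev_i),
    levels_confirm = f(lev_c),
    levels_both = f(paste(lev_i, "+", lev_c)),
    baseline_pos_both = f(paste(base, "+", pos_i, "+", pos_c)),
    baseline_levels_both = f(paste(base, "+", lev_i, "+", lev_c)),
    levels_third = f("ln_iaa_t0 + ln_gada_t0 + ln_ia2a_t0")
  )
}

#' Cross-validated IPCW concordance of one model
#'
#' Ten-fold (by default) cross-validation with child-level fold assignment.
#' In each fold the censoring model and the IPCW logistic regression are
#' fitted on the training children only; the held-out children are scored and
#' their IPCW concordance index computed with the training-fold censoring
#' model. The reported performance is the mean of the fold concordances.
#' Folds where the fit or the concordance is undefined (single outcome class,
#' no comparable pair) are skipped with a warning and recorded.
#'
#' @param instances Instance table from [build_instances()].
#' @param formula One-sided covariate formula (see [covariate_sets()]).
#' @param horizon Follow-up period `T`, years.
#' @param seed Integer seed controlling fold assignment (and the bootstrap).
#' @param k Number of folds.
#' @param ci `"full"` (default): percentile bootstrap resampling children and
#'   re-running the whole cross-validation; `"fold"`: cheap percentile
#'   bootstrap over the k fold concordances (flagged in the result);
#'   `"none"`: no interval.
#' @param B Bootstrap replicates.
#' @param weight_cap,cens_scope IPCW options; `cens_scope = "full"` fits the
#'   censoring model once on all instances instead of per training fold.
#' @return Object of class `ipcw_eval`: `fold_c`, `mean_c`, `ci_lo`, `ci_hi`,
#'   `ci_method`, `n_instances`, `n_events`, `n_folds_used`, `formula`,
#'   `horizon`, `seed`.
#' @export
cross_validate <- function(instances, formula, horizon, seed = 1L, k = 10L,
                           ci = c("full", "fold", "none"), B = 1000L,
                           weight_cap = 20, cens_scope = c("train", "full")) {
  ci <- match.arg(ci)
  cens_scope <- match.arg(cens_scope)
  point <- cv_mean_c(instances, formula, horizon, seed, k, weight_cap, cens_scope)
  lo <- hi <- NA_real_
  if (ci == "fold") {
    vals <- point$fold_c[!is.na(point$fold_c)]
    reps <- with_seed(derive_seed(seed, "foldboot"), {
      vapply(seq_len(B), function(b) {
        mean(sample(vals, length(vals), replace = TRUE))
      }, numeric(1))
    })
    qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  } else if (ci == "full") {
    bs <- bootstrap_ci(function(d) {
      cv_mean_c(d, formula, horizon, seed, k, weight_cap, cens_scope)$mean_c
    }, instances, B = B, seed = derive_seed(seed, "fullboot"))
    lo <- bs$lo; hi <- bs$hi
  }
  structure(list(fold_c = point$fold_c, mean_c = point$mean_c,
                 ci_lo = lo, ci_hi = hi, ci_method = ci, B = if (ci == "none") 0L else B,
                 n_instances = nrow(instances),
                 n_events = sum(instances$label == "event"),
                 n_censored = sum(instances$label == "censored"),
                 n_folds_used = sum(!is.na(point$fold_c)),
                 formula = formula, horizon = horizon, k = k, seed = seed),
            class = "ipcw_eval")
}

cv_mean_c <- function(instances, formula, horizon, seed, k, weight_cap,
                      cens_scope) {
  n <- nrow(instances)
  if (n < k) stop_input("need at least ", k, " instances for ", k, "-fold CV")
  children <- unique(instances$child_id)
  fold_of <- with_seed(derive_seed(seed, "folds"), {
    stats::setNames(sample(rep_len(seq_len(k), length(children))), children)
  })
  fold <- fold_of[instances$child_id]
  g_full <- if (cens_scope == "full") {
    fit_censoring_km(instances$followup_time, instances$event_observed)
  } else NULL
  fold_c <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    train <- instances[fold != f, , drop = FALSE]
    test <- instances[fold == f, , drop = FALSE]
    if (!nrow(test)) next
    fit <- tryCatch(
      suppressWarnings(ipcw_glm(formula, train, horizon = horizon,
                                cens_model = g_full, weight_cap = weight_cap)),
      error = function(e) {
        warning(sprintf("fold %d skipped: %s", f, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    scores <- tryCatch(predict(fit, test, type = "link"),
                       error = function(e) {
                         warning(sprintf("fold %d skipped at scoring: %s", f,
                                         conditionMessage(e)), call. = FALSE)
                         NULL
                       })
    if (is.null(scores)) next
    g_eval <- g_full %||% fit$cens_model
    fold_c[f] <- suppressWarnings(
      ipcw_c_index(scores, test$followup_time, test$event_observed,
                   model = g_eval, tau = horizon, cap = weight_cap))
  }
  if (all(is.na(fold_c))) {
    warning("all folds skipped: concordance undefined", call. = FALSE)
  }
  list(fold_c = fold_c, mean_c = mean(fold_c, na.rm = TRUE))
}

#' @export
print.ipcw_eval <- function(x, ...) {
  cat(sprintf("Cross-validated IPCW C index (T = %g y, %d folds used of %d)\n",
              x$horizon, x$n_folds_used, x$k))
  ci_txt <- if (x$ci_method == "none") "" else
    sprintf(" (95%% CI %.3f, %.3f; %s bootstrap, B = %d)",
            x$ci_lo, x$ci_hi, x$ci_method, x$B)
  cat(sprintf("  mean C = %.3f%s\n", x$mean_c, ci_txt))
  cat(sprintf("  n = %d instances, %d events, %d censored\n",
              x$n_instances, x$n_events, x$n_censored))
  invisible(x)
}

#' Percentile bootstrap over children
#'
#' Resamples children (never individual visits or rows within a child) with
#' replacement, recomputes the statistic on each resample and returns the
#' 2.5/97.5 percentile interval.
#'
#' @param statistic Function taking a resampled instance table and returning
#'   a scalar.
#' @param instances Instance table with a `child_id` column.
#' @param B Number of resamples, `>= 1`.
#' @param seed Integer seed.
#' @return List with `lo`, `hi` and the vector of `replicates`.
#' @export
bootstrap_ci <- function(statistic, instances, B = 1000L, seed = 1L) {
  if (B < 1) stop_input("'B' must be >= 1")
  children <- unique(instances$child_id)
  rows_of <- split(seq_len(nrow(instances)), instances$child_id)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      draw <- sample(children, length(children), replace = TRUE)
      idx <- unlist(rows_of[draw], use.names = FALSE)
      d <- instances[idx, , drop = FALSE]
      # Resampled copies of a child count as distinct children.
      d$child_id <- paste0(rep(seq_along(draw), lengths(rows_of[draw])), "#",
                           d$child_id)
      as.numeric(statistic(d))
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7,
                        na.rm = TRUE)
  list(lo = qs[1], hi = qs[2], replicates = reps)
}

#' Covariate-set battery at seroconversion
#'
#' Evaluates the nine covariate sets with time 0 at the confirmatory visit
#' and a fixed follow-up period (10 years by default), each by
#' cross-validated IPCW concordance.
#'
#' @param cohort `iab_cohort` or list with `children`/`visits`.
#' @param horizon Follow-up period, years.
#' @param seed Integer seed.
#' @param k,ci,B,weight_cap Passed to [cross_validate()].
#' @param floor Log-transform floor.
#' @return data.frame with one row per covariate set: `set_id`, `set_name`,
#'   `T`, `W`, `mean_c`, `ci_lo`, `ci_hi`, `n`, `events`, `n_folds_used`.
#'   Fold-level detail in `attr(, "evals")`.
#' @export
covariate_battery <- function(cohort, horizon = 10, seed = 1L, k = 10L,
                              ci = c("fold", "full", "none"), B = 1000L,
                              weight_cap = 20, floor = 0.01) {
  ci <- match.arg(ci)
  inst <- build_instances(cohort, horizon = horizon, W = 0, floor = floor)
  sets <- covariate_sets()[1:9]
  evals <- lapply(seq_along(sets), function(j) {
    cross_validate(inst, sets[[j]], horizon = horizon,
                   seed = derive_seed(seed, names(sets)[j]), k = k,
                   ci = ci, B = B, weight_cap = weight_cap)
  })
  out <- data.frame(
    experiment = "battery",
    set_id = seq_along(sets), set_name = names(sets),
    T = horizon, W = 0,
    mean_c = vapply(evals, `[[`, numeric(1), "mean_c"),
    ci_lo = vapply(evals, `[[`, numeric(1), "ci_lo"),
    ci_hi = vapply(evals, `[[`, numeric(1), "ci_hi"),
    n = vapply(evals, `[[`, numeric(1), "n_instances"),
    events = vapply(evals, `[[`, numeric(1), "n_events"),
    n_folds_used = vapply(evals, `[[`, numeric(1), "n_folds_used"),
    stringsAsFactors = FALSE
  )
  attr(out, "evals") <- evals
  out
}

#' Follow-up-period sweep
#'
#' Re-labels the cohort for each follow-up period `T` and evaluates, by
#' default, the confirmatory-visit levels-only model and the full model
#' (baseline covariates plus levels from both seroconversion visits).
#'
#' @param cohort `iab_cohort` or list with `children`/`visits`.
#' @param T_list Follow-up periods in years (default 1..15).
#' @param models Names into [covariate_sets()].
#' @param seed,k,ci,B,weight_cap,floor See [cross_validate()].
#' @return data.frame with one row per (model, T).
#' @export
t_sweep <- function(cohort, T_list = 1:15,
                    models = c("levels_confirm", "baseline_levels_both"),
                    seed = 1L, k = 10L, ci = c("fold", "full", "none"),
                    B = 1000L, weight_cap = 20, floor = 0.01) {
  ci <- match.arg(ci)
  sets <- covariate_sets()
  if (!all(models %in% names(sets))) {
    stop_input("unknown model name(s): ",
               paste(setdiff(models, names(sets)), collapse = ", "))
  }
  serocon <- seroconversion_records(cohort$children, cohort$visits)
  rows <- list()
  for (tt in T_list) {
    inst <- build_instances(cohort, horizon = tt, W = 0, floor = floor,
                            serocon = serocon)
    for (m in models) {
      ev <- cross_validate(inst, sets[[m]], horizon = tt,
                           seed = derive_seed(seed, paste0("T", tt, m)),
                           k = k, ci = ci, B = B, weight_cap = weight_cap)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = "t_sweep", set_name = m, T = tt, W = 0,
        mean_c = ev$mean_c, ci_lo = ev$ci_lo, ci_hi = ev$ci_hi,
        n = ev$n_instances, events = ev$n_events,
        n_folds_used = ev$n_folds_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Follow-up-period by test-interval grid
#'
#' For every pair of follow-up period `T` and test interval `W`, rebuilds the
#' cohort with time 0 at the third visit (`age_confirm + W`, features from
#' the visit immediately before) and evaluates the three-log-level model by
#' cross-validated IPCW concordance. The default grid is 15 x 9 = 135 cells.
#'
#' @param cohort `iab_cohort` or list with `children`/`visits`.
#' @param T_list Follow-up periods, years.
#' @param W_list Test intervals, years (`W = 0` is allowed and means the
#'   confirmatory visit, but the default grid starts at 0.25).
#' @param seed,k,ci,B,weight_cap,floor See [cross_validate()].
#' @return data.frame of class `tw_grid` with one row per (T, W) cell:
#'   `mean_c`, `ci_lo`, `ci_hi`, `n`, `events`, `n_folds_used`.
#' @seealso [grid_matrix()] to reshape a column into the W-by-T layout,
#'   [fit_tw_cell()] for the full-data fit of one cell.
#' @export
tw_grid <- function(cohort, T_list = 1:15,
                    W_list = c(0.25, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 5.0),
                    seed = 1L, k = 10L, ci = c("none", "fold", "full"),
                    B = 1000L, weight_cap = 20, floor = 0.01) {
  ci <- match.arg(ci)
  f <- covariate_sets()$levels_third
  serocon <- seroconversion_records(cohort$children, cohort$visits)
  rows <- list()
  for (w in W_list) {
    for (tt in T_list) {
      inst <- build_instances(cohort, horizon = tt, W = w, floor = floor,
                              serocon = serocon)
      ev <- tryCatch(
        cross_validate(inst, f, horizon = tt,
                       seed = derive_seed(seed, paste0("T", tt, "W", w)),
                       k = k, ci = ci, B = B, weight_cap = weight_cap),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = "tw_grid", set_name = "levels_third", T = tt, W = w,
        mean_c = if (is.null(ev)) NA_real_ else ev$mean_c,
        ci_lo = if (is.null(ev)) NA_real_ else ev$ci_lo,
        ci_hi = if (is.null(ev)) NA_real_ else ev$ci_hi,
        n = nrow(inst), events = sum(inst$label == "event"),
        n_folds_used = if (is.null(ev)) 0L else ev$n_folds_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tw_grid", "data.frame")
  out
}

#' Reshape a grid column into the W-by-T matrix layout
#'
#' @param grid Result of [tw_grid()].
#' @param value Column to spread (default `"mean_c"`).
#' @return Matrix with one row per `W` and one column per `T`.
#' @export
grid_matrix <- function(grid, value = "mean_c") {
  ws <- sort(unique(grid$W))
  ts <- sort(unique(grid$T))
  m <- matrix(NA_real_, length(ws), length(ts),
              dimnames = list(paste0("W=", ws), paste0("T=", ts)))
  m[cbind(match(grid$W, ws), match(grid$T, ts))] <- grid[[value]]
  m
}

#' Full-data fit of one (T, W) grid cell
#'
#' Fits the three-log-level model on all instances of one grid cell (no
#' cross-validation); used to read off coefficients and n-fold-increase odds
#' ratios for that cell.
#'
#' @param cohort `iab_cohort` or list with `children`/`visits`.
#' @param horizon Follow-up period `T`, years.
#' @param W Test interval, years.
#' @param weight_cap,floor See [ipcw_glm()].
#' @return An `ipcw_glm` fit.
#' @export
fit_tw_cell <- function(cohort, horizon, W, weight_cap = 20, floor = 0.01) {
  inst <- build_instances(cohort, horizon = horizon, W = W, floor = floor)
  ipcw_glm(covariate_sets()$levels_third, inst, horizon = horizon,
           weight_cap = weight_cap)
}
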