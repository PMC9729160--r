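#' Label the fixed-horizon outcome for one prediction start time
#'
#' Children diagnosed at or before `time0` are excluded, as are children whose
#' follow-up ended before `time0` without a diagnosis (their status at `time0`
#' is unobservable). The follow-up interval is half-open `(time0, time0 + T]`:
#' a diagnosis exactly at `time0` is excluded, exactly at `time0 + T` is an
#' event. A diagnosis after `time0 + T` counts as not diagnosed within the
#' horizon. Event-free children last seen at or before `time0 + T` are
#' censored (handled downstream by inverse-probability-of-censoring weights).
#'
#' @param diagnosis_age Diagnosis age in years, `NA` when not diagnosed.
#' @param last_followup_age Age at last contact (equals diagnosis age for
#'   diagnosed children). Vectorised with `diagnosis_age`.
#' @param time0 Prediction start age, years.
#' @param horizon Follow-up period `T` in years.
#' @return data.frame with `status` (`"excluded"`, `"event"`, `"nonevent"`,
#'   `"censored"`), `followup_time` (years from `time0` to
#'   `min(diagnosis, last contact)`; `NA` for excluded rows) and
#'   `event_observed`.
#' @export
label_outcome <- function(diagnosis_age, last_followup_age, time0, horizon) {
  check_scalar(horizon, "horizon", 0, strict_lower = TRUE)
  n <- max(length(diagnosis_age), length(last_followup_age), length(time0))
  diagnosis_age <- rep_len(diagnosis_age, n)
  last_followup_age <- rep_len(last_followup_age, n)
  time0 <- rep_len(time0, n)

  has_dx <- !is.na(diagnosis_age)
  excluded <- (has_dx & diagnosis_age <= time0) |
    (!has_dx & last_followup_age < time0)
  x <- pmin(ifelse(has_dx, diagnosis_age, Inf), last_followup_age) - time0
  status <- rep(NA_character_, n)
  status[excluded] <- "excluded"
  ok <- !excluded
  status[ok & has_dx & x <= horizon] <- "event"
  status[ok & has_dx & x > horizon] <- "nonevent"
  status[ok & !has_dx & x > horizon] <- "nonevent"
  status[ok & !has_dx & x <= horizon] <- "censored"
  data.frame(status = status,
             followup_time = ifelse(excluded, NA_real_, x),
             event_observed = ifelse(excluded, NA, has_dx),
             stringsAsFactors = FALSE)
}

#' Select the feature visit for a third-test landmark
#'
#' For a test interval `W` after the confirmatory visit, the prediction start
#' time is `time0 = age_confirm + W` and the antibody information used is the
#' latest recorded visit at or before `time0` (the confirmatory visit itself
#' when no later visit exists). Returns `NULL` when the child was diagnosed or
#' lost to follow-up before `time0` (such children leave the W-analysis
#' cohort).
#'
#' @param visits Age-ordered visits of one child.
#' @param age_confirm Child-level confirmatory-visit age, years.
#' @param W Test interval in years, `> 0`.
#' @param diagnosis_age,last_followup_age Child outcome ages (see
#'   [label_outcome()]).
#' @return One-row data.frame (the selected visit) or `NULL`.
#' @export
select_third_visit <- function(visits, age_confirm, W,
                               diagnosis_age = NA_real_,
                               last_followup_age = Inf) {
  check_scalar(W, "W", 0, strict_lower = TRUE)
  time0 <- age_confirm + W
  if (!is.na(diagnosis_age) && diagnosis_age <= time0) return(NULL)
  if (is.na(diagnosis_age) && last_followup_age < time0) return(NULL)
  cand <- visits[visits$age_years <= time0 + 1e-9 &
                   visits$age_years >= age_confirm - 1e-9, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand[which.max(cand$age_years), , drop = FALSE]
}

#' Build prediction instances for one (T, W) window
#'
#' Joins child covariates, seroconversion features and the horizon label into
#' one analysis row per retained child. For `W = 0` the prediction start time
#' is the confirmatory visit; for `W > 0` it is `age_confirm + W` and the
#' third-test features come from the visit selected by
#' [select_third_visit()]. All covariate columns for every covariate set are
#' always materialised; model formulas pick the subset to use.
#'
#' @param cohort An `iab_cohort`, or a list with `children` and `visits`.
#' @param horizon Follow-up period `T`, years.
#' @param W Test interval, years (0 = confirmatory visit).
#' @param floor Log-transform floor passed to [log_level()].
#' @param threshold Positivity threshold.
#' @param serocon Optional precomputed [seroconversion_records()] table.
#' @return data.frame with identifiers (`child_id`, `T`, `W`, `time0_age`,
#'   `third_visit_age`, `third_is_confirm`), outcome columns
#'   (`followup_time`, `event_observed`, `label`), baseline covariates,
#'   positivity indicators and log-levels at the initial/confirmatory visits
#'   (`pos_*_init`, `ln_*_conf`, ...) and at the third visit (`ln_*_t0`,
#'   `pos_*_t0`).
#' @export
build_instances <- function(cohort, horizon, W = 0, floor = 0.01,
                            threshold = 1, serocon = NULL) {
  children <- cohort$children
  visits <- cohort$visits
  check_scalar(W, "W", 0)
  if (is.null(serocon)) serocon <- seroconversion_records(children, visits, threshold)
  if (!nrow(serocon)) return(empty_instances(horizon, W))

  sc <- merge(serocon, children, by = "child_id", sort = TRUE)
  time0 <- sc$age_confirm + W
  lab <- label_outcome(sc$diagnosis_age_years, sc$last_followup_age_years,
                       time0, horizon)
  keep <- lab$status != "excluded"
  if (!any(keep)) return(empty_instances(horizon, W))
  sc <- sc[keep, , drop = FALSE]
  lab <- lab[keep, , drop = FALSE]
  time0 <- time0[keep]

  # Third-test feature visit (the confirmatory visit itself when W = 0).
  split_visits <- split(visits, visits$child_id)
  third <- lapply(seq_len(nrow(sc)), function(i) {
    vv <- split_visits[[sc$child_id[i]]]
    vv <- vv[order(vv$age_years), , drop = FALSE]
    if (!is.na(sc$diagnosis_age_years[i])) {
      vv <- vv[vv$age_years < sc$diagnosis_age_years[i], , drop = FALSE]
    }
    if (W == 0) {
      vv[match(sc$age_confirm[i], vv$age_years), , drop = FALSE]
    } else {
      select_third_visit(vv, sc$age_confirm[i], W,
                         sc$diagnosis_age_years[i],
                         sc$last_followup_age_years[i])
    }
  })
  got <- !vapply(third, function(x) is.null(x) || !nrow(x) || anyNA(x$age_years),
                 logical(1))
  sc <- sc[got, , drop = FALSE]
  lab <- lab[got, , drop = FALSE]
  time0 <- time0[got]
  third <- do.call(rbind, third[got])

  out <- data.frame(
    child_id = sc$child_id, T = horizon, W = W,
    time0_age = time0,
    third_visit_age = third$age_years,
    third_is_confirm = abs(third$age_years - sc$age_confirm) < 1e-9,
    followup_time = lab$followup_time,
    event_observed = lab$event_observed,
    label = lab$status,
    source = sc$source, sex = sc$sex,
    family_history = sc$family_history, hla_group = sc$hla_group,
    age_initial = sc$age_initial, age_confirm = sc$age_confirm,
    stringsAsFactors = FALSE
  )
  for (ab in ANTIBODIES) {
    out[[paste0("pos_", ab, "_init")]] <- sc[[paste0("pos_", ab, "_init")]]
    out[[paste0("pos_", ab, "_conf")]] <- sc[[paste0("pos_", ab, "_conf")]]
    out[[paste0("ln_", ab, "_init")]] <- log_level(sc[[paste0(ab, "_mULN_init")]], floor)
    out[[paste0("ln_", ab, "_conf")]] <- log_level(sc[[paste0(ab, "_mULN_conf")]], floor)
    out[[paste0("ln_", ab, "_t0")]] <- log_level(third[[paste0(ab, "_mULN")]], floor)
    out[[paste0("pos_", ab, "_t0")]] <- third[[paste0(ab, "_mULN")]] > threshold
  }
  rownames(out) <- NULL
  out
}

empty_instances <- function(horizon, W) {
  out <- data.frame(child_id = character(), T = numeric(), W = numeric(),
                    time0_age = numeric(), third_visit_age = numeric(),
                    third_is_confirm = logical(), followup_time = numeric(),
                    event_observed = logical(), label = character(),
                    source = character(), sex = character(),
                    family_history = logical(), hla_group = character(),
                    age_initial = numeric(), age_confirm = numeric(),
                    stringsAsFactors = FALSE)
  for (ab in ANTIBODIES) {
    out[[paste0("pos_", ab, "_init")]] <- logical()
    out[[paste0("pos_", ab, "_conf")]] <- logical()
    out[[paste0("ln_", ab, "_init")]] <- numeric()
    out[[paste0("ln_", ab, "_conf")]] <- numeric()
    out[[paste0("ln_", ab, "_t0")]] <- numeric()
    out[[paste0("pos_", ab, "_t0")]] <- logical()
  }
  out
}
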