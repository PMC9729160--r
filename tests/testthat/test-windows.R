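test_that("horizon labelling follows the half-open window conventions", {
  t0 <- 5
  # diagnosis inside the window
  expect_equal(label_outcome(t0 + 0.5, t0 + 0.5, t0, 10)$status, "event")
  # diagnosis after the window counts as not diagnosed
  expect_equal(label_outcome(t0 + 12, t0 + 12, t0, 10)$status, "nonevent")
  # event-free last contact inside the window: censored
  expect_equal(label_outcome(NA, t0 + 3, t0, 10)$status, "censored")
  # boundary rules: at time0 excluded, at time0 + T an event
  expect_equal(label_outcome(t0, t0, t0, 10)$status, "excluded")
  expect_equal(label_outcome(t0 + 10, t0 + 10, t0, 10)$status, "event")
  # unobservable at time0: excluded
  expect_equal(label_outcome(NA, t0 - 0.1, t0, 10)$status, "excluded")
  # event-free past the window
  lab <- label_outcome(NA, t0 + 10.5, t0, 10)
  expect_equal(lab$status, "nonevent")
  expect_equal(lab$followup_time, 10.5)
  expect_false(lab$event_observed)
})

test_that("every retained instance has exactly one label and T is monotone", {
  withr::local_seed(99)
  for (rep in 1:300) {
    dx_age <- ifelse(runif(1) < 0.5, NA, runif(1, 0, 20))
    lastfu <- if (is.na(dx_age)) runif(1, 0, 20) else dx_age
    t0 <- runif(1, 0, 15)
    t_small <- runif(1, 1, 8); t_big <- t_small + runif(1, 0, 8)
    a <- label_outcome(dx_age, lastfu, t0, t_small)
    b <- label_outcome(dx_age, lastfu, t0, t_big)
    expect_true(a$status %in% c("excluded", "event", "nonevent", "censored"))
    # exclusion is independent of T; labels partition the retained
    expect_equal(a$status == "excluded", b$status == "excluded")
    # raising T never demotes an event
    if (a$status == "event") expect_equal(b$status, "event")
  }
})

test_that("third-visit selection takes the visit immediately before time0", {
  v <- data.frame(age_years = c(2.0, 2.6, 3.2),
                  iaa_mULN = 1:3, gada_mULN = 1:3, ia2a_mULN = 1:3)
  # W = 1.0: time0 = 3.0, latest visit at or before is 2.6
  expect_equal(select_third_visit(v, age_confirm = 2.0, W = 1.0)$age_years, 2.6)
  # only the confirmatory visit exists
  v1 <- v[1, , drop = FALSE]
  expect_equal(select_third_visit(v1, 2.0, W = 0.25)$age_years, 2.0)
  # diagnosed before time0: child leaves the W-analysis cohort
  expect_null(select_third_visit(v, 2.0, W = 1.0, diagnosis_age = 2.5))
  # lost to follow-up before time0, event-free
  expect_null(select_third_visit(v, 2.0, W = 1.0, last_followup_age = 2.8))
  # a visit exactly at time0 is usable
  expect_equal(select_third_visit(v, 2.0, W = 1.2)$age_years, 3.2)
  expect_error(select_third_visit(v, 2.0, W = 0), "W")
})

test_that("instances use the confirmatory visit as time 0 when W = 0", {
  coh <- generate_cohort(cohort_config(n_children = 200, seed = 15))
  inst <- build_instances(coh, horizon = 10, W = 0)
  expect_true(nrow(inst) > 100)
  expect_equal(inst$time0_age, inst$age_confirm)
  expect_true(all(inst$third_is_confirm))
  expect_true(all(inst$label %in% c("event", "nonevent", "censored")))
  expect_true(all(inst$followup_time >= 0))
  # label consistency with the typed invariants
  ev <- inst$label == "event"
  expect_true(all(inst$event_observed[ev] & inst$followup_time[ev] <= 10))
  ne <- inst$label == "nonevent"
  expect_true(all(inst$followup_time[ne] > 10 |
                    (inst$event_observed[ne] & inst$followup_time[ne] > 10)))
  cs <- inst$label == "censored"
  expect_true(all(!inst$event_observed[cs] & inst$followup_time[cs] <= 10))
})

test_that("W-cohorts are nested and shrink as W grows", {
  coh <- generate_cohort(cohort_config(n_children = 300, seed = 16))
  ws <- c(0.25, 1, 2.5, 5)
  ids <- lapply(ws, function(w) build_instances(coh, horizon = 10, W = w)$child_id)
  for (k in 2:length(ws)) {
    expect_true(all(ids[[k]] %in% ids[[k - 1]]))
  }
  # a child diagnosed between the confirmatory visit and confirmatory + W is
  # present at W = 0 but absent at that W
  inst0 <- build_instances(coh, horizon = 10, W = 0)
  sc <- seroconversion_records(coh$children, coh$visits)
  m <- merge(sc, coh$children, by = "child_id")
  gone <- m$child_id[!is.na(m$diagnosis_age_years) &
                       m$diagnosis_age_years <= m$age_confirm + 2.5 &
                       m$diagnosis_age_years > m$age_confirm]
  if (length(gone)) {
    expect_true(any(gone %in% inst0$child_id))
    expect_false(any(gone %in% ids[[3]]))
  }
  # third-visit features come from a visit no later than time0
  instw <- build_instances(coh, horizon = 10, W = 1.5)
  expect_true(all(instw$third_visit_age <= instw$time0_age + 1e-9))
  expect_true(all(instw$third_visit_age >= instw$age_confirm - 1e-9))
})

test_that("degenerate inputs give empty instance tables, not errors", {
  coh <- generate_cohort(cohort_config(n_children = 0, seed = 1))
  inst <- build_instances(coh, horizon = 10)
  expect_equal(nrow(inst), 0)
  expect_true(all(c("ln_iaa_t0", "label", "followup_time") %in% names(inst)))
  # horizon beyond all follow-up: everything is event or censored, no crash
  coh2 <- generate_cohort(cohort_config(n_children = 150, seed = 17))
  inst2 <- build_instances(coh2, horizon = 40)
  expect_true(all(inst2$label %in% c("event", "censored")))
})
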