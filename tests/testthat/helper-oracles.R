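# Independent brute-force oracles and tiny in-code fixtures.

# Exhaustive weighted pair-sum concordance: the definition, written as a
# double loop with no shared code with ipcw_c_index().
oracle_c_index <- function(scores, time, event, model, tau, cap = 20) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (!event[i] || time[i] >= tau) next
    wi <- min(1 / censoring_survival(model, time[i], left = TRUE), cap)^2
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + wi
      if (scores[i] > scores[j]) num <- num + wi
      else if (scores[i] == scores[j]) num <- num + wi / 2
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Classical concordance with no censoring: plain pair count.
oracle_concordance <- function(scores, time) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] >= time[j]) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# Brute-force scan of every consecutive pair for seroconversion.
oracle_detect <- function(levels, threshold = 1) {
  for (i in seq_len(length(levels) - 1L)) {
    ok1 <- !is.na(levels[i]) && levels[i] > threshold
    ok2 <- !is.na(levels[i + 1]) && levels[i + 1] > threshold
    if (ok1 && ok2) return(c(i, i + 1L))
  }
  NULL
}

# A small deterministic two-child cohort used across IO and window tests.
toy_cohort <- function() {
  children <- data.frame(
    child_id = c("A", "B"),
    source = c("DIPP", "DAISY"),
    sex = c("M", "F"),
    family_history = c(TRUE, FALSE),
    hla_group = c("A", "B"),
    diagnosis_age_years = c(4.0, NA),
    last_followup_age_years = c(4.0, 12.0),
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    child_id = rep(c("A", "B"), times = c(3, 4)),
    age_years = c(1.0, 1.5, 2.0, 2.0, 2.5, 3.0, 4.0),
    iaa_mULN = c(0.5, 2.0, 3.0, 0.2, 0.3, 0.2, 0.1),
    gada_mULN = c(0.4, 0.8, 0.9, 1.5, 2.5, 3.0, 2.0),
    ia2a_mULN = c(0.1, 0.1, 0.2, 0.3, 0.2, 0.5, 0.9),
    stringsAsFactors = FALSE
  )
  list(children = children, visits = visits)
}

# Uncensored instance table for exercising the weighted fit directly:
# events get times inside the horizon, non-events past it.
instances_from_xy <- function(x, y, horizon = 1) {
  data.frame(child_id = sprintf("k%04d", seq_along(y)),
             x = x,
             followup_time = ifelse(y == 1, horizon / 2, horizon + 1),
             event_observed = y == 1,
             stringsAsFactors = FALSE)
}

# Random small survival instance for property tests.
random_instance <- function(n, p_cens = 0.4, tie_prob = 0.3) {
  time <- round(stats::rexp(n, 0.3) + 0.1, if (stats::runif(1) < tie_prob) 0 else 3)
  time <- pmax(time, 0.1)
  event <- stats::runif(n) > p_cens
  scores <- round(stats::rnorm(n), if (stats::runif(1) < tie_prob) 0 else 3)
  list(time = time, event = event, scores = scores)
}
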