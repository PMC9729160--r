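#' Generate a synthetic seroconverted cohort
#'
#' Simulates a visit-level longitudinal cohort with the statistical structure
#' the downstream analysis assumes. In `longitudinal` mode each child gets a
#' visit schedule starting one interval before the seroconversion (initial)
#' visit; log-mULN antibody trajectories follow a child-specific
#' intercept-plus-drift process, and the onset hazard between consecutive
#' visits is piecewise constant, `exp(eta)` per year with `eta` linear in the
#' log-levels observed at the most recent visit plus the HLA group effect.
#' In `logistic_direct` mode the horizon outcome is drawn directly from the
#' logistic model so that weighted maximum likelihood must recover the
#' generating coefficients.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `iab_cohort`: list with elements
#'   \describe{
#'     \item{children}{data.frame: `child_id`, `source`, `sex`,
#'       `family_history`, `hla_group`, `diagnosis_age_years` (NA if not
#'       diagnosed), `last_followup_age_years`.}
#'     \item{visits}{data.frame: `child_id`, `age_years`, `iaa_mULN`,
#'       `gada_mULN`, `ia2a_mULN`, age-ordered within child.}
#'     \item{truth}{generating parameters and per-child latents (onset and
#'       censoring times; in `logistic_direct` mode also the exact feature
#'       row per child under `truth$instances`).}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_children = 50, seed = 7))
#' nrow(coh$children)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop_input("'config' must be built by cohort_config()")
  }
  with_seed(config$seed, {
    if (config$n_children == 0L) {
      return(empty_cohort(config))
    }
    if (config$mode == "logistic_direct") {
      generate_logistic_direct(config)
    } else {
      generate_longitudinal(config)
    }
  })
}

empty_cohort <- function(config) {
  structure(list(
    children = data.frame(child_id = character(), source = character(),
                          sex = character(), family_history = logical(),
                          hla_group = character(),
                          diagnosis_age_years = numeric(),
                          last_followup_age_years = numeric(),
                          stringsAsFactors = FALSE),
    visits = data.frame(child_id = character(), age_years = numeric(),
                        iaa_mULN = numeric(), gada_mULN = numeric(),
                        ia2a_mULN = numeric(), stringsAsFactors = FALSE),
    truth = list(risk_betas = config$risk_betas, latents = NULL),
    config = config), class = "iab_cohort")
}

sample_child_covariates <- function(config) {
  n <- config$n_children
  hla <- ifelse(stats::runif(n) < config$hla_missing_prob, "missing",
                sample(HLA_GROUPS, n, replace = TRUE, prob = config$hla_probs))
  data.frame(
    child_id = sprintf("C%05d", seq_len(n)),
    source = sample(SOURCES, n, replace = TRUE, prob = config$source_probs),
    sex = ifelse(stats::runif(n) < config$male_prob, "M", "F"),
    family_history = stats::runif(n) < config$famhist_prob,
    hla_group = hla,
    stringsAsFactors = FALSE
  )
}

# Truncated lognormal seroconversion (initial-visit) ages.
sample_serocon_ages <- function(n, dist, lower = 0.3, upper = 23.3) {
  meanlog <- dist[["meanlog"]]; sdlog <- dist[["sdlog"]]
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

generate_longitudinal <- function(config) {
  kids <- sample_child_covariates(config)
  n <- config$n_children
  lp <- config$level_params
  rb <- config$risk_betas
  dt <- config$visit_interval_years
  serocon <- sample_serocon_ages(n, config$serocon_age_dist)

  # Which antibodies seroconvert for each child; at least one must.
  cp <- vapply(ANTIBODIES, function(ab) lp[[ab]]$convert_prob, numeric(1))
  converted <- matrix(stats::runif(n * 3) < rep(cp, each = n), nrow = n,
                      dimnames = list(NULL, ANTIBODIES))
  none <- which(rowSums(converted) == 0L)
  if (length(none)) {
    forced <- sample.int(3L, length(none), replace = TRUE, prob = cp)
    converted[cbind(none, forced)] <- TRUE
  }

  dropout <- if (config$dropout_rate > 0) {
    stats::rexp(n, rate = config$dropout_rate)
  } else rep(Inf, n)
  censor_age <- serocon + pmin(dropout, config$followup_end_years)

  visit_list <- vector("list", n)
  diagnosis <- rep(NA_real_, n)
  onset_latent <- rep(Inf, n)
  hla_eff <- rb$hla[kids$hla_group]

  for (i in seq_len(n)) {
    s <- serocon[i]
    ages <- c(max(0.25, s - dt), seq(s, s + config$followup_end_years, by = dt))
    m <- length(ages)
    lnlev <- matrix(NA_real_, m, 3, dimnames = list(NULL, ANTIBODIES))
    for (j in seq_along(ANTIBODIES)) {
      ab <- ANTIBODIES[j]; p <- lp[[ab]]
      base <- stats::rnorm(m, p$baseline_mean, p$baseline_sd)
      if (converted[i, j]) {
        a0 <- stats::rnorm(1, p$post_mean, p$post_sd)
        dr <- stats::rnorm(1, p$drift_mean, p$drift_sd)
        post <- a0 + dr * (ages - s) + stats::rnorm(m, 0, p$noise_sd)
        lnlev[, j] <- ifelse(ages < s, base, post)
      } else {
        lnlev[, j] <- base
      }
    }
    # Piecewise-constant hazard from the initial visit onward, driven by the
    # levels at the most recent visit.
    risk_idx <- which(ages >= s)
    eta <- rb$intercept + hla_eff[i] +
      rb$iaa * pmax(lnlev[risk_idx, "iaa"], log(config$log_floor)) +
      rb$gada * pmax(lnlev[risk_idx, "gada"], log(config$log_floor)) +
      rb$ia2a * pmax(lnlev[risk_idx, "ia2a"], log(config$log_floor))
    lam <- exp(eta)
    t_onset <- Inf
    for (k in seq_along(risk_idx)) {
      gap <- if (k < length(risk_idx)) dt else Inf
      e <- stats::rexp(1, 1) / lam[k]
      if (e < gap) { t_onset <- ages[risk_idx[k]] + e; break }
    }
    onset_latent[i] <- t_onset
    last <- min(censor_age[i], t_onset)
    if (t_onset < censor_age[i]) diagnosis[i] <- t_onset
    keep <- if (is.na(diagnosis[i])) ages <= last else ages < last
    keep_idx <- which(keep)
    visit_list[[i]] <- data.frame(
      child_id = kids$child_id[i],
      age_years = round(ages[keep_idx], 3),
      iaa_mULN = round(exp(lnlev[keep_idx, "iaa"]), 6),
      gada_mULN = round(exp(lnlev[keep_idx, "gada"]), 6),
      ia2a_mULN = round(exp(lnlev[keep_idx, "ia2a"]), 6),
      stringsAsFactors = FALSE
    )
  }

  kids$diagnosis_age_years <- round(diagnosis, 3)
  kids$last_followup_age_years <- round(pmin(censor_age, onset_latent), 3)
  visits <- do.call(rbind, visit_list)
  rownames(visits) <- NULL

  structure(list(
    children = kids,
    visits = visits,
    truth = list(risk_betas = rb,
                 latents = data.frame(child_id = kids$child_id,
                                      serocon_age = serocon,
                                      latent_onset_age = onset_latent,
                                      censor_age = censor_age)),
    config = config), class = "iab_cohort")
}

generate_logistic_direct <- function(config) {
  kids <- sample_child_covariates(config)
  n <- config$n_children
  lp <- config$level_params
  rb <- config$risk_betas
  tt <- config$horizon_T

  lnlev <- vapply(ANTIBODIES, function(ab) {
    stats::rnorm(n, lp[[ab]]$post_mean, lp[[ab]]$post_sd)
  }, numeric(n))
  eta <- rb$intercept + rb$hla[kids$hla_group] +
    lnlev %*% c(rb$iaa, rb$gada, rb$ia2a)
  eta <- drop(eta)
  d <- stats::runif(n) < stats::plogis(eta)
  # Event times uniform inside the horizon; non-events survive past it.
  t_true <- ifelse(d, stats::runif(n, 0, tt), tt + stats::runif(n, 0.1, 5))
  cens <- if (config$dropout_rate > 0) {
    pmin(stats::rexp(n, config$dropout_rate), config$followup_end_years)
  } else rep(config$followup_end_years + tt, n)
  x <- pmin(t_true, cens)
  event <- d & (t_true <= cens)

  age0 <- 1
  age1 <- age0 + config$visit_interval_years
  kids$diagnosis_age_years <- ifelse(event, round(age1 + x, 3), NA_real_)
  kids$last_followup_age_years <- round(age1 + x, 3)

  mk_visit <- function(age) data.frame(
    child_id = kids$child_id, age_years = age,
    iaa_mULN = round(exp(lnlev[, "iaa"]), 6),
    gada_mULN = round(exp(lnlev[, "gada"]), 6),
    ia2a_mULN = round(exp(lnlev[, "ia2a"]), 6),
    stringsAsFactors = FALSE)
  visits <- rbind(mk_visit(age0), mk_visit(age1))
  visits <- visits[order(visits$child_id, visits$age_years), , drop = FALSE]
  rownames(visits) <- NULL

  inst <- data.frame(child_id = kids$child_id,
                     ln_iaa = lnlev[, "iaa"], ln_gada = lnlev[, "gada"],
                     ln_ia2a = lnlev[, "ia2a"],
                     hla_group = kids$hla_group,
                     eta = eta,
                     followup_time = x, event_observed = event,
                     stringsAsFactors = FALSE)

  structure(list(
    children = kids, visits = visits,
    truth = list(risk_betas = rb, horizon_T = tt, instances = inst,
                 latents = data.frame(child_id = kids$child_id,
                                      latent_event = d,
                                      latent_time = t_true,
                                      censor_time = cens)),
    config = config), class = "iab_cohort")
}

#' @export
print.iab_cohort <- function(x, ...) {
  nprog <- sum(!is.na(x$children$diagnosis_age_years))
  cat(sprintf("Synthetic IAb cohort (%s mode): %d children, %d visits\n",
              x$config$mode, nrow(x$children), nrow(x$visits)))
  if (nrow(x$children)) {
    cat(sprintf("  progressors: %d (%.1f%%)\n", nprog,
                100 * nprog / nrow(x$children)))
  }
  invisible(x)
}

#' Summarise a cohort in the style of a baseline characteristics table
#'
#' Produces counts and percentages by sex, data source and HLA risk group, and
#' mean/SD of seroconversion ages and antibody levels at the initial and
#' confirmatory visits, split by progression status (diagnosed vs not).
#' Seroconversion visits are located with the same two-consecutive-positives
#' rule the analysis uses; children with no confirmed seroconversion are
#' omitted from the seroconversion-age and level rows but counted in the
#' cohort-level rows.
#'
#' @param cohort An `iab_cohort`, or a list with `children` and `visits`
#'   data.frames.
#' @return A data.frame of class `cohort_summary` in long format with columns
#'   `variable`, `level`, `group` (`all`, `progressor`, `nonprogressor`),
#'   `n`, `pct`, `mean`, `sd`.
#' @export
summarise_cohort <- function(cohort) {
  children <- cohort$children
  visits <- cohort$visits
  prog <- !is.na(children$diagnosis_age_years)
  groups <- list(all = rep(TRUE, nrow(children)), progressor = prog,
                 nonprogressor = !prog)

  rows <- list()
  add <- function(variable, level, group, n = NA_real_, pct = NA_real_,
                  mean = NA_real_, sd = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, group = group, n = n, pct = pct,
      mean = mean, sd = sd, stringsAsFactors = FALSE)
  }

  for (g in names(groups)) {
    sel <- groups[[g]]
    ng <- sum(sel)
    add("n", "", g, n = ng, pct = if (nrow(children)) 100 * ng / nrow(children) else 0)
    add("sex", "Male", g, n = sum(children$sex[sel] == "M"),
        pct = if (ng) 100 * sum(children$sex[sel] == "M") / ng else 0)
    for (s in SOURCES) {
      add("source", s, g, n = sum(children$source[sel] == s),
          pct = if (ng) 100 * sum(children$source[sel] == s) / ng else 0)
    }
    for (h in c(HLA_GROUPS, "missing")) {
      add("hla_group", h, g, n = sum(children$hla_group[sel] == h),
          pct = if (ng) 100 * sum(children$hla_group[sel] == h) / ng else 0)
    }
  }

  sc <- seroconversion_records(children, visits)
  if (nrow(sc)) {
    sc$progressor <- prog[match(sc$child_id, children$child_id)]
    sgroups <- list(all = rep(TRUE, nrow(sc)), progressor = sc$progressor,
                    nonprogressor = !sc$progressor)
    msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
    for (g in names(sgroups)) {
      sel <- sgroups[[g]]
      if (!sum(sel)) next
      a <- msd(sc$age_initial[sel]); b <- msd(sc$age_confirm[sel])
      add("serocon_age_initial", "", g, n = sum(sel), mean = a["mean"], sd = a["sd"])
      add("serocon_age_confirm", "", g, n = sum(sel), mean = b["mean"], sd = b["sd"])
      for (ab in ANTIBODIES) {
        for (vis in c("init", "conf")) {
          col <- paste0(ab, "_mULN_", vis)
          v <- msd(sc[[col]][sel])
          add(paste0("level_", vis), toupper(ab), g, n = sum(sel),
              mean = v["mean"], sd = v["sd"])
          pcol <- paste0("pos_", ab, "_", vis)
          add(paste0("positive_", vis), toupper(ab), g, n = sum(sc[[pcol]][sel]),
              pct = 100 * sum(sc[[pcol]][sel]) / sum(sel))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  needed <- c("variable", "level", "group", "n", "pct", "mean", "sd")
  if (!all(needed %in% names(x))) return(NextMethod())
  cat("Cohort summary (counts n (%), levels mean +/- SD)\n")
  wide <- x[x$group == "all", , drop = FALSE]
  for (i in seq_len(nrow(wide))) {
    r <- wide[i, ]
    lbl <- if (nzchar(r$level)) paste(r$variable, r$level) else r$variable
    if (!is.na(r$mean)) {
      cat(sprintf("  %-28s %.1f +/- %.1f\n", lbl, r$mean, r$sd))
    } else if (!is.na(r$pct)) {
      cat(sprintf("  %-28s %d (%.1f%%)\n", lbl, as.integer(r$n), r$pct))
    } else {
      cat(sprintf("  %-28s %d\n", lbl, as.integer(r$n)))
    }
  }
  invisible(x)
}
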