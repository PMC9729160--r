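#' IPCW-weighted logistic regression for a fixed-horizon outcome
#'
#' Fits the probability of an event within `horizon` years of time 0 by
#' weighted maximum likelihood, where censoring before the horizon is handled
#' by inverse-probability-of-censoring weights from a Kaplan-Meier model of
#' the censoring distribution (fitted on the same data unless supplied).
#' Event rows are weighted by `1/G(X-)`, rows known event-free through the
#' horizon by `1/G(T)`, and rows censored inside the horizon drop out
#' (weight 0). The weighted Bernoulli likelihood is maximised by iteratively
#' reweighted least squares; the weighted log-likelihood is checked to be
#' nondecreasing at every iteration (with step halving) and convergence is
#' declared when no coefficient moves by more than `1e-8`.
#'
#' Categorical covariates use treatment coding. When present, the `source`
#' column is releveled to reference `DIPP`, `hla_group` to reference `B`
#' (with an explicit `missing` level retained), and `sex` to reference `F`.
#' Continuous covariates (ages, log-levels) enter untouched. Non-intercept
#' design columns that are constant are dropped with a warning.
#'
#' @param formula One-sided formula giving the covariates, e.g.
#'   `~ ln_iaa_conf + ln_gada_conf + ln_ia2a_conf`. The response is defined by
#'   `time`, `event` and `horizon`, not by the formula.
#' @param data Instance table (see [build_instances()]), one row per child.
#' @param horizon Follow-up period `T` in years.
#' @param time,event Names of the follow-up-time and event-indicator columns.
#' @param cens_model Optional [fit_censoring_km()] model; fitted on `data`
#'   when `NULL`.
#' @param weight_cap Maximum IPCW weight (default 20).
#' @param vcov_type `"robust"` (default) for sandwich standard errors, which
#'   stay calibrated under the heteroscedastic IPCW weights, or `"model"` for
#'   inverse weighted-information SEs (anticonservative when weights vary).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   `max |delta beta|`.
#' @return Object of class `ipcw_glm` with `coefficients`, `se`, `vcov`,
#'   fitted values, the censoring model, weights, counts and convergence
#'   diagnostics. Supports `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `residuals`, [wald_test()] and [fold_change_or()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_children = 400, seed = 3))
#' inst <- build_instances(coh, horizon = 10)
#' fit <- ipcw_glm(~ ln_iaa_conf + ln_gada_conf + ln_ia2a_conf, inst, horizon = 10)
#' summary(fit)
#' @export
ipcw_glm <- function(formula, data, horizon,
                     time = "followup_time", event = "event_observed",
                     cens_model = NULL, weight_cap = 20,
                     vcov_type = c("robust", "model"),
                     max_iter = 100L, tol = 1e-8) {
  vcov_type <- match.arg(vcov_type)
  if (length(formula) != 2L) {
    stop_input("'formula' must be one-sided (the outcome is defined by ",
               "'time', 'event' and 'horizon')")
  }
  check_scalar(horizon, "horizon", 0, strict_lower = TRUE)
  for (col in c(time, event)) {
    if (is.null(data[[col]])) stop_input("column '", col, "' not found in 'data'")
  }
  x_time <- data[[time]]
  x_event <- as.logical(data[[event]])
  if (is.null(cens_model)) cens_model <- fit_censoring_km(x_time, x_event)
  wl <- ipcw_weights(x_time, x_event, cens_model, tau = horizon, cap = weight_cap)

  used <- which(wl$weight > 0 & !is.na(wl$label))
  n_censored <- sum(is.na(wl$label))
  if (!length(used)) stop_input("no uncensored instances inside the horizon")

  dd <- relevel_covariates(data[used, , drop = FALSE])
  mf <- stats::model.frame(formula, dd, na.action = stats::na.fail)
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  y <- wl$label[used]
  w <- wl$weight[used]
  if (all(y == 1) || all(y == 0)) {
    stop_input("one-class data: both outcomes must be present with positive weight")
  }

  # Drop constant (non-intercept) columns, e.g. a factor level absent here.
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  keep[colnames(X) == "(Intercept)"] <- TRUE
  if (!all(keep)) {
    warning("dropping constant design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }

  fit <- irls_logistic(X, y, w, max_iter = max_iter, tol = tol)

  p <- fit$fitted
  info <- crossprod(X * sqrt(w * p * (1 - p)))
  info_inv <- solve_psd(info)
  V <- if (vcov_type == "robust") {
    score <- X * (w * (y - p))
    info_inv %*% crossprod(score) %*% info_inv
  } else {
    info_inv
  }
  dimnames(V) <- list(colnames(X), colnames(X))

  structure(list(
    coefficients = fit$beta, se = sqrt(diag(V)), vcov = V,
    vcov_type = vcov_type,
    fitted = p, linear.predictors = fit$eta,
    labels = y, ipcw = w, used_rows = used,
    loglik = fit$loglik, iter = fit$iter, converged = fit$converged,
    separation = fit$separation,
    formula = formula, terms = mt,
    xlevels = stats::.getXlevels(mt, mf),
    contrasts = attr(X, "contrasts"),
    dropped = if (all(keep)) character() else names(keep)[!keep],
    cens_model = cens_model, horizon = horizon, weight_cap = weight_cap,
    time_col = time, event_col = event,
    n = length(used), n_events = sum(y == 1), n_nonevents = sum(y == 0),
    n_censored = n_censored, sum_weights = sum(w),
    call = match.call()
  ), class = "ipcw_glm")
}

# Treatment-coding reference levels used throughout: data source DIPP,
# HLA risk group B (largest), sex F; an explicit "missing" HLA level is kept.
# Values outside the canonical levels are retained as extra levels so that
# prediction on unseen categories fails with an error naming them.
relevel_covariates <- function(d) {
  relev <- function(x, canonical) {
    factor(x, levels = union(canonical, unique(as.character(x))))
  }
  if (!is.null(d$source)) {
    d$source <- relev(d$source, c("DIPP", setdiff(SOURCES, "DIPP")))
  }
  if (!is.null(d$hla_group)) {
    d$hla_group <- relev(d$hla_group, c("B", setdiff(c(HLA_GROUPS, "missing"), "B")))
  }
  if (!is.null(d$sex) && !is.factor(d$sex)) {
    d$sex <- relev(d$sex, c("F", "M"))
  }
  d
}

# Weighted-logistic IRLS with likelihood-ascent guarantee via step halving.
irls_logistic <- function(X, y, w, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  ll <- weighted_bernoulli_ll(X, y, w, beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    v <- pmax(w * p * (1 - p), 1e-12)
    z <- eta + (y - p) / pmax(p * (1 - p), 1e-10)
    qr_fit <- stats::lm.wfit(X, z, v)
    beta_new <- qr_fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    step <- beta_new - beta
    # Likelihood must not decrease; halve the step until it does not.
    ll_new <- weighted_bernoulli_ll(X, y, w, beta + step)
    halvings <- 0L
    while (ll_new < ll - 1e-10 && halvings < 30L) {
      step <- step / 2
      ll_new <- weighted_bernoulli_ll(X, y, w, beta + step)
      halvings <- halvings + 1L
    }
    if (ll_new < ll - 1e-10) {
      warning("IRLS could not improve the weighted log-likelihood; stopping",
              call. = FALSE)
      break
    }
    beta <- beta + step
    ll <- ll_new
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  separation <- any(p < 1e-8 | p > 1 - 1e-8) && max(abs(beta)) > 10
  if (separation) {
    warning("possible complete separation: fitted probabilities numerically ",
            "0 or 1; coefficients unreliable", call. = FALSE)
  }
  if (!converged && !separation) {
    warning(sprintf("IRLS did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  list(beta = stats::setNames(beta, colnames(X)), eta = eta, fitted = p,
       loglik = ll, iter = iter, converged = converged,
       separation = separation)
}

weighted_bernoulli_ll <- function(X, y, w, beta) {
  eta <- drop(X %*% beta)
  # Numerically stable: log(1 + exp(eta)) without overflow.
  sum(w * (y * eta - ifelse(eta > 35, eta, log1p(exp(eta)))))
}

solve_psd <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out)) out <- MASS_ginv(A)
  out
}

# Moore-Penrose fallback for near-singular information matrices.
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
coef.ipcw_glm <- function(object, ...) object$coefficients

#' @export
vcov.ipcw_glm <- function(object, ...) object$vcov

#' @export
logLik.ipcw_glm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
residuals.ipcw_glm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$labels - object$fitted
  if (type == "pearson") {
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  }
  r
}

#' @export
print.ipcw_glm <- function(x, digits = 4, ...) {
  cat(sprintf("IPCW logistic regression (horizon T = %g years)\n", x$horizon))
  cat(sprintf("  n = %d used (%d events, %d event-free), %d censored dropped; sum(w) = %.1f\n",
              x$n, x$n_events, x$n_nonevents, x$n_censored, x$sum_weights))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.ipcw_glm <- function(object, level = 0.95, ...) {
  z <- object$coefficients / object$se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    estimate = object$coefficients, se = object$se, z = z, p.value = p,
    OR = exp(object$coefficients),
    OR_lo = exp(object$coefficients - q * object$se),
    OR_hi = exp(object$coefficients + q * object$se)
  )
  structure(list(coefficients = tab, horizon = object$horizon,
                 n = object$n, n_events = object$n_events,
                 n_censored = object$n_censored,
                 sum_weights = object$sum_weights,
                 converged = object$converged, iter = object$iter,
                 vcov_type = object$vcov_type, level = level),
            class = "summary.ipcw_glm")
}

#' @export
print.summary.ipcw_glm <- function(x, digits = 4, ...) {
  cat(sprintf("IPCW logistic regression (horizon T = %g y, %s SEs)\n",
              x$horizon, x$vcov_type))
  cat(sprintf("  n = %d (%d events), %d censored dropped, sum(w) = %.1f; %s in %d iter\n",
              x$n, x$n_events, x$n_censored, x$sum_weights,
              if (x$converged) "converged" else "NOT converged", x$iter))
  stats::printCoefmat(as.matrix(round(x$coefficients, digits)), P.values = TRUE,
                      has.Pvalue = TRUE, cs.ind = 1:2, tst.ind = 3)
  invisible(x)
}

#' Predict from an IPCW logistic model
#'
#' @param object An `ipcw_glm` fit.
#' @param newdata Instance table with the covariate columns of the model
#'   formula. An unseen factor level raises an error naming it.
#' @param type `"link"` (log-odds risk score) or `"response"` (horizon
#'   probability).
#' @param ... Unused.
#' @return Numeric vector of scores or probabilities.
#' @export
predict.ipcw_glm <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    eta <- object$linear.predictors
  } else {
    dd <- relevel_covariates(newdata)
    mt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(mt, dd, na.action = stats::na.fail,
                             xlev = object$xlevels)
    X <- stats::model.matrix(mt, mf, contrasts.arg = object$contrasts)
    X <- X[, names(object$coefficients), drop = FALSE]
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' Two-sided Wald test for a model term
#'
#' @param fit An `ipcw_glm` object.
#' @param term Coefficient name.
#' @param alpha Significance level for the `significant` flag (default 0.01,
#'   two-sided).
#' @return List with `z`, `p`, `significant`.
#' @export
wald_test <- function(fit, term, alpha = 0.01) {
  stopifnot(inherits(fit, "ipcw_glm"))
  if (!term %in% names(fit$coefficients)) {
    stop_input("term '", term, "' not in the fit")
  }
  se <- fit$se[[term]]
  if (!is.finite(se) || se == 0) {
    warning("standard error is zero or undefined for '", term, "'", call. = FALSE)
    return(list(z = NA_real_, p = NA_real_, significant = NA))
  }
  z <- unname(fit$coefficients[[term]] / se)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, significant = p < alpha)
}

#' Odds ratio for an n-fold increase in an antibody level
#'
#' A model coefficient `beta` on the natural-log level scale implies an odds
#' ratio `exp(beta * log(n))` for an `n`-fold increase in the level, since
#' multiplying the level by `n` adds `log(n)` to the covariate.
#'
#' @param object A per-log-unit coefficient (numeric) or an `ipcw_glm` fit.
#' @param n Fold change(s), `> 0`.
#' @param term For the `ipcw_glm` method, the coefficient name(s); defaults
#'   to all log-level terms (names starting with `ln_`).
#' @param ... Passed between methods.
#' @return Numeric odds ratio(s); for the fit method, a data.frame with one
#'   row per (term, n).
#' @examples
#' fold_change_or(log(4), n = 2)
#' @export
fold_change_or <- function(object, n, ...) UseMethod("fold_change_or")

#' @rdname fold_change_or
#' @export
fold_change_or.default <- function(object, n, ...) {
  if (any(n <= 0)) stop_input("'n' must be > 0")
  drop(exp(outer(as.numeric(object), log(n))))
}

#' @rdname fold_change_or
#' @export
fold_change_or.ipcw_glm <- function(object, n, term = NULL, ...) {
  if (any(n <= 0)) stop_input("'n' must be > 0")
  if (is.null(term)) {
    term <- grep("^ln_", names(object$coefficients), value = TRUE)
  }
  if (!length(term)) stop_input("no log-level terms in the fit")
  out <- expand.grid(term = term, fold = n, stringsAsFactors = FALSE)
  out$beta <- object$coefficients[out$term]
  out$OR <- exp(out$beta * log(out$fold))
  out
}
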