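#' Kaplan-Meier model of the censoring distribution
#'
#' Product-limit estimate of the censoring survival function `G(t)`,
#' obtained by treating censoring (`event = FALSE`) as the event of interest
#' and diagnosis (`event = TRUE`) as censoring of the censoring process.
#' `G(t)` is the probability of still being under observation just after `t`.
#'
#' At tied times the default convention removes diagnoses from the risk set
#' before the censoring events at that time (`ties = "diagnosis_first"`);
#' `"censoring_first"` keeps them at risk, which matches the usual
#' reversed-role Kaplan-Meier.
#'
#' @param time Follow-up times (years), all `>= 0`.
#' @param event Logical/0-1 diagnosis indicator (TRUE = diagnosed,
#'   FALSE = censored).
#' @param ties Tie-handling convention, see Details.
#' @return Object of class `censoring_km`: `jump_times` (increasing),
#'   `surv` (value of `G` from each jump onward), `n_fitted`, `ties`.
#' @examples
#' g <- fit_censoring_km(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
#' censoring_survival(g, c(1.5, 2, 4))  # 1, 2/3, 0
#' @export
fit_censoring_km <- function(time, event,
                             ties = c("diagnosis_first", "censoring_first")) {
  ties <- match.arg(ties)
  if (!length(time)) stop_input("empty input: no subjects to fit")
  if (length(time) != length(event)) stop_input("'time' and 'event' lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop_input("'time' must be finite and >= 0")
  }
  event <- as.logical(event)
  ct <- sort(unique(time[!event]))
  surv <- numeric(length(ct))
  g <- 1
  for (k in seq_along(ct)) {
    d_k <- sum(!event & time == ct[k])
    n_k <- if (ties == "diagnosis_first") {
      sum(time > ct[k]) + d_k
    } else {
      sum(time >= ct[k])
    }
    g <- g * (1 - d_k / n_k)
    surv[k] <- g
  }
  structure(list(jump_times = ct, surv = surv, n_fitted = length(time),
                 ties = ties),
            class = "censoring_km")
}

#' Evaluate the censoring survival function
#'
#' @param model A `censoring_km` object.
#' @param t Times at which to evaluate.
#' @param left If TRUE return the left limit `G(t-)` (the value just before
#'   `t`), the convention used when weighting an event at its own time.
#' @return `G(t)` (right-continuous step function) or `G(t-)`.
#' @export
censoring_survival <- function(model, t, left = FALSE) {
  stopifnot(inherits(model, "censoring_km"))
  idx <- findInterval(t, model$jump_times, left.open = left)
  c(1, model$surv)[idx + 1L]
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf("Censoring-distribution Kaplan-Meier: %d subjects, %d jumps (ties: %s)\n",
              x$n_fitted, length(x$jump_times), x$ties))
  if (length(x$jump_times)) {
    show <- utils::head(data.frame(time = x$jump_times, G = x$surv), 10)
    print(show, row.names = FALSE)
    if (length(x$jump_times) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Serialise / restore a censoring model
#'
#' @param model A `censoring_km`.
#' @param path File path for the JSON representation.
#' @return `write_censoring_km` returns `path` invisibly;
#'   `read_censoring_km` returns the restored `censoring_km`.
#' @export
write_censoring_km <- function(model, path) {
  stopifnot(inherits(model, "censoring_km"))
  jsonlite::write_json(list(jump_times = model$jump_times, surv = model$surv,
                            n_fitted = model$n_fitted, ties = model$ties),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_censoring_km
#' @export
read_censoring_km <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(jump_times = as.numeric(x$jump_times),
                 surv = as.numeric(x$surv),
                 n_fitted = as.integer(x$n_fitted), ties = x$ties),
            class = "censoring_km")
}

#' Inverse-probability-of-censoring weights for a horizon outcome
#'
#' Subjects with an observed event at `X <= tau` get weight `1/G(X-)`;
#' subjects known event-free past the horizon (`X > tau`, diagnosed later or
#' not at all) get `1/G(tau)`; event-free subjects last seen at or before the
#' horizon are censored and get weight 0 (they drop out of the weighted
#' likelihood). Weights are capped at `cap`, with a warning when the cap or a
#' zero `G` is hit.
#'
#' @param time Follow-up times from time 0 (years).
#' @param event Diagnosis indicator.
#' @param model `censoring_km` fitted on (training) data.
#' @param tau Horizon `T` in years.
#' @param cap Maximum weight (default 20).
#' @return data.frame with `label` (1 event within horizon, 0 event-free
#'   through horizon, `NA` censored) and `weight`.
#' @export
ipcw_weights <- function(time, event, model, tau, cap = 20) {
  check_scalar(tau, "tau", 0, strict_lower = TRUE)
  check_scalar(cap, "cap", 0, strict_lower = TRUE)
  event <- as.logical(event)
  n <- length(time)
  label <- rep(NA_real_, n)
  w <- rep(0, n)
  is_event <- event & time <= tau
  is_nonevent <- time > tau
  label[is_event] <- 1
  label[is_nonevent] <- 0
  w[is_event] <- 1 / censoring_survival(model, time[is_event], left = TRUE)
  w[is_nonevent] <- 1 / censoring_survival(model, tau)
  over <- is.infinite(w) | w > cap
  if (any(over)) {
    warning(sprintf("%d IPCW weight(s) capped at %g (G near 0)", sum(over), cap),
            call. = FALSE)
    w[over] <- cap
  }
  data.frame(label = label, weight = w)
}
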