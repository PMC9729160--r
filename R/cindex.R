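#' IPCW (Uno-type) concordance index
#'
#' Censoring-adjusted concordance for risk scores against a right-censored
#' time-to-event outcome, restricted to event times before the truncation
#' horizon `tau`. A pair `(i, j)` is comparable when subject `i` has an
#' observed event at `X_i < tau` and `X_j > X_i`; it contributes weight
#' `1/G(X_i-)^2`, where `G` is the Kaplan-Meier censoring survival function.
#' The numerator adds the pair weight when `score_i > score_j` and half of it
#' on score ties. With no censoring this reduces to the classical
#' concordance/AUC.
#'
#' @param scores Risk scores, higher = predicted earlier onset.
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param model `censoring_km` for `G`; fitted from `time`/`event` when
#'   `NULL`.
#' @param tau Truncation horizon, years.
#' @param cap Cap applied to each `1/G` factor (default 20).
#' @return Concordance in `[0, 1]`, or `NA` (with a warning) when no pair is
#'   comparable.
#' @export
ipcw_c_index <- function(scores, time, event, model = NULL, tau, cap = 20) {
  check_scalar(tau, "tau", 0, strict_lower = TRUE)
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (any(!is.finite(scores))) stop_input("'scores' must be finite")
  event <- as.logical(event)
  if (is.null(model)) model <- fit_censoring_km(time, event)

  idx <- which(event & time < tau)
  if (!length(idx)) {
    warning("no comparable pairs: concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  g <- censoring_survival(model, time[idx], left = TRUE)
  wi <- pmin(1 / g, cap)^2
  num <- 0
  den <- 0
  for (k in seq_along(idx)) {
    i <- idx[k]
    later <- time > time[i]
    m <- sum(later)
    if (!m) next
    conc <- sum(scores[i] > scores[later]) + 0.5 * sum(scores[i] == scores[later])
    num <- num + wi[k] * conc
    den <- den + wi[k] * m
  }
  if (den == 0) {
    warning("no comparable pairs: concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  num / den
}
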