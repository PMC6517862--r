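#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. The returned curve has
#' one row per distinct event time (censored-only times do not create
#' steps); \eqn{S(0) = 1} is implicit. Estimation is delegated to
#' [survival::survfit()].
#'
#' @param times Non-negative follow-up times (months).
#' @param events Binary event indicators (1 = death from the studied cancer,
#'   0 = censored).
#' @param weights Optional case weights (used internally when pooling
#'   pre-aggregated combination counts).
#' @return A `km_curve`: a tibble with columns `time`, `n_risk` (at risk
#'   just before `time`), `n_event` and `surv`, plus attributes `n0`
#'   (initial size) and `t_max` (last observed follow-up).
#' @export
#' @examples
#' km_estimate(c(5, 10), c(1, 1))
km_estimate <- function(times, events, weights = NULL) {
  if (length(times) == 0) abort("Empty survival sample.")
  if (length(times) != length(events)) {
    abort("`times` and `events` must have equal length.")
  }
  if (anyNA(times) || any(times < 0)) abort("`times` must be non-negative.")
  if (!all(events %in% c(0, 1))) abort("`events` must be 0/1.")
  if (is.null(weights)) weights <- rep(1, length(times))

  df <- data.frame(time = times, event = events, w = weights)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                          weights = df$w, conf.type = "none")
  keep <- sf$n.event > 0
  out <- tibble::tibble(
    time = sf$time[keep],
    n_risk = sf$n.risk[keep],
    n_event = sf$n.event[keep],
    surv = sf$surv[keep]
  )
  structure(out,
            n0 = sum(weights),
            t_max = max(times),
            class = c("km_curve", class(out)))
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function value \eqn{S(t)}; `t = 60` gives the
#' 5-year rate. Times beyond the last observed follow-up return the last
#' value with a warning.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Time point(s) in months, non-negative.
#' @return Numeric vector of survival probabilities.
#' @export
survival_at <- function(curve, t) {
  if (anyNA(t) || any(t < 0)) abort("`t` must be non-negative.")
  t_max <- attr(curve, "t_max")
  if (!is.null(t_max) && any(t > t_max)) {
    warn(paste0("Evaluating survival beyond the last follow-up (",
                format(t_max), " months); returning the last value."))
  }
  s <- c(1, curve$surv)
  idx <- findInterval(t, curve$time) + 1L
  s[idx]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n0 =", format(attr(x, "n0")),
      ", last follow-up =", format(attr(x, "t_max")), "months\n")
  NextMethod()
}

# Pool per-combination aggregated (time, event, weight) rows into one curve.
km_from_counts <- function(counts) {
  km_estimate(counts$time, counts$event, weights = counts$w)
}
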