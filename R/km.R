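#' Kaplan-Meier product-limit estimator
#'
#' Fits the Kaplan-Meier survival curve for a censored dataset. The estimate
#' is a non-increasing step function that starts at 1 and drops only at event
#' times; censored observations reduce the risk set without changing the
#' survival value. Deaths tied at the same time are aggregated into a single
#' multiplicative factor. Estimation is delegated to [survival::survfit()].
#'
#' @param data A [survival_dataset].
#' @return An object of class `km_curve`: list with `event_times` (strictly
#'   increasing) and `survival` (value of the estimate just after each event
#'   time, right-continuous).
#' @export
#' @examples
#' d <- survival_dataset(c(1, 2, 3), c(1, 1, 1), matrix(0, 3, 1), tau = 3)
#' km_fit(d)$survival  # 2/3, 1/3, 0
km_fit <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  fit <- survival::survfit(survival::Surv(data$time, data$status) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep], survival = fit$surv[keep]),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d event times", length(x$event_times)))
  if (length(x$event_times))
    cat(sprintf(", S drops from %.3f to %.3f over [%g, %g]",
                x$survival[1], x$survival[length(x$survival)],
                x$event_times[1], x$event_times[length(x$event_times)]))
  cat("\n")
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function evaluation: the value returned at `t` is the
#' estimate just after the last event time `<= t`; 1 before the first event,
#' and the last value beyond the final event time.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param t Non-negative time(s).
#' @return Survival probabilities in \[0, 1\], vectorized over `t`.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) stop("t must be non-negative")
  if (length(curve$event_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$event_times)  # right-continuous: ties included
  c(1, curve$survival)[idx + 1L]
}

#' Conditional survival weight for a censored observation
#'
#' Probability of remaining event-free for a further `z` time units given
#' survival to the censoring time `t_i`, estimated from the Kaplan-Meier curve
#' as the ratio S(t_i + z) / S(t_i). This is the quantity used to weight (or
#' assign an event probability to) censored observations under the
#' conditional-survival scheme. Floating-point ratios marginally above 1 are
#' clipped to 1.
#'
#' @param curve A `km_curve`.
#' @param t_i Censoring time, `>= 0`.
#' @param z Look-ahead horizon, `>= 0`. The package default elsewhere is
#'   `tau - t_i` (survival through the end of follow-up).
#' @return An object of class `censor_weight`: list with `value` in \[0, 1\]
#'   and `scheme = "conditional_km"`.
#' @export
conditional_weight <- function(curve, t_i, z) {
  stopifnot(inherits(curve, "km_curve"))
  if (t_i < 0 || z < 0) stop("t_i and z must be non-negative")
  s_t <- km_survival_at(curve, t_i)
  if (s_t <= 0) stop("S(t_i) = 0: conditional survival undefined")
  v <- km_survival_at(curve, t_i + z) / s_t
  v <- min(max(v, 0), 1)
  structure(list(value = v, scheme = "conditional_km"), class = "censor_weight")
}

#' Proportional follow-up weight
#'
#' The earlier literature's weighting rule for censored observations:
#' W = T_i / tau, the fraction of the administrative follow-up completed
#' before censoring.
#'
#' @param T_i Observed censoring time, `0 <= T_i <= tau`.
#' @param tau Administrative horizon, positive.
#' @return A `censor_weight` with `scheme = "proportional"`.
#' @export
proportional_weight <- function(T_i, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (T_i < 0 || T_i > tau) stop("T_i must lie in [0, tau]")
  structure(list(value = T_i / tau, scheme = "proportional"),
            class = "censor_weight")
}

#' @export
print.censor_weight <- function(x, ...) {
  cat(sprintf("censor_weight: %.4f (%s)\n", x$value, x$scheme))
  invisible(x)
}
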