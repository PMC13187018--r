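# Kaplan-Meier estimation and the two-sided log-rank (Mantel-Cox) test.
# The product-limit and Mantel-Cox machinery is delegated to the
# survival package (survfit/survdiff); these wrappers expose the exact
# quantities the stratified analyses consume and pin down the
# conventions (ties: events before censorings; median = smallest event
# time with S(t) <= 0.5; NA when never reached).

#' Fit a Kaplan-Meier curve
#'
#' @param time follow-up times in months (>= 0, finite).
#' @param event logical (or 0/1) event indicator; `FALSE` = censored.
#' @return object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (aligned vectors over observed times), `median`
#'   (months, `NA` if not reached) and `n`.
#' @export
km_fit <- function(time, event) {
  time <- as.numeric(time); event <- as.logical(event)
  if (!length(time) || length(time) != length(event))
    stop_load("km_fit needs non-empty, equal-length time and event vectors")
  if (any(!is.finite(time)) || any(time < 0))
    stop_load("times must be finite and non-negative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  # median by the smallest-event-time-with-S<=0.5 rule (boundary
  # inclusive), not survfit's midpoint convention for exact ties at 0.5
  hit <- fit$n.event > 0 & fit$surv <= 0.5 + 1e-12
  med <- if (any(hit)) fit$time[hit][1] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv,
                 median = med, n = length(time)),
            class = "km_curve")
}

#' Median survival from a fitted curve
#'
#' Smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` ("not reached") when the curve never does.
#'
#' @param curve a [km_fit()] result.
#' @return months, or `NA_real_` when not reached.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$median %||% NA_real_
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "NR" else format(x$median)))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             n_censor = x$n_censor, surv = x$surv)
}

#' Two-sided log-rank (Mantel-Cox) test
#'
#' Compares two censored samples via the summed hypergeometric
#' observed-minus-expected event counts; p from the chi-square
#' distribution with 1 df. With no events in either group (or a single
#' shared time pattern making the statistic undefined) the degenerate
#' convention `chi_square = 0`, `p = 1` applies, flagged in the result.
#'
#' @param time_a,event_a follow-up and event indicator, group A.
#' @param time_b,event_b follow-up and event indicator, group B.
#' @return object of class `logrank_result`: `chi_square`, `df`,
#'   `p_value`, per-group `n`, `observed`, `expected`, `degenerate`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop_load("both groups must be non-empty")
  time <- c(as.numeric(time_a), as.numeric(time_b))
  event <- c(as.logical(event_a), as.logical(event_b))
  if (any(!is.finite(time)) || any(time < 0))
    stop_load("times must be finite and non-negative")
  group <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))))
  obs_n <- c(A = length(time_a), B = length(time_b))
  if (sum(event) == 0) {
    return(structure(list(chi_square = 0, df = 1L, p_value = 1,
                          n = obs_n, observed = c(A = 0, B = 0),
                          expected = c(A = 0, B = 0), degenerate = TRUE),
                     class = "logrank_result"))
  }
  sd <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ group),
                 error = function(e) NULL)
  if (is.null(sd)) {
    # zero hypergeometric variance at every event time (e.g. all events
    # tied at one shared time): statistic undefined, p = 1 by convention
    ev <- table(group[event])
    obs <- c(A = unname(ev["A"]) %||% 0, B = unname(ev["B"]) %||% 0)
    obs[is.na(obs)] <- 0
    return(structure(list(chi_square = 0, df = 1L, p_value = 1, n = obs_n,
                          observed = obs, expected = obs, degenerate = TRUE),
                     class = "logrank_result"))
  }
  chi <- unname(sd$chisq)
  degenerate <- !is.finite(chi)
  if (degenerate) chi <- 0
  structure(list(chi_square = chi, df = 1L,
                 p_value = if (degenerate) 1 else
                   stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 n = obs_n,
                 observed = stats::setNames(unname(sd$obs), c("A", "B")),
                 expected = stats::setNames(unname(sd$exp), c("A", "B")),
                 degenerate = degenerate),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi-square = %.4g on %d df, p = %.4g%s\n",
              x$chi_square, x$df, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  group A: n = %d, observed %g, expected %.3g\n",
              x$n[1], x$observed[1], x$expected[1]))
  cat(sprintf("  group B: n = %d, observed %g, expected %.3g\n",
              x$n[2], x$observed[2], x$expected[2]))
  invisible(x)
}
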