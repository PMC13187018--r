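# Exact single-arm phase II statistics: response tabulation,
# Clopper-Pearson intervals, and the A'Hern one-stage design.

#' Tabulate RECIST best responses
#'
#' Counts best-response categories and derives the objective response
#' (CR + PR) and disease control (CR + PR + SD) counts. Patients with no
#' assessment (`NE`) count in the denominator but in neither numerator,
#' the convention of intention-to-treat response tables.
#'
#' @param clinical a [clinical_table()].
#' @return object of class `response_summary`: counts per category plus
#'   `orr_count` and `dcr_count`.
#' @export
tabulate_responses <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  tab <- table(clinical$best_response)
  out <- list(n_total = nrow(clinical),
              n_CR = unname(tab["CR"]), n_PR = unname(tab["PR"]),
              n_SD = unname(tab["SD"]), n_PD = unname(tab["PD"]),
              n_NE = unname(tab["NE"]))
  out$orr_count <- out$n_CR + out$n_PR
  out$dcr_count <- out$orr_count + out$n_SD
  structure(out, class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  ci <- function(k) {
    i <- clopper_pearson(k, x$n_total)
    sprintf("%d/%d = %.1f%% (95%% CI %.1f to %.1f)", k, x$n_total,
            round_half_away(100 * k / x$n_total),
            round_half_away(100 * i$lower), round_half_away(100 * i$upper))
  }
  cat("Best response (n =", x$n_total, "):\n")
  cat(sprintf("  CR %d  PR %d  SD %d  PD %d  NE %d\n",
              x$n_CR, x$n_PR, x$n_SD, x$n_PD, x$n_NE))
  cat("  ORR:", ci(x$orr_count), "\n")
  cat("  DCR:", ci(x$dcr_count), "\n")
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion from beta
#' quantiles: lower bound the `alpha/2` quantile of `Beta(x, n - x + 1)`
#' (0 when `x = 0`), upper the `1 - alpha/2` quantile of
#' `Beta(x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @return object of class `exact_interval` with elements `x`, `n`,
#'   `conf`, `estimate`, `lower`, `upper` (all proportions).
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (length(x) != 1 || length(n) != 1 || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n))
    stop_load("clopper_pearson needs integers 0 <= x <= n, n >= 1")
  check_prob(conf, "conf")
  a <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  structure(list(x = x, n = n, conf = conf, estimate = x / n,
                 lower = lower, upper = upper),
            class = "exact_interval")
}

#' @export
print.exact_interval <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f to %.1f)\n", x$x, x$n,
              round_half_away(100 * x$estimate), 100 * x$conf,
              round_half_away(100 * x$lower), round_half_away(100 * x$upper)))
  invisible(x)
}

#' Minimum responders under the A'Hern exact one-stage design
#'
#' Finds the smallest integer `r` whose exact binomial tail
#' `P(X >= r | n, p0)` does not exceed the one-sided type-I error
#' `alpha`, by direct tail summation (no normal approximation). If even
#' `r = n` fails, the sentinel `r = n + 1` is returned with
#' `feasible = FALSE`.
#'
#' @param n planned sample size.
#' @param p0 null (uninteresting) response proportion.
#' @param alpha one-sided type-I error.
#' @return list of class `ahern_threshold`: `r_min`, `attained_alpha`,
#'   `feasible`, plus the inputs.
#' @export
ahern_min_responses <- function(n, p0, alpha = 0.05) {
  if (n < 1 || n != round(n)) stop_load("n must be a positive integer")
  if (!(p0 > 0 && p0 < 1)) stop_load("p0 must lie strictly in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop_load("alpha must lie strictly in (0, 1)")
  # P(X >= r) over r = 0..n by exact summation
  tail <- stats::pbinom(seq_len(n + 1) - 2, n, p0, lower.tail = FALSE)
  ok <- which(tail <= alpha)
  if (!length(ok)) {
    return(structure(list(n = n, p0 = p0, alpha = alpha, r_min = n + 1L,
                          attained_alpha = NA_real_, feasible = FALSE),
                     class = "ahern_threshold"))
  }
  r <- ok[1] - 1L
  structure(list(n = n, p0 = p0, alpha = alpha, r_min = as.integer(r),
                 attained_alpha = tail[ok[1]], feasible = TRUE),
            class = "ahern_threshold")
}

#' Exact binomial power of a minimum-responders rule
#'
#' `P(X >= r | n, p1)` by exact summation.
#'
#' @param n sample size.
#' @param r minimum responders required.
#' @param p1 alternative (target) response proportion.
#' @return power as a proportion.
#' @export
exact_power <- function(n, r, p1) {
  if (r < 0 || r > n) stop_load("need 0 <= r <= n")
  check_prob(p1, "p1")
  stats::pbinom(r - 1, n, p1, lower.tail = FALSE)
}

#' Evaluate a full A'Hern single-stage design
#'
#' Combines [ahern_min_responses()] and [exact_power()]: the minimum
#' responders needed to reject a null response proportion `p0` at
#' one-sided level `alpha`, and the exact power attained at the
#' alternative `p1`.
#'
#' @param n sample size.
#' @param p0 null response proportion.
#' @param p1 alternative response proportion (`p1 > p0`).
#' @param alpha one-sided type-I error.
#' @return object of class `ahern_design`.
#' @export
ahern_design <- function(n, p0, p1, alpha = 0.05) {
  if (!(p1 > p0)) stop_load("p1 must exceed p0")
  th <- ahern_min_responses(n, p0, alpha)
  structure(c(unclass(th),
              list(p1 = p1,
                   attained_power = if (th$feasible)
                     exact_power(n, th$r_min, p1) else NA_real_)),
            class = "ahern_design")
}

#' @export
print.ahern_design <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("A'Hern design infeasible at n = %d, p0 = %.3g, alpha = %.3g\n",
                x$n, x$p0, x$alpha))
    return(invisible(x))
  }
  cat(sprintf(
    "A'Hern one-stage design: >= %d responses of %d required (p0 = %.2f, p1 = %.2f)\n",
    x$r_min, x$n, x$p0, x$p1))
  cat(sprintf("  attained one-sided alpha = %.4f, exact power = %.4f\n",
              x$attained_alpha, x$attained_power))
  invisible(x)
}

#' @export
print.ahern_threshold <- function(x, ...) {
  if (!x$feasible)
    cat(sprintf("infeasible: no r <= n meets alpha = %.3g (sentinel r = %d)\n",
                x$alpha, x$r_min))
  else
    cat(sprintf("r_min = %d of n = %d (attained alpha %.4f)\n",
                x$r_min, x$n, x$attained_alpha))
  invisible(x)
}
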