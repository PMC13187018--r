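# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding convention used when rendering percentages: ties go away from
#' zero (so 0.25 -> 0.3 at one decimal), matching how clinical tables are
#' typically printed, rather than R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible sub-stream seed from a base seed and a stage name.
# Each simulation stage draws from its own stream so that adding a stage
# never perturbs the draws of another. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch)) %% 104729
  as.integer((abs(as.numeric(seed)) %% 1048573) * 2053 + h * 7919) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_load <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop_load("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

# Fixed-precision rendering for tabular output: significant-digit format
# so re-running with the same inputs writes byte-identical files.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}
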