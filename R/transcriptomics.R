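# Count filtering, TMM normalization, principal components, and the
# fold-change + t-test differential-expression selection between
# prognosis subgroups.

#' Filter low-expressed genes from a count matrix
#'
#' Removes genes with zero counts in every sample, then genes failing
#' the low-count rule: total across samples below `threshold`
#' (`mode = "total"`, the default) or maximum in any single sample below
#' `threshold` (`mode = "max"`). The boundary is strict-below, so a gene
#' totalling exactly `threshold` is retained. Idempotent.
#'
#' @param counts a [count_matrix()].
#' @param threshold low-count threshold (default 20).
#' @param mode `"total"` or `"max"`.
#' @return filtered `count_matrix`.
#' @export
filter_genes <- function(counts, threshold = 20, mode = c("total", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "count_matrix"), threshold >= 0)
  keep <- rowSums(counts) > 0
  stat <- if (mode == "total") rowSums(counts) else apply(counts, 1, max)
  keep <- keep & stat >= threshold
  if (!any(keep)) stop_load("filtering removed every gene")
  count_matrix(unclass(counts)[keep, , drop = FALSE])
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (edgeR's TMM): the reference
#' sample is the one whose upper-quartile count fraction is closest to
#' the mean; each sample's factor is the inverse-variance-weighted mean
#' of gene-wise log-ratios after trimming the most extreme `trim_m` of
#' M-values and `trim_a` of A-values; factors are rescaled to geometric
#' mean 1. Degenerate samples (at most one expressed gene) get factor 1
#' with a warning.
#'
#' @param counts a [count_matrix()] (typically after [filter_genes()]).
#' @param trim_m two-sided trim fraction on log-ratios (default 0.30).
#' @param trim_a two-sided trim fraction on average log intensity
#'   (default 0.05).
#' @return named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  if (ncol(counts) < 2) stop_load("TMM needs >= 2 samples")
  if (any(colSums(counts) <= 0)) stop_load("every sample needs a positive total")
  m <- unclass(counts); storage.mode(m) <- "double"
  degen <- colSums(m > 0) <= 1
  f <- rep(1, ncol(m))
  if (all(degen)) {
    warning("all samples degenerate; TMM factors set to 1")
  } else {
    f <- edgeR::calcNormFactors(m, method = "TMM",
                                logratioTrim = trim_m, sumTrim = trim_a)
    if (any(degen)) {
      warning("degenerate sample(s) with a single expressed gene; factor set to 1: ",
              paste(colnames(m)[degen], collapse = ", "))
      f[degen] <- 1
      # rescale the informative factors among themselves: their log-mean
      # is zero, so the overall geometric mean stays 1
      f[!degen] <- f[!degen] / exp(mean(log(f[!degen])))
    }
  }
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts-per-million normalization
#'
#' `log2(count * 1e6 / (library_size * factor) + 1)` per entry, with the
#' effective library size the raw column total times its TMM factor.
#'
#' @param counts a [count_matrix()].
#' @param factors per-sample scaling factors; computed by
#'   [tmm_factors()] when `NULL`.
#' @return object of class `normalized_matrix`: a numeric matrix with
#'   attributes `tmm_factors` and `lib_sizes`.
#' @export
log_normalize <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  factors <- factors %||% tmm_factors(counts)
  if (any(factors <= 0)) stop_load("scaling factors must be positive")
  lib <- colSums(counts)
  x <- log2(t(t(unclass(counts) * 1e6) / (lib * factors)) + 1)
  structure(x, tmm_factors = factors, lib_sizes = lib,
            class = c("normalized_matrix", "matrix", "array"))
}

#' Principal-component coordinates of samples
#'
#' Scores of the mean-centered (gene-wise) normalized matrix, samples as
#' observations. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the output
#' deterministic across linear-algebra backends.
#'
#' @param norm a [log_normalize()] matrix (genes x samples).
#' @param n_components number of components (<= min(genes, samples)).
#' @return list: `scores` (samples x components), `variance_fraction`,
#'   `loadings` (genes x components).
#' @export
pca_coordinates <- function(norm, n_components = 2) {
  x <- unclass(norm)
  if (n_components > min(dim(x)))
    stop_load("n_components exceeds min(genes, samples)")
  tot <- sum(apply(x, 1, stats::var) * (ncol(x) - 1))
  if (tot == 0) stop_load("constant matrix: zero variance, no principal components")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]; scores[, j] <- -scores[, j]
    }
  }
  vf <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(scores = scores, variance_fraction = vf, loadings = load)
}

#' Differential expression by fold change and t-test
#'
#' Per-gene two-sample t-test (pooled-variance Student test by default)
#' on the normalized values, and a signed linear-scale fold change from
#' the group means of `2^x` (sign-minus-reciprocal convention for
#' down-regulation: a gene halved in A vs B gets fold change -2). A gene
#' is selected when its fold change strictly exceeds the threshold in
#' magnitude and its unadjusted p-value is at most `p_threshold`.
#'
#' @param norm a [log_normalize()] matrix.
#' @param group_a,group_b sample ids of the two groups (>= 2 each).
#' @param fc_threshold linear fold-change threshold (default 2.5,
#'   strict inequality).
#' @param p_threshold p-value threshold (default 0.0128, unadjusted).
#' @param var_equal pooled-variance test when `TRUE` (default); Welch
#'   otherwise.
#' @return data frame of class `deg_result`: gene, mean_a, mean_b,
#'   fold_change, t, p_value, selected; thresholds stored as attributes.
#' @export
select_degs <- function(norm, group_a, group_b, fc_threshold = 2.5,
                        p_threshold = 0.0128, var_equal = TRUE) {
  x <- unclass(norm)
  if (!all(group_a %in% colnames(x)) || !all(group_b %in% colnames(x)))
    stop_load("group sample ids must name columns of the normalized matrix")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_load("each group needs >= 2 samples")
  a <- x[, group_a, drop = FALSE]; b <- x[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero pooled variance: identical values in both groups
  flat <- se == 0
  p[flat & ma == mb] <- 1
  tstat[flat & ma == mb] <- 0
  p[flat & ma != mb] <- 0
  # linear-scale fold change from group means of 2^x
  la <- rowMeans(2^a); lb <- rowMeans(2^b)
  fc <- ifelse(la >= lb, la / lb, -lb / la)
  sel <- (fc > fc_threshold | fc < -fc_threshold) & p <= p_threshold
  out <- data.frame(gene = rownames(x), mean_a = ma, mean_b = mb,
                    fold_change = fc, t = tstat, p_value = p,
                    selected = sel, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, fc_threshold = fc_threshold, p_threshold = p_threshold,
            class = c("deg_result", "data.frame"))
}

#' @export
print.deg_result <- function(x, ...) {
  up <- sum(x$selected & x$fold_change > 0)
  dn <- sum(x$selected & x$fold_change < 0)
  cat(sprintf(
    "DEG selection (|FC| > %.3g, p <= %.4g): %d selected (%d up, %d down) of %d genes\n",
    attr(x, "fc_threshold"), attr(x, "p_threshold"), up + dn, up, dn, nrow(x)))
  invisible(x)
}
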