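# Fixtures built in code, plus independent brute-force oracles used to
# check the package implementations. The oracles deliberately share no
# code with the package: product-limit and log-rank by explicit
# event-time tables, TMM by a literal trimmed weighted mean, the
# hypergeometric tail by enumeration, BH by the textbook step-up.

toy_clinical <- function(n = 12, pfs = NULL, event = NULL, msi = NULL) {
  clinical_table(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    msi_status = msi %||% rep("MSS", n),
    ras_status = "mut", braf_status = "wt",
    pfs_months = pfs %||% seq_len(n),
    pfs_event = event %||% rep(TRUE, n),
    best_response = "PR", stringsAsFactors = FALSE))
}

toy_alterations <- function(records, patients = NULL, tmb = NULL) {
  # records: data.frame(patient_id, gene) or (patient_id, gene, class)
  if (is.null(records$alteration_class)) records$alteration_class <- "SNV"
  pts <- patients %||% unique(records$patient_id)
  alteration_table(records,
                   tmb %||% stats::setNames(rep(5, length(pts)), pts))
}

# --- product-limit oracle -------------------------------------------------
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1; out <- numeric(0)
  for (t in ts) {
    at_risk <- sum(time >= t)            # events before censorings at ties
    d <- sum(time == t & event)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
  }
  med <- if (any(out <= 0.5 + 1e-12)) ts[which(out <= 0.5 + 1e-12)[1]] else NA_real_
  list(time = ts, surv = out, median = med)
}

# --- log-rank oracle ------------------------------------------------------
logrank_oracle <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(1:2, c(length(ta), length(tb)))
  ts <- sort(unique(time[event]))
  o_a <- e_a <- v <- 0
  for (t in ts) {
    n1 <- sum(time >= t & grp == 1); n2 <- sum(time >= t & grp == 2)
    d1 <- sum(time == t & event & grp == 1)
    d2 <- sum(time == t & event & grp == 2)
    n <- n1 + n2; d <- d1 + d2
    o_a <- o_a + d1
    e_a <- e_a + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(chi_square = chi,
       p_value = if (v > 0) stats::pchisq(chi, 1, lower.tail = FALSE) else 1)
}

# --- signature-derivation oracle: double loop over genes x patients -------
derive_oracle <- function(records, q1_ids, q4_ids) {
  genes <- unique(records$gene)
  res <- sens <- character(0)
  for (g in genes) {
    in_q1 <- any(records$patient_id[records$gene == g] %in% q1_ids)
    in_q4 <- any(records$patient_id[records$gene == g] %in% q4_ids)
    if (in_q1 && !in_q4) res <- c(res, g)
    if (in_q4 && !in_q1) sens <- c(sens, g)
  }
  list(res_genes = sort(res), sens_genes = sort(sens))
}

# --- TMM oracle: literal weighted trimmed mean of M-values ----------------
tmm_oracle <- function(counts, ref_col, sample_col,
                       trim_m = 0.30, trim_a = 0.05) {
  obs <- counts[, sample_col] / sum(counts[, sample_col])
  ref <- counts[, ref_col] / sum(counts[, ref_col])
  keep <- obs > 0 & ref > 0
  m <- log2(obs[keep] / ref[keep])
  a <- (log2(obs[keep]) + log2(ref[keep])) / 2
  w <- (1 - counts[keep, sample_col] / sum(counts[, sample_col])) /
    counts[keep, sample_col] +
    (1 - counts[keep, ref_col] / sum(counts[, ref_col])) /
    counts[keep, ref_col]
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# --- hypergeometric tail by enumeration -----------------------------------
hyper_tail_oracle <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# --- BH step-up oracle ----------------------------------------------------
bh_oracle <- function(p) {
  m <- length(p); o <- order(p); q <- numeric(m)
  sorted <- p[o]
  q_sorted <- pmin(1, rev(cummin(rev(sorted * m / seq_len(m)))))
  q[o] <- q_sorted
  q
}
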