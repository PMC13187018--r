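# Survival-quartile genomic signature analysis: the bespoke procedure at
# the heart of the package. Patients in a profiled MSS subcohort are
# ranked by progression-free survival, the extreme quartiles compared at
# the mutated-gene level, and the genes altered exclusively in the worst
# (resistance, RES) or best (sensitivity, SENS) quartile form signatures
# whose carriers are then evaluated by stratified survival, including
# held-out variants that drop the derivation quartile from the carrier
# group.

#' Assign progression-free-survival quartiles
#'
#' Ranks the subcohort by observed PFS (regardless of censoring status;
#' ties broken by event-before-censored, then patient id, so the
#' assignment is deterministic). Q1 holds the `floor(n/4)` shortest-PFS
#' patients, Q4 the `floor(n/4)` longest; the remainder splits into
#' Q2/Q3 with the extra patient(s) in Q2. At n = 49 this yields group
#' sizes 12/13/12/12.
#'
#' @param clinical a [clinical_table()].
#' @param subset optional: character vector of patient ids, a logical
#'   vector over rows, or a predicate function applied to the table.
#'   Default keeps every patient.
#' @return object of class `quartile_assignment`: `table` (patient_id,
#'   pfs_months, pfs_event, quartile), `sizes`, `n`.
#' @export
assign_quartiles <- function(clinical, subset = NULL) {
  stopifnot(inherits(clinical, "clinical_table"))
  keep <- rep(TRUE, nrow(clinical))
  if (is.function(subset)) keep <- subset(clinical)
  else if (is.character(subset)) keep <- clinical$patient_id %in% subset
  else if (is.logical(subset)) keep <- subset
  sub <- clinical[keep, , drop = FALSE]
  n <- nrow(sub)
  if (n < 8) stop_load("quartile assignment needs >= 8 patients (got %d)", n)
  ord <- order(sub$pfs_months, ifelse(sub$pfs_event, 0L, 1L), sub$patient_id)
  q14 <- n %/% 4
  rem <- n - 2L * q14
  sizes <- c(Q1 = q14, Q2 = ceiling(rem / 2), Q3 = floor(rem / 2), Q4 = q14)
  quart <- rep(names(sizes), sizes)
  tab <- data.frame(patient_id = sub$patient_id[ord],
                    pfs_months = sub$pfs_months[ord],
                    pfs_event = sub$pfs_event[ord],
                    quartile = factor(quart, levels = names(sizes)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, sizes = sizes, n = n),
            class = "quartile_assignment")
}

#' @export
print.quartile_assignment <- function(x, ...) {
  cat(sprintf("PFS quartiles on %d patients: Q1 %d / Q2 %d / Q3 %d / Q4 %d\n",
              x$n, x$sizes[1], x$sizes[2], x$sizes[3], x$sizes[4]))
  invisible(x)
}

# genes altered (any class) in at least one patient of `ids`
altered_genes <- function(alterations, ids) {
  rec <- alterations$records
  unique(rec$gene[rec$patient_id %in% ids])
}

#' Derive resistance and sensitivity gene signatures
#'
#' RES = genes with at least one alteration (any class) in a Q1 patient
#' and none in any Q4 patient; SENS symmetric with Q4 and Q1 swapped. A
#' gene altered in both extreme quartiles joins neither set, so the two
#' signatures are disjoint by construction.
#'
#' @param alterations an [alteration_table()]. Every quartile patient
#'   must appear in its patient index (the TMB side table, when present)
#'   or simply contribute zero records.
#' @param quartiles an [assign_quartiles()] result.
#' @return list with character vectors `res_genes` and `sens_genes`.
#' @export
derive_signatures <- function(alterations, quartiles) {
  stopifnot(inherits(alterations, "alteration_table"),
            inherits(quartiles, "quartile_assignment"))
  tab <- quartiles$table
  q1 <- tab$patient_id[tab$quartile == "Q1"]
  q4 <- tab$patient_id[tab$quartile == "Q4"]
  g1 <- altered_genes(alterations, q1)
  g4 <- altered_genes(alterations, q4)
  list(res_genes = sort(setdiff(g1, g4)),
       sens_genes = sort(setdiff(g4, g1)))
}

#' Classify signature carriers
#'
#' A patient is a carrier (`TRUE`, "+") when they have at least one
#' alteration record of any class in at least one signature gene.
#'
#' @param alterations an [alteration_table()].
#' @param genes character vector of signature genes (may be empty).
#' @param patients patient ids to classify.
#' @return named logical vector over `patients`.
#' @export
classify_carriers <- function(alterations, genes, patients) {
  rec <- alterations$records
  hit <- unique(rec$patient_id[rec$gene %in% genes])
  stats::setNames(patients %in% hit, patients)
}

#' Evaluate a signature by stratified survival
#'
#' Compares carriers (+) against non-carriers (-) with the two-sided
#' log-rank test and per-group Kaplan-Meier medians. The held-out
#' variants remove the derivation-quartile patients from the carrier
#' group only — the non-carrier group is left intact — mirroring the
#' "without the 25th/75th percentile" analyses that guard against the
#' circularity of evaluating a signature on the quartiles it was
#' derived from.
#'
#' @param clinical a [clinical_table()].
#' @param flags named logical carrier vector (from [classify_carriers()]);
#'   its names define the evaluated subcohort.
#' @param holdout `"none"`, `"drop_Q1_positives"`,
#'   `"drop_Q4_positives"`, or `"drop_extremes"`. The first two mirror
#'   the published "without the 25th/75th percentile" analyses; because
#'   they keep the non-carrier group intact (which by construction
#'   contains the whole opposite extreme quartile) they remain
#'   anti-conservative under the null. `"drop_extremes"` removes both
#'   extreme quartiles from *both* arms and compares carriers and
#'   non-carriers within the middle quartiles only; under the null its
#'   rejection rate is at the nominal level.
#' @param quartiles required for the holdout variants.
#' @return object of class `signature_evaluation`: `logrank`
#'   (a `logrank_result`, or `NULL` when degenerate), `medians`,
#'   `group_n`, `groups` (per-patient +/- after holdout), `degenerate`.
#' @export
evaluate_signature <- function(clinical, flags,
                               holdout = c("none", "drop_Q1_positives",
                                           "drop_Q4_positives",
                                           "drop_extremes"),
                               quartiles = NULL) {
  holdout <- match.arg(holdout)
  stopifnot(inherits(clinical, "clinical_table"))
  ids <- names(flags)
  if (is.null(ids)) stop_load("carrier flags must be a named logical vector")
  idx <- match(ids, clinical$patient_id)
  if (anyNA(idx)) stop_load("carrier flags name patients absent from the clinical table")
  pos <- ids[flags]
  neg <- ids[!flags]
  if (holdout != "none") {
    if (is.null(quartiles)) stop_load("holdout evaluation needs the quartile assignment")
    qt <- quartiles$table
    if (holdout == "drop_extremes") {
      keep <- qt$patient_id[qt$quartile %in% c("Q2", "Q3")]
      pos <- intersect(pos, keep)
      neg <- intersect(neg, keep)
    } else {
      qlab <- if (holdout == "drop_Q1_positives") "Q1" else "Q4"
      drop <- qt$patient_id[qt$quartile == qlab]
      pos <- setdiff(pos, drop)   # carrier group only; '-' group unchanged
    }
  }
  group_n <- c(pos = length(pos), neg = length(neg))
  if (any(group_n == 0)) {
    return(structure(list(logrank = NULL, medians = c(pos = NA_real_, neg = NA_real_),
                          group_n = group_n, holdout = holdout,
                          groups = NULL, degenerate = TRUE),
                     class = "signature_evaluation"))
  }
  cl <- function(p) clinical[match(p, clinical$patient_id), , drop = FALSE]
  a <- cl(pos); b <- cl(neg)
  lr <- logrank_test(a$pfs_months, a$pfs_event, b$pfs_months, b$pfs_event)
  med <- c(pos = km_median(km_fit(a$pfs_months, a$pfs_event)),
           neg = km_median(km_fit(b$pfs_months, b$pfs_event)))
  groups <- stats::setNames(c(rep("+", length(pos)), rep("-", length(neg))),
                            c(pos, neg))
  structure(list(logrank = lr, medians = med, group_n = group_n,
                 holdout = holdout, groups = groups,
                 degenerate = lr$degenerate),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  fmt_med <- function(m) if (is.na(m)) "NR" else sprintf("%.3g", m)
  cat(sprintf("Carrier-stratified PFS (%s): + n = %d (median %s) vs - n = %d (median %s)\n",
              x$holdout, x$group_n["pos"], fmt_med(x$medians["pos"]),
              x$group_n["neg"], fmt_med(x$medians["neg"])))
  if (is.null(x$logrank)) cat("  degenerate: one group empty\n")
  else cat(sprintf("  log-rank p = %.4g%s\n", x$logrank$p_value,
                   if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Full resistance/sensitivity signature analysis
#'
#' Convenience wrapper running the whole bespoke procedure on a profiled
#' subcohort: quartile assignment, RES/SENS derivation, carrier
#' classification, and all six stratified-survival evaluations (RES and
#' SENS, each with no holdout and with its derivation quartile held out
#' of the carrier group).
#'
#' @param clinical a [clinical_table()].
#' @param alterations an [alteration_table()].
#' @param subset subcohort selector as in [assign_quartiles()]; default
#'   restricts to MSS patients.
#' @return object of class `signature_result`.
#' @export
signature_analysis <- function(clinical, alterations,
                               subset = function(cl) cl$msi_status == "MSS") {
  quart <- assign_quartiles(clinical, subset)
  sig <- derive_signatures(alterations, quart)
  ids <- quart$table$patient_id
  res_fl <- classify_carriers(alterations, sig$res_genes, ids)
  sens_fl <- classify_carriers(alterations, sig$sens_genes, ids)
  structure(list(
    quartiles = quart,
    res_genes = sig$res_genes, sens_genes = sig$sens_genes,
    res_carrier = res_fl, sens_carrier = sens_fl,
    res_eval = evaluate_signature(clinical, res_fl, "none", quart),
    res_eval_holdout = evaluate_signature(clinical, res_fl,
                                          "drop_Q1_positives", quart),
    sens_eval = evaluate_signature(clinical, sens_fl, "none", quart),
    sens_eval_holdout = evaluate_signature(clinical, sens_fl,
                                           "drop_Q4_positives", quart)),
    class = "signature_result")
}

signature_tests_df <- function(x) {
  row <- function(name, ev) data.frame(
    comparison = name,
    n_pos = ev$group_n["pos"], n_neg = ev$group_n["neg"],
    median_pos = ev$medians["pos"], median_neg = ev$medians["neg"],
    chi_square = if (is.null(ev$logrank)) NA_real_ else ev$logrank$chi_square,
    p_value = if (is.null(ev$logrank)) NA_real_ else ev$logrank$p_value,
    degenerate = ev$degenerate, row.names = NULL)
  rbind(row("RES+_vs_RES-", x$res_eval),
        row("RES+_wo_Q1_vs_RES-", x$res_eval_holdout),
        row("SENS+_vs_SENS-", x$sens_eval),
        row("SENS+_wo_Q4_vs_SENS-", x$sens_eval_holdout))
}

#' @export
print.signature_result <- function(x, ...) {
  print(x$quartiles)
  cat(sprintf("RES signature: %d genes; SENS signature: %d genes\n",
              length(x$res_genes), length(x$sens_genes)))
  cat("RES  : "); print(x$res_eval)
  cat("RES  w/o Q1: "); print(x$res_eval_holdout)
  cat("SENS : "); print(x$sens_eval)
  cat("SENS w/o Q4: "); print(x$sens_eval_holdout)
  invisible(x)
}

#' @export
summary.signature_result <- function(object, ...) signature_tests_df(object)

#' Dichotomize patients by tumor mutational burden
#'
#' `high` when TMB is at or above the cutoff (boundary inclusive),
#' `low` below.
#'
#' @param tmb named numeric vector of mutations/Mb, or an
#'   [alteration_table()] carrying a TMB side table.
#' @param cutoff mutations/Mb, default 10.4 (the panel-calibrated
#'   threshold used to dichotomize this assay's TMB estimates).
#' @return named factor with levels `low`, `high`.
#' @export
classify_tmb <- function(tmb, cutoff = 10.4) {
  if (!(is.numeric(cutoff) && cutoff > 0)) stop_load("cutoff must be > 0")
  if (inherits(tmb, "alteration_table")) {
    if (is.null(tmb$tmb))
      stop_load("alteration table has no TMB side table; TMB analysis refused")
    tmb <- tmb$tmb
  }
  if (is.null(names(tmb))) stop_load("tmb must be a named vector")
  if (anyNA(tmb)) stop_load("missing TMB for patient(s): %s",
                            paste(names(tmb)[is.na(tmb)], collapse = ", "))
  stats::setNames(factor(ifelse(tmb >= cutoff, "high", "low"),
                         levels = c("low", "high")), names(tmb))
}

#' Stratify patients by pathway alteration status
#'
#' Labels a patient `MUT` when they carry at least one alteration in at
#' least one pathway gene, `WT` otherwise; compares PFS between the two
#' groups by log-rank; and crosses pathway status with the TMB high/low
#' dichotomy in a 2x2 table tested by the two-sided Fisher exact test
#' (degenerate margins give p = 1, flagged).
#'
#' @param alterations an [alteration_table()] (TMB side table required
#'   for the contingency part; set `tmb_cutoff = NA` to skip it).
#' @param pathway non-empty character vector of pathway gene symbols.
#' @param clinical a [clinical_table()] covering the stratified patients.
#' @param patients patient ids to stratify; defaults to the clinical
#'   table's patients.
#' @param tmb_cutoff mutations/Mb for [classify_tmb()]; `NA` skips the
#'   TMB contingency.
#' @return object of class `pathway_stratification`: `labels`,
#'   `logrank`, `medians`, `tmb_table`, `fisher_p`, `tmb_degenerate`.
#' @export
stratify_by_pathway <- function(alterations, pathway, clinical,
                                patients = NULL, tmb_cutoff = 10.4) {
  if (!length(pathway)) stop_load("pathway gene set must be non-empty")
  patients <- patients %||% clinical$patient_id
  mut <- classify_carriers(alterations, pathway, patients)
  labels <- stats::setNames(factor(ifelse(mut, "MUT", "WT"),
                                   levels = c("WT", "MUT")), patients)
  cl <- clinical[match(patients, clinical$patient_id), , drop = FALSE]
  lr <- NULL; med <- c(MUT = NA_real_, WT = NA_real_)
  if (any(mut) && any(!mut)) {
    a <- cl[mut, ]; b <- cl[!mut, ]
    lr <- logrank_test(a$pfs_months, a$pfs_event, b$pfs_months, b$pfs_event)
    med <- c(MUT = km_median(km_fit(a$pfs_months, a$pfs_event)),
             WT = km_median(km_fit(b$pfs_months, b$pfs_event)))
  }
  tmb_tab <- NULL; fp <- NA_real_; tmb_degen <- NA
  if (!is.na(tmb_cutoff)) {
    tmb_cls <- classify_tmb(alterations, tmb_cutoff)[patients]
    tmb_tab <- table(pathway = labels, tmb = tmb_cls)
    tmb_degen <- any(rowSums(tmb_tab) == 0) || any(colSums(tmb_tab) == 0)
    fp <- if (tmb_degen) 1 else stats::fisher.test(tmb_tab)$p.value
  }
  structure(list(labels = labels, logrank = lr, medians = med,
                 tmb_table = tmb_tab, fisher_p = fp,
                 tmb_degenerate = tmb_degen),
            class = "pathway_stratification")
}

#' @export
print.pathway_stratification <- function(x, ...) {
  cat(sprintf("Pathway stratification: MUT n = %d, WT n = %d\n",
              sum(x$labels == "MUT"), sum(x$labels == "WT")))
  if (!is.null(x$logrank))
    cat(sprintf("  PFS log-rank p = %.4g (medians MUT %s vs WT %s)\n",
                x$logrank$p_value,
                ifelse(is.na(x$medians["MUT"]), "NR", sprintf("%.3g", x$medians["MUT"])),
                ifelse(is.na(x$medians["WT"]), "NR", sprintf("%.3g", x$medians["WT"]))))
  if (!is.null(x$tmb_table))
    cat(sprintf("  TMB-high x pathway Fisher p = %.4g%s\n", x$fisher_p,
                if (isTRUE(x$tmb_degenerate)) " [degenerate margins]" else ""))
  invisible(x)
}

#' Summarize an alteration table
#'
#' Totals by alteration class, distinct altered genes, and the mean
#' number of (deduplicated) alteration records per patient.
#'
#' @param alterations an [alteration_table()].
#' @return list: `by_class`, `n_alterations`, `n_genes`, `n_patients`,
#'   `mean_per_patient`.
#' @export
summarize_alterations <- function(alterations) {
  rec <- alterations$records
  pts <- union(unique(rec$patient_id), names(alterations$tmb))
  list(by_class = table(rec$alteration_class),
       n_alterations = nrow(rec),
       n_genes = length(unique(rec$gene)),
       n_patients = length(pts),
       mean_per_patient = if (length(pts)) nrow(rec) / length(pts) else 0)
}
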