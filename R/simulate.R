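# Seeded synthetic-cohort generator. The generator emulates the
# statistical structure the downstream analyses assume — an MSS/MSI
# cohort with sparse per-class genomic alterations over a few-hundred-
# gene universe, exponential right-censored PFS whose hazard is
# multiplied by planted resistance/sensitivity genes, log-normal TMB
# straddling the 10.4 mut/Mb cutoff, and negative-binomial counts with
# subtype-template mean shifts plus fold-change effects planted between
# prognosis groups — so every stage is testable without restricted
# patient-level data.

#' Configuration for the synthetic cohort
#'
#' Defaults emulate a profiled first-line metastatic colorectal cancer
#' cohort: 55 profiled patients of whom 6 MSI; a 500-gene alteration
#' universe whose per-gene alteration rates are gamma-distributed
#' (shape 0.15, mean 0.0357) — a few near-ubiquitous driver genes and a
#' long tail of rarely hit ones, giving a mean of ~17.9 alterations per
#' patient with classes drawn at the observed SNV/indel/CNV/LOH
#' proportions; baseline exponential PFS with median
#' 10.1 months; administrative censoring at 36 months plus light
#' independent dropout; log-normal TMB with median 6.71 mut/Mb; and a
#' 200-gene negative-binomial expression layer with two subtype classes
#' (25 markers each, 2 log2-unit shift) and 20 DEGs planted at 2 log2
#' units between good- and poor-prognosis halves. Five resistance genes
#' (hazard ratio 4) and five sensitivity genes (hazard ratio 0.25) are
#' planted at 10% marginal carrier prevalence; with those hazard ratios
#' the carriers concentrate in the extreme PFS quartiles, giving
#' roughly 30% carrier prevalence within the relevant tail quartile.
#'
#' @param n_patients cohort size (>= 8).
#' @param msi_fraction fraction of MSI patients; the MSI count is the
#'   rounded product, applied deterministically.
#' @param gene_universe number of genes in the alteration universe.
#' @param background_alteration_rate mean per-gene-per-patient
#'   alteration probability for non-planted genes.
#' @param rate_shape gamma shape of the per-gene rate distribution
#'   (mean `background_alteration_rate`); smaller values concentrate
#'   alterations in fewer recurrent genes. `NULL` gives a homogeneous
#'   rate.
#' @param resistance_hr named numeric vector of hazard ratios (> 1) for
#'   planted resistance genes; `NULL` or empty for none.
#' @param sensitivity_hr named numeric vector of hazard ratios (< 1)
#'   for planted sensitivity genes.
#' @param planted_prevalence carrier prevalence of each planted gene.
#' @param baseline_hazard events/month for a carrier-free patient.
#' @param dropout_hazard independent censoring hazard (events/month).
#' @param admin_censor_time administrative censoring time (months).
#' @param tmb_meanlog,tmb_sdlog log-normal TMB parameters
#'   (mutations/Mb).
#' @param weibull_shape optional Weibull shape; 1 (default) gives the
#'   exponential model.
#' @param expression `NULL` to skip the expression layer, else a list
#'   with `n_genes`, `n_marker_per_class`, `marker_shift` (log2),
#'   `lib_size` (length-2 range), `dispersion`, `n_classes`,
#'   `deg_effect` (log2), `n_deg`.
#' @param seed integer seed; all draws flow from stage-keyed
#'   sub-streams of it.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 55,
                          msi_fraction = 6 / 55,
                          gene_universe = 500,
                          background_alteration_rate = 0.0357,
                          rate_shape = 0.15,
                          resistance_hr = stats::setNames(rep(4, 5), paste0("RESG", 1:5)),
                          sensitivity_hr = stats::setNames(rep(0.25, 5), paste0("SENSG", 1:5)),
                          planted_prevalence = 0.1,
                          baseline_hazard = log(2) / 10.1,
                          dropout_hazard = 0.01,
                          admin_censor_time = 36,
                          tmb_meanlog = log(6.71),
                          tmb_sdlog = 0.85,
                          weibull_shape = 1,
                          expression = list(n_genes = 200, n_marker_per_class = 25,
                                            marker_shift = 2, lib_size = c(1e5, 2e5),
                                            dispersion = 0.15, n_classes = 2,
                                            deg_effect = 2, n_deg = 20),
                          seed = 1L) {
  if (n_patients < 8 || n_patients != round(n_patients))
    stop_load("n_patients must be an integer >= 8")
  check_prob(msi_fraction, "msi_fraction")
  check_prob(background_alteration_rate, "background_alteration_rate")
  check_prob(planted_prevalence, "planted_prevalence")
  if (length(resistance_hr) && (is.null(names(resistance_hr)) ||
                                any(resistance_hr <= 1)))
    stop_load("resistance_hr must be a named vector of hazard ratios > 1")
  if (length(sensitivity_hr) && (is.null(names(sensitivity_hr)) ||
                                 any(sensitivity_hr <= 0 | sensitivity_hr >= 1)))
    stop_load("sensitivity_hr must be a named vector of hazard ratios in (0, 1)")
  planted <- c(names(resistance_hr), names(sensitivity_hr))
  if (anyDuplicated(planted))
    stop_load("a gene cannot be planted as both resistance and sensitivity")
  if (length(planted) > gene_universe)
    stop_load("more planted genes (%d) than the gene universe (%d)",
              length(planted), gene_universe)
  if (baseline_hazard <= 0 || admin_censor_time <= 0 || dropout_hazard < 0 ||
      weibull_shape <= 0)
    stop_load("hazards, censoring time and Weibull shape must be positive")
  if (!is.null(expression)) {
    need <- c("n_genes", "n_marker_per_class", "marker_shift", "lib_size",
              "dispersion", "n_classes", "deg_effect", "n_deg")
    miss <- setdiff(need, names(expression))
    if (length(miss))
      stop_load("expression config missing: %s", paste(miss, collapse = ", "))
    with(expression, {
      if (n_classes * n_marker_per_class + n_deg > n_genes)
        stop_load("markers plus DEGs exceed the expression gene count")
    })
  }
  if (!is.null(rate_shape) && rate_shape <= 0)
    stop_load("rate_shape must be positive (or NULL for a homogeneous rate)")
  structure(list(n_patients = as.integer(n_patients),
                 msi_fraction = msi_fraction, gene_universe = as.integer(gene_universe),
                 background_alteration_rate = background_alteration_rate,
                 rate_shape = rate_shape,
                 resistance_hr = resistance_hr, sensitivity_hr = sensitivity_hr,
                 planted_prevalence = planted_prevalence,
                 baseline_hazard = baseline_hazard, dropout_hazard = dropout_hazard,
                 admin_censor_time = admin_censor_time,
                 tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
                 weibull_shape = weibull_shape,
                 expression = expression, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a synthetic trial cohort
#'
#' Draws, in stage-keyed seeded sub-streams (clinical, alterations,
#' survival, tmb, response, expression — so enabling or reconfiguring
#' one stage never perturbs another's draws): MSI labels for
#' `round(n * msi_fraction)` patients; per-gene Bernoulli alteration
#' indicators (background rate for background genes, the configured
#' prevalence for planted genes) with alteration classes at fixed
#' SNV/indel/CNV/LOH proportions; PFS from a Weibull (default
#' exponential) whose per-patient rate is the baseline times the
#' product of carried planted-gene hazard ratios, censored at the
#' minimum of the administrative time and an independent exponential
#' dropout; log-normal TMB; best responses at fixed category
#' probabilities; and, when enabled, negative-binomial counts with
#' subtype-marker shifts and DEG effects between the top and bottom
#' halves of simulated PFS.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `clinical`
#'   ([clinical_table()]), `alterations` ([alteration_table()]),
#'   `counts` ([count_matrix()] or `NULL`), `ground_truth` (planted
#'   resistance/sensitivity genes, true DEG list, true subtype per
#'   sample, marker genes per class), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  planted <- c(names(config$resistance_hr), names(config$sensitivity_hr))
  n_bg <- config$gene_universe - length(planted)
  genes <- c(planted, sprintf("G%04d", seq_len(n_bg)))

  # clinical covariates -----------------------------------------------------
  set.seed(stage_seed(config$seed, "clinical"))
  n_msi <- round(n * config$msi_fraction)
  msi <- rep("MSS", n)
  msi[sample.int(n, n_msi)] <- "MSI"
  ras <- ifelse(stats::runif(n) < 62 / 73, "mut", "wt")
  braf <- ifelse(ras == "mut", ifelse(stats::runif(n) < 0.02, "mut", "wt"), "mut")

  # alteration indicators ---------------------------------------------------
  set.seed(stage_seed(config$seed, "alterations"))
  bg_rate <- if (is.null(config$rate_shape))
    rep(config$background_alteration_rate, length(genes))
  else pmin(stats::rgamma(length(genes), shape = config$rate_shape,
                          scale = config$background_alteration_rate /
                            config$rate_shape), 0.95)
  prob <- ifelse(genes %in% planted, config$planted_prevalence, bg_rate)
  carrier <- matrix(stats::runif(n * length(genes)) <
                      rep(prob, each = n), nrow = n,
                    dimnames = list(ids, genes))
  idx <- which(carrier, arr.ind = TRUE)
  cls <- sample(ALTERATION_CLASSES, nrow(idx), replace = TRUE,
                prob = c(602, 101, 258, 21) / 982)
  records <- data.frame(patient_id = ids[idx[, 1]], gene = genes[idx[, 2]],
                        alteration_class = cls, stringsAsFactors = FALSE)

  # survival ----------------------------------------------------------------
  set.seed(stage_seed(config$seed, "survival"))
  loghr <- rep(0, n)
  if (length(config$resistance_hr))
    loghr <- loghr + as.numeric(carrier[, names(config$resistance_hr),
                                        drop = FALSE] %*% log(config$resistance_hr))
  if (length(config$sensitivity_hr))
    loghr <- loghr + as.numeric(carrier[, names(config$sensitivity_hr),
                                        drop = FALSE] %*% log(config$sensitivity_hr))
  rate <- config$baseline_hazard * exp(loghr)
  t_event <- if (config$weibull_shape == 1) stats::rexp(n, rate) else
    stats::rweibull(n, shape = config$weibull_shape,
                    scale = (1 / rate)^(1 / config$weibull_shape))
  t_drop <- if (config$dropout_hazard > 0)
    stats::rexp(n, config$dropout_hazard) else rep(Inf, n)
  t_cens <- pmin(t_drop, config$admin_censor_time)
  pfs <- pmin(t_event, t_cens)
  event <- t_event <= t_cens

  # TMB ---------------------------------------------------------------------
  set.seed(stage_seed(config$seed, "tmb"))
  tmb <- stats::rlnorm(n, config$tmb_meanlog, config$tmb_sdlog)

  # best response -----------------------------------------------------------
  set.seed(stage_seed(config$seed, "response"))
  resp <- sample(RESPONSE_LEVELS, n, replace = TRUE,
                 prob = c(7, 49, 15, 0, 2) / 73)

  clinical <- clinical_table(data.frame(
    patient_id = ids, msi_status = msi, ras_status = ras, braf_status = braf,
    pfs_months = pfs, pfs_event = event, best_response = resp,
    stringsAsFactors = FALSE))
  alterations <- alteration_table(records,
                                  stats::setNames(tmb, ids))

  # expression --------------------------------------------------------------
  counts <- NULL; truth_expr <- list()
  ex <- config$expression
  if (!is.null(ex)) {
    set.seed(stage_seed(config$seed, "expression"))
    g <- sprintf("E%04d", seq_len(ex$n_genes))
    subtype <- sample(paste0("class", seq_len(ex$n_classes)), n, replace = TRUE)
    marker_of <- lapply(seq_len(ex$n_classes), function(k)
      g[((k - 1) * ex$n_marker_per_class + 1):(k * ex$n_marker_per_class)])
    names(marker_of) <- paste0("class", seq_len(ex$n_classes))
    deg_genes <- g[(ex$n_classes * ex$n_marker_per_class + 1):
                     (ex$n_classes * ex$n_marker_per_class + ex$n_deg)]
    good <- rank(pfs, ties.method = "first") > n / 2
    base_rel <- stats::rlnorm(ex$n_genes, meanlog = log(50), sdlog = 1)
    lib <- stats::runif(n, ex$lib_size[1], ex$lib_size[2])
    shift <- matrix(0, ex$n_genes, n, dimnames = list(g, ids))
    for (k in names(marker_of)) shift[marker_of[[k]], subtype == k] <-
      shift[marker_of[[k]], subtype == k] + ex$marker_shift
    shift[deg_genes, good] <- shift[deg_genes, good] + ex$deg_effect
    rel <- base_rel * 2^shift
    mu <- t(t(rel) / colSums(rel)) * rep(lib, each = ex$n_genes)
    cm <- matrix(stats::rnbinom(ex$n_genes * n, mu = as.numeric(mu),
                                size = 1 / ex$dispersion),
                 nrow = ex$n_genes, dimnames = list(g, ids))
    counts <- count_matrix(cm)
    truth_expr <- list(subtype = stats::setNames(subtype, ids),
                       marker_genes = marker_of, deg_genes = deg_genes,
                       good_prognosis = stats::setNames(good, ids))
  }

  structure(list(clinical = clinical, alterations = alterations,
                 counts = counts,
                 ground_truth = c(list(
                   resistance_genes = names(config$resistance_hr),
                   sensitivity_genes = names(config$sensitivity_hr),
                   carrier = carrier), truth_expr),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%d MSI), %d alteration records",
              nrow(x$clinical), sum(x$clinical$msi_status == "MSI"),
              nrow(x$alterations$records)))
  if (!is.null(x$counts))
    cat(sprintf(", %d x %d count matrix", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("; seed %d\n", x$config$seed))
  invisible(x)
}

#' Simulate best-response outcomes for a response-rate design
#'
#' Bernoulli responder draws at a true response probability, mapped to
#' `PR` (responder) / `SD` (non-responder) labels; a harness for
#' checking the operating characteristics of minimum-responder rules.
#'
#' @param n number of patients.
#' @param p_true true response probability.
#' @param seed integer seed.
#' @return character vector of best responses, length `n`.
#' @export
simulate_trial_responses <- function(n, p_true, seed = 1L) {
  check_prob(p_true, "p_true")
  set.seed(stage_seed(seed, "trial_responses"))
  ifelse(stats::runif(n) < p_true, "PR", "SD")
}
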