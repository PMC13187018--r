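# End-to-end orchestration: one config drives simulate/load ->
# trial stats -> survival -> signatures -> DEG -> subtype -> enrichment,
# with fail-fast input validation, per-stage status bookkeeping, and a
# manifest sufficient to re-run identically.

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; the top-level keys mirror the arguments of
#'   [run_pipeline()]: `seed`, `out_dir`, `stages` (character vector),
#'   optional `inputs` (paths: clinical, alterations, tmb, counts,
#'   markers, gmt), optional `simulate` (overrides for
#'   [cohort_config()]), optional `thresholds` (tmb_cutoff,
#'   fc_threshold, p_threshold, fdr_threshold, n_permutations).
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_load("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

default_stages <- c("simulate", "trial_stats", "survival", "signatures",
                    "deg", "subtype", "enrich")

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a
#' simulated cohort (stage `"simulate"`) or files named under
#' `inputs`. Input paths for every enabled stage are validated before
#' any computation (fail fast); a stage failure is recorded in the
#' manifest and halts the stages downstream of it. All randomness
#' derives from the single `seed` through stage-keyed sub-streams.
#'
#' @param config a list or [read_run_config()] result; see that
#'   function for the recognized keys. Stages default to all.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return a run manifest (list of class `run_manifest`): per-stage
#'   status and outputs, parameter echo, seed, package version.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- unclass(config)
  stages <- cfg$stages %||% default_stages
  bad <- setdiff(stages, default_stages)
  if (length(bad)) stop_load("unknown stage(s): %s", paste(bad, collapse = ", "))
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% stop_load("out_dir is required")
  th <- cfg$thresholds %||% list()
  tmb_cutoff <- th$tmb_cutoff %||% 10.4
  fc_threshold <- th$fc_threshold %||% 2.5
  p_threshold <- th$p_threshold %||% 0.0128
  fdr_threshold <- th$fdr_threshold %||% 0.05
  n_permutations <- th$n_permutations %||% 1000

  # fail fast: every enabled stage's inputs must be resolvable up front
  inputs <- cfg$inputs %||% list()
  simulate_on <- "simulate" %in% stages
  need_file <- function(key, why) {
    p <- inputs[[key]]
    if (is.null(p) || !file.exists(p))
      stop_load("stage '%s' needs input '%s' (missing or not a file: %s)",
                why, key, p %||% "<unset>")
    p
  }
  if (!simulate_on) {
    if (any(c("trial_stats", "survival", "signatures") %in% stages))
      need_file("clinical", "trial_stats/survival/signatures")
    if ("signatures" %in% stages) need_file("alterations", "signatures")
    if (any(c("deg", "subtype") %in% stages)) need_file("counts", "deg/subtype")
  }
  if ("subtype" %in% stages && !simulate_on) need_file("markers", "subtype")
  if ("enrich" %in% stages && !is.null(inputs$gmt)) need_file("gmt", "enrich")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, out_dir = out_dir,
                   package_version = as.character(utils::packageVersion("trialomics")),
                   parameters = list(tmb_cutoff = tmb_cutoff,
                                     fc_threshold = fc_threshold,
                                     p_threshold = p_threshold,
                                     fdr_threshold = fdr_threshold,
                                     n_permutations = n_permutations),
                   stages = list())
  halted <- FALSE
  note <- function(stage, status, outputs = character(0), detail = NULL) {
    manifest$stages[[stage]] <<- list(status = status, outputs = outputs,
                                      detail = detail)
  }
  run_stage <- function(stage, fun) {
    if (halted) { note(stage, "skipped (upstream failure)"); return(NULL) }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, "failed", detail = conditionMessage(res))
      halted <<- TRUE
      return(NULL)
    }
    res
  }

  env <- new.env()
  if (simulate_on) {
    run_stage("simulate", function() {
      sim_cfg <- do.call(cohort_config,
                         c(cfg$simulate %||% list(), list(seed = seed)))
      env$cohort <- simulate_cohort(sim_cfg)
      man <- rbind(write_results(env$cohort$clinical, out_dir),
                   write_results(env$cohort$alterations, out_dir))
      if (!is.null(env$cohort$counts))
        man <- rbind(man, write_results(env$cohort$counts, out_dir))
      truth <- file.path(out_dir, "ground_truth.tsv")
      write_tsv(data.frame(
        role = c(rep("resistance", length(env$cohort$ground_truth$resistance_genes)),
                 rep("sensitivity", length(env$cohort$ground_truth$sensitivity_genes)),
                 rep("deg", length(env$cohort$ground_truth$deg_genes %||% character(0)))),
        gene = c(env$cohort$ground_truth$resistance_genes,
                 env$cohort$ground_truth$sensitivity_genes,
                 env$cohort$ground_truth$deg_genes %||% character(0))), truth)
      note("simulate", "ok", c(man$file, truth))
      TRUE
    })
  } else if (!halted) {
    run_stage("load", function() {
      if (!is.null(inputs$clinical)) env$cohort$clinical <- read_clinical(inputs$clinical)
      if (!is.null(inputs$alterations))
        env$cohort$alterations <- read_alterations(inputs$alterations, inputs$tmb)
      if (!is.null(inputs$counts)) env$cohort$counts <- read_counts(inputs$counts)
      note("load", "ok")
      TRUE
    })
  }

  if ("trial_stats" %in% stages) run_stage("trial_stats", function() {
    rs <- tabulate_responses(env$cohort$clinical)
    orr <- clopper_pearson(rs$orr_count, rs$n_total)
    dcr <- clopper_pearson(rs$dcr_count, rs$n_total)
    env$trial <- list(summary = rs, orr = orr, dcr = dcr)
    df <- data.frame(measure = c("ORR", "DCR"),
                     count = c(rs$orr_count, rs$dcr_count), n = rs$n_total,
                     pct = round_half_away(100 * c(orr$estimate, dcr$estimate)),
                     ci_lower_pct = round_half_away(100 * c(orr$lower, dcr$lower)),
                     ci_upper_pct = round_half_away(100 * c(orr$upper, dcr$upper)))
    p <- file.path(out_dir, "trial_stats.tsv"); write_tsv(df, p)
    note("trial_stats", "ok", p)
    TRUE
  })

  if ("survival" %in% stages) run_stage("survival", function() {
    cl <- env$cohort$clinical
    groups <- split(seq_len(nrow(cl)), cl$msi_status, drop = TRUE)
    rows <- NULL
    for (g in names(groups)) {
      d <- cl[groups[[g]], ]
      km <- km_fit(d$pfs_months, d$pfs_event)
      rows <- rbind(rows, cbind(group = g, as.data.frame(km)))
      env$survival[[g]] <- km
    }
    p <- file.path(out_dir, "km_curves.tsv"); write_tsv(rows, p)
    note("survival", "ok", p)
    TRUE
  })

  if ("signatures" %in% stages) run_stage("signatures", function() {
    env$signatures <- signature_analysis(env$cohort$clinical,
                                         env$cohort$alterations)
    man <- write_results(env$signatures, out_dir)
    note("signatures", "ok", man$file)
    TRUE
  })

  if ("deg" %in% stages) run_stage("deg", function() {
    if (is.null(env$cohort$counts)) stop("no count matrix available")
    counts <- filter_genes(env$cohort$counts, threshold = 20)
    norm <- log_normalize(counts)
    quart <- assign_quartiles(env$cohort$clinical,
                              intersect(env$cohort$clinical$patient_id,
                                        colnames(norm)))
    qt <- quart$table
    ga <- intersect(qt$patient_id[qt$quartile == "Q4"], colnames(norm))
    gb <- intersect(qt$patient_id[qt$quartile == "Q1"], colnames(norm))
    env$deg <- select_degs(norm, ga, gb, fc_threshold, p_threshold)
    env$norm <- norm
    pcs <- pca_coordinates(norm, 2)
    p1 <- file.path(out_dir, "deg.tsv"); write_tsv(as.data.frame(env$deg), p1)
    p2 <- file.path(out_dir, "pca_scores.tsv")
    write_tsv(data.frame(sample = rownames(pcs$scores), pcs$scores), p2)
    note("deg", "ok", c(p1, p2))
    TRUE
  })

  if ("subtype" %in% stages) run_stage("subtype", function() {
    if (is.null(env$norm)) {
      counts <- filter_genes(env$cohort$counts, threshold = 20)
      env$norm <- log_normalize(counts)
    }
    markers <- if (!is.null(inputs$markers)) read_markers(inputs$markers)
    else {
      truth <- env$cohort$ground_truth
      if (is.null(truth$marker_genes)) stop("no marker table available")
      marker_table(do.call(rbind, lapply(names(truth$marker_genes), function(k)
        data.frame(gene = truth$marker_genes[[k]], class = k, direction = "up"))))
    }
    tpl <- build_templates(markers, "one_vs_rest")
    env$subtype <- ntp_classify(env$norm, tpl, n_permutations,
                                fdr_threshold, seed = seed)
    p <- file.path(out_dir, "subtype_calls.tsv")
    write_tsv(as.data.frame(env$subtype), p)
    note("subtype", "ok", p)
    TRUE
  })

  if ("enrich" %in% stages) run_stage("enrich", function() {
    if (is.null(env$deg)) stop("enrichment needs the DEG stage")
    query <- env$deg$gene[env$deg$selected]
    if (!length(query)) stop("no selected DEGs to enrich")
    sets <- if (!is.null(inputs$gmt)) read_gmt(inputs$gmt)
    else stats::setNames(
      list(env$cohort$ground_truth$deg_genes %||% stop("no gene sets available")),
      "planted_deg")
    env$enrich <- ora(query, sets, universe = env$deg$gene)
    p <- file.path(out_dir, "enrichment.tsv")
    write_tsv(as.data.frame(env$enrich), p)
    note("enrich", "ok", p)
    TRUE
  })

  manifest$results <- as.list(env)
  structure(manifest, class = "run_manifest")
}

#' Human-readable pipeline report
#'
#' Deterministic text summary assembled verbatim from stage outputs:
#' response table with exact confidence limits, signature sizes and
#' stratified medians/p-values, subtype call counts. Incomplete
#' manifests yield a partial report with explicit gaps.
#'
#' @param manifest a [run_pipeline()] manifest.
#' @return character vector of report lines (also printed by
#'   `print()`).
#' @export
pipeline_report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  ln <- c(sprintf("Pipeline report (seed %d)", manifest$seed), "")
  if (!length(manifest$stages)) return(c(ln, "No stages were run."))
  for (s in names(manifest$stages)) {
    st <- manifest$stages[[s]]
    ln <- c(ln, sprintf("stage %-12s %s%s", s, st$status,
                        if (!is.null(st$detail)) paste0(": ", st$detail) else ""))
  }
  r <- manifest$results
  if (!is.null(r$trial)) {
    rs <- r$trial$summary
    ln <- c(ln, "", sprintf(
      "ORR %d/%d = %.1f%% (95%% CI %.1f to %.1f); DCR %d/%d = %.1f%% (95%% CI %.1f to %.1f)",
      rs$orr_count, rs$n_total, round_half_away(100 * r$trial$orr$estimate),
      round_half_away(100 * r$trial$orr$lower), round_half_away(100 * r$trial$orr$upper),
      rs$dcr_count, rs$n_total, round_half_away(100 * r$trial$dcr$estimate),
      round_half_away(100 * r$trial$dcr$lower), round_half_away(100 * r$trial$dcr$upper)))
  }
  if (!is.null(r$signatures)) {
    x <- r$signatures
    fm <- function(ev) sprintf("n %d vs %d, medians %s vs %s, p %s",
                               ev$group_n[1], ev$group_n[2],
                               ifelse(is.na(ev$medians[1]), "NR", sprintf("%.3g", ev$medians[1])),
                               ifelse(is.na(ev$medians[2]), "NR", sprintf("%.3g", ev$medians[2])),
                               if (is.null(ev$logrank)) "NA" else sprintf("%.4g", ev$logrank$p_value))
    ln <- c(ln, "",
            sprintf("RES signature: %d genes; SENS signature: %d genes",
                    length(x$res_genes), length(x$sens_genes)),
            paste0("RES+ vs RES-:        ", fm(x$res_eval)),
            paste0("RES+ w/o Q1 vs RES-: ", fm(x$res_eval_holdout)),
            paste0("SENS+ vs SENS-:      ", fm(x$sens_eval)),
            paste0("SENS+ w/o Q4 vs SENS-: ", fm(x$sens_eval_holdout)))
  }
  if (!is.null(r$deg)) {
    ln <- c(ln, "", sprintf("DEGs selected: %d (%d up, %d down) of %d genes",
                            sum(r$deg$selected),
                            sum(r$deg$selected & r$deg$fold_change > 0),
                            sum(r$deg$selected & r$deg$fold_change < 0),
                            nrow(r$deg)))
  }
  if (!is.null(r$subtype)) {
    tb <- table(r$subtype$label)
    ln <- c(ln, "", paste("Subtype calls:",
                          paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  }
  gaps <- setdiff(default_stages, names(manifest$stages))
  if (length(gaps))
    ln <- c(ln, "", paste("Stages not run:", paste(gaps, collapse = ", ")))
  ln
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(paste(pipeline_report(x), collapse = "\n"), "\n")
  invisible(x)
}
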