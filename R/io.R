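# Readers and writers for the delimited-text formats the pipeline consumes.
# Tab-separated is the canonical dialect (GMT is tab-native); comma is
# accepted via `sep = ","`. All loaders validate into typed objects so the
# analysis modules never see raw files.

RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")
ALTERATION_CLASSES <- c("SNV", "INDEL", "CNV", "LOH")

#' Construct a validated clinical table
#'
#' A clinical table holds one row per enrolled patient: microsatellite
#' status, RAS/BRAF mutational status, right-censored progression-free
#' survival (months plus event flag), and RECIST best response. Missing
#' best response is coded `NE` (not evaluable / no assessment).
#'
#' @param df data frame with columns `patient_id`, `msi_status`
#'   (`MSS`/`MSI`), `ras_status`, `braf_status` (`mut`/`wt`),
#'   `pfs_months`, `pfs_event` (logical or 0/1), `best_response`
#'   (`CR`/`PR`/`SD`/`PD`/`NE`). Extra columns are preserved.
#' @return an object of class `clinical_table` (a data frame).
#' @export
clinical_table <- function(df) {
  req <- c("patient_id", "msi_status", "ras_status", "braf_status",
           "pfs_months", "pfs_event", "best_response")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_load("clinical table is missing column(s): %s", paste(miss, collapse = ", "))
  df$patient_id <- trimws(as.character(df$patient_id))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    stop_load("duplicated patient_id: %s", paste(unique(dup), collapse = ", "))
  check_enum <- function(col, levels) {
    v <- trimws(as.character(df[[col]]))
    v[is.na(v) | v == ""] <- if (col == "best_response") "NE" else NA
    bad <- which(!v %in% levels)
    if (length(bad))
      stop_load("invalid value '%s' in column '%s' (row %d)", v[bad[1]], col, bad[1])
    factor(v, levels = levels)
  }
  df$msi_status  <- check_enum("msi_status", c("MSS", "MSI"))
  df$ras_status  <- check_enum("ras_status", c("mut", "wt"))
  df$braf_status <- check_enum("braf_status", c("mut", "wt"))
  df$best_response <- check_enum("best_response", RESPONSE_LEVELS)
  pfs <- suppressWarnings(as.numeric(df$pfs_months))
  bad <- which(!is.finite(pfs) | pfs < 0)
  if (length(bad))
    stop_load("pfs_months must be finite and non-negative (row %d, value '%s')",
              bad[1], as.character(df$pfs_months[bad[1]]))
  df$pfs_months <- pfs
  ev <- df$pfs_event
  if (is.character(ev)) ev <- ev %in% c("TRUE", "true", "1", "yes")
  df$pfs_event <- as.logical(as.integer(ev) != 0L)
  rownames(df) <- NULL
  # canonical row order: by patient id, so loading is order-insensitive
  df <- df[order(df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("clinical_table", "data.frame"))
}

#' Read a clinical table from delimited text
#'
#' @param path file path.
#' @param sep field delimiter, default tab.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_load("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  clinical_table(df)
}

#' Construct a validated alteration table
#'
#' Holds the deduplicated long-format genomic-alteration records
#' (patient, gene, alteration class among SNV/INDEL/CNV/LOH) together
#' with the per-patient tumor mutational burden (mutations/Mb) side
#' table. Repeated (patient, gene, class) rows collapse to one record.
#'
#' @param records data frame with columns `patient_id`, `gene`,
#'   `alteration_class`.
#' @param tmb optional data frame with columns `patient_id`, `tmb`, or a
#'   named numeric vector. When provided it must cover every patient in
#'   `records`; when `NULL`, TMB-based analyses will refuse to run.
#' @return object of class `alteration_table`: a list with elements
#'   `records` (deduplicated data frame) and `tmb` (named numeric or NULL).
#' @export
alteration_table <- function(records, tmb = NULL) {
  req <- c("patient_id", "gene", "alteration_class")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop_load("alteration records missing column(s): %s", paste(miss, collapse = ", "))
  records$patient_id <- trimws(as.character(records$patient_id))
  records$gene <- trimws(as.character(records$gene))
  cls <- toupper(trimws(as.character(records$alteration_class)))
  bad <- which(!cls %in% ALTERATION_CLASSES)
  if (length(bad))
    stop_load("invalid alteration_class '%s' (row %d); expected one of %s",
              records$alteration_class[bad[1]], bad[1],
              paste(ALTERATION_CLASSES, collapse = "/"))
  records$alteration_class <- factor(cls, levels = ALTERATION_CLASSES)
  records <- unique(records[, req])
  records <- records[order(records$patient_id, records$gene,
                           records$alteration_class), , drop = FALSE]
  rownames(records) <- NULL
  tmb_vec <- NULL
  if (!is.null(tmb)) {
    if (is.data.frame(tmb)) {
      if (!all(c("patient_id", "tmb") %in% names(tmb)))
        stop_load("tmb table needs columns patient_id, tmb")
      tmb_vec <- stats::setNames(as.numeric(tmb$tmb),
                                 trimws(as.character(tmb$patient_id)))
    } else {
      tmb_vec <- as.numeric(tmb)
      names(tmb_vec) <- names(tmb)
    }
    if (any(!is.finite(tmb_vec)) || any(tmb_vec < 0))
      stop_load("tmb values must be finite and >= 0")
    missing_tmb <- setdiff(unique(records$patient_id), names(tmb_vec))
    if (length(missing_tmb))
      stop_load("tmb missing for patient(s): %s", paste(missing_tmb, collapse = ", "))
    tmb_vec <- tmb_vec[order(names(tmb_vec))]
  }
  structure(list(records = records, tmb = tmb_vec), class = "alteration_table")
}

#' Read alteration records (and optional TMB side table) from delimited text
#'
#' @param path path to the long-format records file.
#' @param tmb_path optional path to the per-patient TMB file
#'   (columns `patient_id`, `tmb`).
#' @param sep field delimiter.
#' @return an [alteration_table()].
#' @export
read_alterations <- function(path, tmb_path = NULL, sep = "\t") {
  if (!file.exists(path)) stop_load("file not found: %s", path)
  rec <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  tmb <- NULL
  if (!is.null(tmb_path)) {
    if (!file.exists(tmb_path)) stop_load("file not found: %s", tmb_path)
    tmb <- utils::read.table(tmb_path, header = TRUE, sep = sep, quote = "",
                             stringsAsFactors = FALSE)
  }
  alteration_table(rec, tmb)
}

#' Construct a validated count matrix
#'
#' @param m numeric matrix of non-negative integer read counts with gene
#'   row names and sample column names, both unique.
#' @return object of class `count_matrix` (an integer matrix).
#' @export
count_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_load("count matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(m))) stop_load("duplicated gene ids in count matrix")
  if (anyDuplicated(colnames(m))) stop_load("duplicated sample ids in count matrix")
  if (any(!is.finite(m)) || any(m < 0)) stop_load("counts must be finite and non-negative")
  storage.mode(m) <- "integer"
  structure(m, class = c("count_matrix", class(matrix())))
}

#' Read a gene-by-sample count matrix from delimited text
#'
#' First column holds gene ids; remaining columns one sample each.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_load("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  genes <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  count_matrix(m)
}

#' Construct a validated marker table
#'
#' Marker tables drive subtype-template construction: one row per
#' (gene, subtype class) with a direction, `up` or `down`.
#'
#' @param df data frame with columns `gene`, `class`, `direction`.
#' @return object of class `marker_table` (a data frame).
#' @export
marker_table <- function(df) {
  req <- c("gene", "class", "direction")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_load("marker table missing column(s): %s", paste(miss, collapse = ", "))
  df$gene <- trimws(as.character(df$gene))
  df$class <- trimws(as.character(df$class))
  dir <- tolower(trimws(as.character(df$direction)))
  bad <- which(!dir %in% c("up", "down"))
  if (length(bad))
    stop_load("invalid direction '%s' (row %d)", df$direction[bad[1]], bad[1])
  df$direction <- dir
  key <- paste(df$gene, df$class)
  dupk <- df[duplicated(key), , drop = FALSE]
  if (nrow(dupk))
    stop_load("duplicated (gene, class) marker row: %s / %s",
              dupk$gene[1], dupk$class[1])
  df <- df[order(df$class, df$gene), req]
  rownames(df) <- NULL
  structure(df, class = c("marker_table", "data.frame"))
}

#' Read a subtype marker table from delimited text
#' @param path file path.
#' @param sep field delimiter.
#' @return a [marker_table()].
#' @export
read_markers <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_load("file not found: %s", path)
  marker_table(utils::read.table(path, header = TRUE, sep = sep, quote = "",
                                 stringsAsFactors = FALSE))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one gene per field, all
#' tab-separated. Duplicate genes within a line collapse to one.
#'
#' @param path file path.
#' @return a named list of character vectors of gene symbols, with a
#'   `descriptions` attribute; class `gene_sets`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_load("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    f <- f[nzchar(f) | seq_along(f) <= 2]
    if (length(f) < 3)
      stop_load("GMT parse error at line %d: expected name, description and >= 1 gene", i)
    nm <- f[1]
    if (nm %in% names(sets)) stop_load("duplicated gene-set name '%s' (line %d)", nm, i)
    sets[[nm]] <- unique(f[-(1:2)])
    desc[nm] <- f[2]
  }
  structure(sets, descriptions = desc, class = "gene_sets")
}

#' Write gene sets to GMT format
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- writers -------------------------------------------------------------

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a pipeline product to a directory
#'
#' Dispatches on the product's class and writes one or more
#' tab-separated files with deterministic names and fixed-precision
#' numeric rendering, so re-running on identical inputs reproduces
#' byte-identical outputs.
#'
#' @param x a pipeline product (clinical/alteration/count table,
#'   signature result, data frame, ...).
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return data frame manifest of written files (invisibly for methods).
#' @export
write_results <- function(x, dir, prefix = NULL) UseMethod("write_results")

manifest_row <- function(path, what) data.frame(file = path, what = what,
                                                stringsAsFactors = FALSE)

#' @export
write_results.data.frame <- function(x, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, paste0(prefix %||% "table", ".tsv"))
  write_tsv(as.data.frame(x), p)
  manifest_row(p, class(x)[1])
}

#' @export
write_results.clinical_table <- function(x, dir, prefix = NULL) {
  df <- as.data.frame(x)
  df$pfs_event <- as.integer(df$pfs_event)
  write_results.data.frame(df, dir, prefix %||% "clinical")
}

#' @export
write_results.alteration_table <- function(x, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- prefix %||% "alterations"
  p1 <- file.path(dir, paste0(pre, ".tsv"))
  write_tsv(x$records, p1)
  man <- manifest_row(p1, "alteration_records")
  if (!is.null(x$tmb)) {
    p2 <- file.path(dir, paste0(pre, "_tmb.tsv"))
    write_tsv(data.frame(patient_id = names(x$tmb), tmb = unname(x$tmb)), p2)
    man <- rbind(man, manifest_row(p2, "tmb"))
  }
  man
}

#' @export
write_results.count_matrix <- function(x, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, paste0(prefix %||% "counts", ".tsv"))
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_row(p, "count_matrix")
}

#' @export
write_results.signature_result <- function(x, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- prefix %||% "signature"
  p1 <- file.path(dir, paste0(pre, "_genes.tsv"))
  genes <- rbind(
    if (length(x$res_genes)) data.frame(signature = "RES", gene = sort(x$res_genes)),
    if (length(x$sens_genes)) data.frame(signature = "SENS", gene = sort(x$sens_genes)))
  if (is.null(genes)) genes <- data.frame(signature = character(0), gene = character(0))
  write_tsv(genes, p1)
  p2 <- file.path(dir, paste0(pre, "_patients.tsv"))
  write_tsv(data.frame(patient_id = names(x$res_carrier),
                       quartile = as.character(x$quartiles$table$quartile[
                         match(names(x$res_carrier), x$quartiles$table$patient_id)]),
                       res = ifelse(x$res_carrier, "RES+", "RES-"),
                       sens = ifelse(x$sens_carrier, "SENS+", "SENS-")), p2)
  p3 <- file.path(dir, paste0(pre, "_tests.tsv"))
  write_tsv(signature_tests_df(x), p3)
  rbind(manifest_row(p1, "signature_genes"),
        manifest_row(p2, "signature_patients"),
        manifest_row(p3, "signature_tests"))
}

#' @export
write_results.default <- function(x, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, paste0(prefix %||% "result", ".tsv"))
  df <- tryCatch(as.data.frame(x), error = function(e) NULL)
  if (is.null(df))
    stop_load("no write_results method for class '%s'", class(x)[1])
  write_tsv(df, p)
  manifest_row(p, class(x)[1])
}

#' Write a clinical table (round-trip compatible with [read_clinical()])
#' @param x a `clinical_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  df <- as.data.frame(x)
  df$pfs_event <- as.integer(df$pfs_event)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
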