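# Nearest-template-prediction molecular subtyping with a permutation
# null and an FDR-based unclassified rule, plus template construction
# from signed marker tables (including the pairwise construction used
# for two-class intrinsic subtypes, where a class's up-markers must be
# up in that class AND down in the other).

#' Build subtype templates from a marker table
#'
#' `one_vs_rest` turns each class's own rows into a signed template
#' (+1 up, -1 down). `pairwise_icms` requires exactly two classes and
#' emits two mirrored templates: a gene is a +1 marker of class A only
#' if it is up in A and down in B (and symmetrically a -1 marker if
#' down in A and up in B); genes moving the same way in both classes
#' are excluded.
#'
#' @param markers a [marker_table()] covering at least two classes.
#' @param mode `"one_vs_rest"` or `"pairwise_icms"`.
#' @return list of `subtype_template` objects, each with `class` and a
#'   named `signs` vector (+1/-1 per marker gene).
#' @export
build_templates <- function(markers, mode = c("one_vs_rest", "pairwise_icms")) {
  mode <- match.arg(mode)
  stopifnot(inherits(markers, "marker_table"))
  classes <- unique(markers$class)
  if (length(classes) < 2) stop_load("marker table must cover >= 2 classes")
  # a gene may not carry both signs within one class
  key <- paste(markers$gene, markers$class)
  contra <- unique(markers$gene[duplicated(key) |
                                  duplicated(key, fromLast = TRUE)])
  if (length(contra))
    stop_load("contradictory marker rows for gene(s): %s",
              paste(contra, collapse = ", "))
  mk_template <- function(class, signs) {
    if (length(signs) < 5)
      stop_load("template for class '%s' has %d markers; >= 5 required",
                class, length(signs))
    structure(list(class = class, signs = signs), class = "subtype_template")
  }
  if (mode == "one_vs_rest") {
    lapply(classes, function(cl) {
      rows <- markers[markers$class == cl, ]
      mk_template(cl, stats::setNames(ifelse(rows$direction == "up", 1, -1),
                                      rows$gene))
    })
  } else {
    if (length(classes) != 2)
      stop_load("pairwise_icms mode needs exactly 2 classes (got %d)", length(classes))
    dir_of <- function(cl) stats::setNames(
      markers$direction[markers$class == cl], markers$gene[markers$class == cl])
    dA <- dir_of(classes[1]); dB <- dir_of(classes[2])
    shared <- intersect(names(dA), names(dB))
    up_in_A <- shared[dA[shared] == "up" & dB[shared] == "down"]
    dn_in_A <- shared[dA[shared] == "down" & dB[shared] == "up"]
    signsA <- stats::setNames(c(rep(1, length(up_in_A)), rep(-1, length(dn_in_A))),
                              c(up_in_A, dn_in_A))
    list(mk_template(classes[1], signsA), mk_template(classes[2], -signsA))
  }
}

#' @export
print.subtype_template <- function(x, ...) {
  cat(sprintf("subtype template '%s': %d markers (%d up, %d down)\n",
              x$class, length(x$signs), sum(x$signs > 0), sum(x$signs < 0)))
  invisible(x)
}

# Similarity of each sample's expression over `genes` to the signed
# template. The sample vector is centered (and implicitly scaled by its
# norm) within the sample, so the result is invariant to per-sample
# affine rescaling of expression. "pearson" additionally centers the
# sign vector; for a single-signed template (zero sign variance) the
# uncentered cosine form is used, which stays well defined.
template_similarity <- function(x, genes, signs, similarity) {
  v <- x[genes, , drop = FALSE]
  vc <- sweep(v, 2, colMeans(v))
  denom_v <- sqrt(colSums(vc^2))
  s <- if (similarity == "pearson" && stats::sd(signs) > 0)
    signs - mean(signs) else signs
  out <- as.numeric(crossprod(vc, s)) / (denom_v * sqrt(sum(s^2)))
  out[denom_v == 0] <- NA_real_
  out
}

#' Nearest-template-prediction subtype classification
#'
#' Each sample's normalized expression, restricted to the union of the
#' templates' marker genes and standardized within the sample, is
#' correlated with each template's sign vector (its +1/-1 markers,
#' zero on the other templates' genes); the best-matching class is
#' called. Computing over the union makes a single-signed template a
#' contrast of its markers against the other classes'. Significance
#' comes from a permutation null: the sign vector is applied to
#' `n_permutations` random gene subsets of the same size drawn (seeded)
#' from the matrix's gene universe, and `p = (1 + #{perm >= obs}) /
#' (n_permutations + 1)`, so p is floored at `1/(n_permutations + 1)`.
#' Best-class p-values are Benjamini-Hochberg adjusted across samples
#' and a sample is left `UNCLASSIFIED` when its FDR is at or above
#' `fdr_threshold`. Constant-expression samples are `UNCLASSIFIED` with
#' a warning. The same seeded permutation subsets serve every sample,
#' so permuting sample order permutes the output rows identically.
#'
#' @param norm a [log_normalize()] matrix (genes x samples).
#' @param templates list of templates from [build_templates()]. At
#'   least half of each template's genes must be present in the matrix.
#' @param n_permutations number of random gene subsets (>= 100,
#'   default 1000).
#' @param fdr_threshold unclassified cutoff on the FDR (default 0.05).
#' @param similarity `"pearson"` (default) or `"cosine"`; both are
#'   computed on per-sample standardized expression and are invariant
#'   to affine rescaling of a sample.
#' @param seed integer seed for the permutation draws.
#' @return data frame of class `subtype_calls`: sample, best_class,
#'   one similarity column per class, p_value, fdr, label (class or
#'   `"UNCLASSIFIED"`).
#' @export
ntp_classify <- function(norm, templates, n_permutations = 1000,
                         fdr_threshold = 0.05,
                         similarity = c("pearson", "cosine"), seed = 1L) {
  similarity <- match.arg(similarity)
  if (n_permutations < 100) stop_load("n_permutations must be >= 100")
  x <- unclass(norm)
  universe <- rownames(x)
  classes <- vapply(templates, `[[`, character(1), "class")
  # similarities are computed over the union of all templates' measured
  # genes, a template's signs extended by zeros elsewhere: per-sample
  # centering then contrasts a class's markers against the other
  # classes' markers, so single-signed templates stay informative
  for (tpl in templates) {
    present <- sum(names(tpl$signs) %in% universe)
    if (present < length(tpl$signs) / 2)
      stop_load("class '%s': only %d of %d template genes present (< 50%%)",
                tpl$class, present, length(tpl$signs))
  }
  feat <- sort(unique(unlist(lapply(templates, function(t)
    intersect(names(t$signs), universe)))))
  k <- length(feat)
  sims <- matrix(NA_real_, ncol(x), length(templates),
                 dimnames = list(colnames(x), classes))
  perm_ge <- matrix(0L, ncol(x), length(templates))
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    signs <- stats::setNames(numeric(k), feat)
    hit <- intersect(names(tpl$signs), feat)
    signs[hit] <- tpl$signs[hit]
    signs <- unname(signs)
    obs <- template_similarity(x, feat, signs, similarity)
    sims[, ti] <- obs
    set.seed(stage_seed(seed, paste0("ntp/", tpl$class)))
    for (p in seq_len(n_permutations)) {
      idx <- sample.int(length(universe), k)
      s <- template_similarity(x, universe[idx], signs, similarity)
      perm_ge[, ti] <- perm_ge[, ti] + as.integer(!is.na(s) & !is.na(obs) & s >= obs)
    }
  }
  best <- apply(sims, 1, function(r) if (all(is.na(r))) NA_integer_ else which.max(r))
  n <- ncol(x)
  p_best <- rep(NA_real_, n); sim_best <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(best[i])) {
      p_best[i] <- (1 + perm_ge[i, best[i]]) / (n_permutations + 1)
      sim_best[i] <- sims[i, best[i]]
    }
  }
  if (anyNA(best))
    warning("constant-expression sample(s) left UNCLASSIFIED: ",
            paste(colnames(x)[is.na(best)], collapse = ", "))
  fdr <- rep(NA_real_, n)
  ok <- !is.na(p_best)
  fdr[ok] <- bh_adjust(p_best[ok])
  label <- ifelse(is.na(best) | fdr >= fdr_threshold, "UNCLASSIFIED",
                  classes[best])
  out <- data.frame(sample = colnames(x),
                    best_class = ifelse(is.na(best), NA_character_, classes[best]),
                    similarity = sim_best, p_value = p_best, fdr = fdr,
                    label = label, row.names = NULL, stringsAsFactors = FALSE)
  out <- cbind(out, stats::setNames(as.data.frame(sims),
                                    paste0("sim_", classes)))
  structure(out, fdr_threshold = fdr_threshold,
            n_permutations = n_permutations, seed = seed,
            class = c("subtype_calls", "data.frame"))
}

#' @export
print.subtype_calls <- function(x, ...) {
  cat(sprintf("NTP subtype calls (%d permutations, FDR < %.3g):\n",
              attr(x, "n_permutations"), attr(x, "fdr_threshold")))
  print(table(x$label))
  invisible(x)
}

#' Carrier-stratified survival within molecular subtypes
#'
#' For each non-`UNCLASSIFIED` subtype class, compares the survival of
#' carrier (+) and non-carrier (-) patients by log-rank with per-arm
#' Kaplan-Meier medians; classes with fewer than two patients per arm
#' are flagged degenerate. Without carrier flags, each class's overall
#' curve and all pairwise between-class log-rank tests are returned
#' instead.
#'
#' @param calls a [ntp_classify()] result whose sample ids match
#'   `clinical$patient_id`.
#' @param clinical a [clinical_table()].
#' @param flags optional named logical carrier vector (e.g. RES+ from
#'   [classify_carriers()]).
#' @return list of class `subtype_survival` keyed by class label.
#' @export
subtype_survival <- function(calls, clinical, flags = NULL) {
  stopifnot(inherits(calls, "subtype_calls"), inherits(clinical, "clinical_table"))
  classes <- setdiff(unique(calls$label), "UNCLASSIFIED")
  cl_of <- function(ids) clinical[match(ids, clinical$patient_id), , drop = FALSE]
  out <- list()
  if (!is.null(flags)) {
    for (cls in classes) {
      ids <- intersect(calls$sample[calls$label == cls], names(flags))
      pos <- ids[flags[ids]]; neg <- ids[!flags[ids]]
      if (length(pos) < 2 || length(neg) < 2) {
        out[[cls]] <- list(degenerate = TRUE,
                           n = c(pos = length(pos), neg = length(neg)))
        next
      }
      a <- cl_of(pos); b <- cl_of(neg)
      out[[cls]] <- list(
        degenerate = FALSE, n = c(pos = length(pos), neg = length(neg)),
        medians = c(pos = km_median(km_fit(a$pfs_months, a$pfs_event)),
                    neg = km_median(km_fit(b$pfs_months, b$pfs_event))),
        logrank = logrank_test(a$pfs_months, a$pfs_event,
                               b$pfs_months, b$pfs_event))
    }
  } else {
    for (cls in classes) {
      d <- cl_of(calls$sample[calls$label == cls])
      out[[cls]] <- list(curve = km_fit(d$pfs_months, d$pfs_event),
                         n = nrow(d))
    }
    if (length(classes) > 1) {
      pw <- list()
      cmb <- utils::combn(classes, 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cl_of(calls$sample[calls$label == cmb[1, j]])
        b <- cl_of(calls$sample[calls$label == cmb[2, j]])
        pw[[paste(cmb[1, j], cmb[2, j], sep = "_vs_")]] <-
          logrank_test(a$pfs_months, a$pfs_event, b$pfs_months, b$pfs_event)
      }
      attr(out, "pairwise") <- pw
    }
  }
  structure(out, class = "subtype_survival")
}
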