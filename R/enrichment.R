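# Over-representation analysis of gene lists against user-supplied gene
# sets, with Benjamini-Hochberg adjustment.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`:
#' adjusted values are returned in the input order, capped at 1, and
#' monotone in the raw p-values.
#'
#' @param p numeric vector of p-values between 0 and 1.
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_load("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query list within
#' a gene universe: one-sided hypergeometric tail
#' `P(overlap >= observed)`, Benjamini-Hochberg adjusted across all
#' tested sets. Sets are intersected with the universe before testing;
#' query genes outside the universe are an error.
#'
#' @param query character vector of genes of interest (subset of
#'   `universe`).
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe character vector of measured genes (e.g. the
#'   post-filter gene ids of the count matrix).
#' @return data frame of class `enrichment_result`: set, overlap,
#'   set_size, query_size, universe_size, p_value, p_adjusted; sorted
#'   by p-value.
#' @export
ora <- function(query, collection, universe) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query) || !length(universe))
    stop_load("query and universe must be non-empty")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_load("query gene(s) outside the universe: %s",
              paste(utils::head(outside, 5), collapse = ", "))
  if (!length(collection)) stop_load("empty gene-set collection")
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), length(universe) - length(s),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = length(query),
               universe_size = length(universe), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation: %d sets tested, %d with adjusted p < 0.05\n",
              nrow(x), sum(x$p_adjusted < 0.05)))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}
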