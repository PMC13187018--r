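# Filtering, TMM factors, normalization, PCA, and DEG selection.

toy_counts <- function(m) {
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  count_matrix(m)
}

test_that("gene filtering removes all-zero and sub-threshold genes, boundary retained", {
  m <- toy_counts(rbind(c(0L, 0L, 0L),      # all zero
                        c(10L, 5L, 4L),     # total 19 < 20
                        c(10L, 5L, 5L),     # total 20, retained
                        c(100L, 0L, 0L)))
  f <- filter_genes(m, 20, "total")
  expect_equal(rownames(f), c("g03", "g04"))
  # max mode: g04 has a sample at 100
  f2 <- filter_genes(m, 20, "max")
  expect_equal(rownames(f2), "g04")
  # idempotent
  expect_equal(unclass(filter_genes(f, 20, "total")), unclass(f))
  expect_error(filter_genes(m, 1000), "every gene")
})

test_that("TMM factors are 1 for identical and for depth-only-scaled samples", {
  set.seed(3)
  base <- as.integer(rnbinom(50, mu = 100, size = 5)) + 1L
  m <- toy_counts(cbind(base, base, base))
  expect_equal(unname(tmm_factors(m)), rep(1, 3), tolerance = 1e-9)
  # doubling depth is not composition bias
  m2 <- toy_counts(cbind(base, 2L * base))
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-9)
})

test_that("TMM matches the hand trimmed-weighted-mean oracle on small toys", {
  # 6-gene toy with one dominant gene that the M-trim removes
  m <- toy_counts(cbind(a = c(1000L, 500L, 200L, 100L, 50L, 25L),
                        b = c(1000L, 500L, 200L, 100L, 50L, 5000L)))
  f <- tmm_factors(m)
  raw <- tmm_oracle(unclass(m), ref_col = 1, sample_col = 2)
  expect_equal(unname(f), c(1 / sqrt(raw), sqrt(raw)), tolerance = 1e-8)
  # a larger random instance against the same oracle
  set.seed(7)
  r <- matrix(as.integer(rnbinom(40, mu = 200, size = 3)) + 1L, ncol = 2)
  m3 <- toy_counts(r)
  # reference = column whose upper-quartile fraction is closest to the mean
  f75 <- apply(r, 2, function(x) stats::quantile(x, 0.75)) / colSums(r)
  ref <- which.min(abs(f75 - mean(f75)))
  other <- 3 - ref
  raw3 <- tmm_oracle(r, ref_col = ref, sample_col = other)
  f3 <- tmm_factors(m3)
  expect_equal(unname(f3[other] / f3[ref]), raw3, tolerance = 1e-8)
  expect_equal(prod(f3), 1, tolerance = 1e-9)   # geometric mean 1
})

test_that("TMM factors are invariant to sample order and flag degenerate samples", {
  set.seed(9)
  m <- matrix(as.integer(rnbinom(60, mu = 150, size = 4)) + 1L, ncol = 3,
              dimnames = list(sprintf("g%02d", 1:20), c("x", "y", "z")))
  f <- tmm_factors(count_matrix(m))
  f_perm <- tmm_factors(count_matrix(m[, c(3, 1, 2)]))
  expect_equal(f_perm[names(f)], f, tolerance = 1e-12)
  # degenerate: a sample with a single expressed gene
  m[, 3] <- 0L; m[1, 3] <- 500L
  expect_warning(fd <- tmm_factors(count_matrix(m)), "degenerate")
  expect_equal(unname(fd["z"]), 1)
})

test_that("log normalization follows log2(CPM + 1) with effective library sizes", {
  m <- toy_counts(rbind(c(0L, 10L), c(100L, 90L)))
  norm <- log_normalize(m, factors = c(1, 1))
  expect_equal(norm[1, 1], 0)                       # zero count -> log2(1)
  expect_equal(norm[2, 1], log2(100 * 1e6 / 100 + 1))
  expect_equal(norm[1, 2], log2(10 * 1e6 / 100 + 1))
  expect_equal(dim(norm), dim(m))
  # doubling a library at fixed factor halves its CPM
  m2 <- toy_counts(rbind(c(0L, 20L), c(100L, 180L)))
  norm2 <- log_normalize(m2, factors = c(1, 1))
  expect_equal(2^norm2[1, 2] - 1, (2^norm[1, 2] - 1), tolerance = 1e-12)
})

test_that("PCA coordinates: duplicates coincide, rank-1 structure is captured, sign fixed", {
  set.seed(5)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  x[, 6] <- x[, 5]                                   # duplicated sample
  norm <- structure(x, class = c("normalized_matrix", "matrix", "array"))
  pc <- pca_coordinates(norm, 2)
  expect_equal(pc$scores[5, ], pc$scores[6, ], tolerance = 1e-10)
  # deterministic sign: the largest-magnitude loading is positive
  for (j in 1:2)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # rank-1: outer product -> first component carries all variance
  u <- rnorm(10); v <- rnorm(6)
  r1 <- structure(outer(u, v, `*`) + 5,
                  dimnames = dimnames(x),
                  class = c("normalized_matrix", "matrix", "array"))
  pc1 <- pca_coordinates(r1, 2)
  expect_equal(pc1$variance_fraction[1], 1, tolerance = 1e-10)
  # two samples -> one informative component
  two <- structure(x[, 1:2], class = c("normalized_matrix", "matrix", "array"))
  pc2 <- pca_coordinates(two, 1)
  expect_equal(pc2$variance_fraction[1], 1, tolerance = 1e-10)
  # constant matrix refused
  cm <- structure(matrix(3, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4))),
                  class = c("normalized_matrix", "matrix", "array"))
  expect_error(pca_coordinates(cm, 1), "zero variance")
})

test_that("DEG selection: pooled t matches the closed form; boundaries are strict", {
  x <- rbind(flat = rep(5, 6),
             hit = c(10, 10.2, 9.8, 3, 3.2, 2.8))
  colnames(x) <- paste0("s", 1:6)
  norm <- structure(x, class = c("normalized_matrix", "matrix", "array"))
  deg <- select_degs(norm, paste0("s", 1:3), paste0("s", 4:6))
  # closed form on the 6 numbers
  a <- x["hit", 1:3]; b <- x["hit", 4:6]
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(deg$t[deg$gene == "hit"], t_hand, tolerance = 1e-10)
  expect_equal(deg$p_value[deg$gene == "hit"],
               2 * pt(abs(t_hand), 4, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(deg$selected[deg$gene == "hit"])
  # identical means -> zero variance, p = 1, never selected
  expect_equal(deg$p_value[deg$gene == "flat"], 1)
  expect_false(deg$selected[deg$gene == "flat"])
  # fold change exactly at the threshold is excluded (strict >):
  # set the threshold to the computed fold change itself
  fc_hit <- deg$fold_change[deg$gene == "hit"]
  at_thr <- select_degs(norm, paste0("s", 1:3), paste0("s", 4:6),
                        fc_threshold = abs(fc_hit))
  expect_false(at_thr$selected[at_thr$gene == "hit"])
  just_below <- select_degs(norm, paste0("s", 1:3), paste0("s", 4:6),
                            fc_threshold = abs(fc_hit) - 1e-9)
  expect_true(just_below$selected[just_below$gene == "hit"])
  # down-regulation carries the minus-reciprocal convention
  down <- select_degs(norm, paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(down$fold_change[down$gene == "hit"], -fc_hit, tolerance = 1e-12)
})

test_that("planted DEGs are recovered at the configured thresholds", {
  co <- simulate_cohort(cohort_config(seed = 2))
  counts <- filter_genes(co$counts, 20)
  norm <- log_normalize(counts)
  good <- names(co$ground_truth$good_prognosis)[co$ground_truth$good_prognosis]
  poor <- names(co$ground_truth$good_prognosis)[!co$ground_truth$good_prognosis]
  deg <- select_degs(norm, good, poor)
  truth <- intersect(co$ground_truth$deg_genes, deg$gene)
  sens <- mean(deg$selected[deg$gene %in% truth])
  fpr <- mean(deg$selected[!deg$gene %in% truth])
  expect_gt(sens, 0.8)
  expect_lt(fpr, 0.05)
})
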