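# Template construction and nearest-template-prediction classification.

toy_markers <- function() {
  marker_table(data.frame(
    gene = c(paste0("up2_", 1:6), paste0("up3_", 1:6),
             paste0("up2_", 1:6), paste0("up3_", 1:6), "both_up", "both_up"),
    class = c(rep("iCMS2", 6), rep("iCMS3", 6),
              rep("iCMS3", 6), rep("iCMS2", 6), "iCMS2", "iCMS3"),
    direction = c(rep("up", 6), rep("up", 6),
                  rep("down", 6), rep("down", 6), "up", "up")))
}

test_that("pairwise template construction keeps only discordant genes", {
  tpl <- build_templates(toy_markers(), "pairwise_icms")
  expect_length(tpl, 2)
  t2 <- tpl[[which(vapply(tpl, `[[`, "", "class") == "iCMS2")]]
  t3 <- tpl[[which(vapply(tpl, `[[`, "", "class") == "iCMS3")]]
  # up in iCMS2 AND down in iCMS3 -> +1 in the iCMS2 template
  expect_true(all(t2$signs[paste0("up2_", 1:6)] == 1))
  expect_true(all(t2$signs[paste0("up3_", 1:6)] == -1))
  # mirrored template
  expect_equal(t3$signs[names(t2$signs)], -t2$signs)
  # up in both classes -> excluded from both
  expect_false("both_up" %in% names(t2$signs))
  expect_false("both_up" %in% names(t3$signs))
})

test_that("template construction rejects contradictions and tiny classes", {
  bad <- data.frame(gene = c("G1", "G1", paste0("x", 1:5), paste0("y", 1:5)),
                    class = c("A", "A", rep("A", 5), rep("B", 5)),
                    direction = c("up", "down", rep("up", 5), rep("up", 5)))
  expect_error(marker_table(bad), "duplicated")
  ok <- marker_table(data.frame(gene = c(paste0("x", 1:5), paste0("y", 1:3)),
                                class = c(rep("A", 5), rep("B", 3)),
                                direction = "up"))
  expect_error(build_templates(ok, "one_vs_rest"), ">= 5")
  one_class <- marker_table(data.frame(gene = paste0("x", 1:5),
                                       class = "A", direction = "up"))
  expect_error(build_templates(one_class, "one_vs_rest"), ">= 2 classes")
})

mk_norm <- function(x) structure(x, class = c("normalized_matrix", "matrix", "array"))

ntp_fixture <- function(n_noise = 3, seed = 99) {
  tpl <- build_templates(toy_markers(), "pairwise_icms")
  genes <- c(names(tpl[[1]]$signs), paste0("bg", 1:40))
  set.seed(seed)
  x <- matrix(rnorm(length(genes) * (n_noise + 2)), nrow = length(genes),
              dimnames = list(genes, c("exact2", "exact3",
                                       paste0("noise", seq_len(n_noise)))))
  x[, "exact2"] <- 0; x[names(tpl[[1]]$signs), "exact2"] <- tpl[[1]]$signs
  x[, "exact3"] <- 0; x[names(tpl[[2]]$signs), "exact3"] <- tpl[[2]]$signs
  list(tpl = tpl, norm = mk_norm(x))
}

test_that("template-exact samples score similarity 1 and are never unclassified", {
  fx <- ntp_fixture()
  calls <- ntp_classify(fx$norm, fx$tpl, n_permutations = 200, seed = 4)
  e2 <- calls[calls$sample == "exact2", ]
  e3 <- calls[calls$sample == "exact3", ]
  expect_equal(e2$best_class, "iCMS2")
  expect_equal(e3$best_class, "iCMS3")
  expect_equal(e2$similarity, 1, tolerance = 1e-12)
  expect_equal(e3$similarity, 1, tolerance = 1e-12)
  expect_equal(e2$p_value, 1 / 201)          # p floor convention
  expect_false(e2$label == "UNCLASSIFIED")
  expect_false(e3$label == "UNCLASSIFIED")
})

test_that("classification is seed-deterministic and sample-order equivariant", {
  fx <- ntp_fixture()
  a <- ntp_classify(fx$norm, fx$tpl, n_permutations = 150, seed = 8)
  b <- ntp_classify(fx$norm, fx$tpl, n_permutations = 150, seed = 8)
  expect_identical(a, b)
  perm <- c(3, 1, 5, 2, 4)
  c2 <- ntp_classify(mk_norm(unclass(fx$norm)[, perm]), fx$tpl,
                     n_permutations = 150, seed = 8)
  expect_equal(c2[match(a$sample, c2$sample), ], a,
               ignore_attr = "row.names")
})

test_that("similarity is invariant to affine rescaling of one sample's expression", {
  fx <- ntp_fixture()
  x2 <- unclass(fx$norm)
  x2[, "noise1"] <- 3 + 7 * x2[, "noise1"]
  a <- ntp_classify(fx$norm, fx$tpl, n_permutations = 120, seed = 2)
  b <- ntp_classify(mk_norm(x2), fx$tpl, n_permutations = 120, seed = 2)
  expect_equal(b$similarity, a$similarity, tolerance = 1e-10)
  expect_equal(b$p_value, a$p_value)
})

test_that("permutation p equals the exact fraction from replaying the seeded stream", {
  fx <- ntp_fixture(n_noise = 2)
  x <- unclass(fx$norm)
  n_perm <- 120
  calls <- ntp_classify(fx$norm, fx$tpl, n_permutations = n_perm, seed = 6)
  # independent replay of the same seeded draws for one template
  tpl1 <- fx$tpl[[1]]
  universe <- rownames(x)
  feat <- sort(unique(unlist(lapply(fx$tpl, function(t)
    intersect(names(t$signs), universe)))))
  signs <- stats::setNames(numeric(length(feat)), feat)
  signs[names(tpl1$signs)] <- tpl1$signs
  simfun <- function(genes) {
    v <- x[genes, , drop = FALSE]
    apply(v, 2, function(col) {
      vc <- col - mean(col)
      sc <- unname(signs) - mean(signs)
      sum(vc * sc) / sqrt(sum(vc^2) * sum(sc^2))
    })
  }
  obs <- simfun(feat)
  set.seed(trialomics:::stage_seed(6, paste0("ntp/", tpl1$class)))
  ge <- numeric(ncol(x))
  for (p in seq_len(n_perm)) {
    idx <- sample.int(length(universe), length(feat))
    s <- simfun(universe[idx])
    ge <- ge + (!is.na(s) & s >= obs)
  }
  p_hand <- (1 + ge) / (n_perm + 1)
  for (smp in colnames(x)) {
    row <- calls[calls$sample == smp, ]
    if (row$best_class == tpl1$class)
      expect_equal(row$p_value, unname(p_hand[smp]), tolerance = 1e-12)
  }
})

test_that("pure-noise samples are left unclassified in most seeded replicates", {
  fx <- ntp_fixture(n_noise = 8)
  unc <- 0; tot <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    x <- unclass(fx$norm)
    noise <- grepl("^noise", colnames(x))
    x[, noise] <- rnorm(sum(noise) * nrow(x))
    calls <- ntp_classify(mk_norm(x[, noise]), fx$tpl,
                          n_permutations = 150, seed = s)
    unc <- unc + sum(calls$label == "UNCLASSIFIED")
    tot <- tot + nrow(calls)
  }
  expect_gte(unc / tot, 0.9)
})

test_that("constant-expression samples warn and come back unclassified", {
  fx <- ntp_fixture(n_noise = 1)
  x <- unclass(fx$norm)
  x[, "noise1"] <- 5
  expect_warning(calls <- ntp_classify(mk_norm(x), fx$tpl,
                                       n_permutations = 100, seed = 3),
                 "constant")
  expect_equal(calls$label[calls$sample == "noise1"], "UNCLASSIFIED")
  expect_true(is.na(calls$similarity[calls$sample == "noise1"]))
})

test_that("carrier-stratified survival within subtype classes matches the oracle", {
  cl <- toy_clinical(10, pfs = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15))
  calls <- structure(data.frame(sample = cl$patient_id,
                                best_class = rep(c("A", "B"), each = 5),
                                similarity = 1, p_value = 0.001, fdr = 0.001,
                                label = rep(c("A", "B"), each = 5)),
                     fdr_threshold = 0.05, n_permutations = 100,
                     class = c("subtype_calls", "data.frame"))
  flags <- stats::setNames(rep(c(TRUE, FALSE), 5), cl$patient_id)
  ss <- subtype_survival(calls, cl, flags)
  expect_named(ss, c("A", "B"))
  # class A: + = P01,P03,P05 (times 1,3,5), - = P02,P04 (2,4)
  or <- logrank_oracle(c(1, 3, 5), rep(TRUE, 3), c(2, 4), rep(TRUE, 2))
  expect_equal(ss$A$logrank$chi_square, or$chi_square, tolerance = 1e-10)
  # degenerate class: < 2 per arm
  flags2 <- flags; flags2[c("P01", "P03", "P05")] <- c(TRUE, FALSE, FALSE)
  flags2["P02"] <- FALSE; flags2["P04"] <- FALSE
  ss2 <- subtype_survival(calls, cl, flags2)
  expect_true(ss2$A$degenerate)
})
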