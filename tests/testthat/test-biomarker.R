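test_that("indval identifies perfect and indifferent indicators", {
  # present in every case sample, absent from all controls
  m <- cbind(c1 = c(0.6, 0.4), c2 = c(0.5, 0.5),
             k1 = c(0, 1), k2 = c(0, 1))
  rownames(m) <- c("perfect", "filler")
  st <- toy_study(m, groups = c(c1 = "case", c2 = "case",
                                k1 = "control", k2 = "control"))
  iv <- indval(st, n_perm = 99, seed = 1)
  row <- iv[iv$species == "perfect", ]
  expect_equal(row$A, 1)
  expect_equal(row$B, 1)
  expect_equal(row$indval, 1)
  expect_equal(row$group, "case")

  # identical mean abundance and full presence in both groups
  m2 <- cbind(c1 = c(0.3, 0.7), c2 = c(0.3, 0.7),
              k1 = c(0.3, 0.7), k2 = c(0.3, 0.7))
  rownames(m2) <- c("even", "filler")
  st2 <- toy_study(m2, groups = c(c1 = "case", c2 = "case",
                                  k1 = "control", k2 = "control"))
  iv2 <- indval(st2, n_perm = 99, seed = 1)
  expect_equal(iv2$A[iv2$species == "even"], 0.5)
  expect_equal(iv2$B[iv2$species == "even"], 1)
  expect_equal(iv2$indval[iv2$species == "even"], 0.5)
})

test_that("indval is scale invariant and detects a planted enrichment", {
  st <- make_case_control(study_design(n_case = 13, n_control = 9, seed = 51))
  iv1 <- suppressMessages(indval(st, n_perm = 199, seed = 2))

  st_scaled <- st
  st_scaled$matrix <- st$matrix * 7
  class(st_scaled) <- "abundance_study"
  iv2 <- suppressMessages(indval(st_scaled, n_perm = 199, seed = 2))
  expect_equal(iv1$indval, iv2$indval, tolerance = 1e-12)

  expect_lt(iv1$p[iv1$species == "Malassezia_globosa"], 0.05)
  expect_equal(iv1$group[iv1$species == "Malassezia_globosa"], "case")
})

test_that("indval p-values are near-uniform under the null", {
  set.seed(52)
  ps <- replicate(300, {
    m <- matrix(runif(10 * 20), nrow = 10,
                dimnames = list(paste0("sp", 1:10), paste0("s", 1:20)))
    m <- sweep(m, 2, colSums(m), "/")
    st <- toy_study(m, groups = setNames(rep(c("a", "b"), each = 10),
                                         colnames(m)))
    iv <- indval(st, n_perm = 99)
    iv$p[iv$species == "sp1"]  # a fixed species, not the post-hoc maximum
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("lefse_lite scores scaled mean differences for KW survivors", {
  # planted difference: 0.1 vs 0.001 -> scaled means 1e5 vs 1e3
  x <- c(rep(0.1, 6), rep(0.001, 6)) + rep(c(0, 1e-5, -1e-5), 4)
  m <- rbind(diff_taxon = x, filler = 1 - x)
  colnames(m) <- paste0("s", 1:12)
  st <- toy_study(m, groups = setNames(rep(c("case", "control"), each = 6),
                                       colnames(m)))
  ef <- lefse_lite(st)
  row <- ef[ef$species == "diff_taxon", ]
  expect_equal(row$enriched_group, "case")
  expect_equal(row$lda_like_score, log10(abs(0.1 - 0.001) * 1e6 + 1),
               tolerance = 1e-3)

  # identical distributions are excluded
  m2 <- rbind(const = rep(0.4, 12), rest = rep(0.6, 12))
  colnames(m2) <- paste0("s", 1:12)
  st2 <- toy_study(m2, groups = setNames(rep(c("case", "control"), each = 6),
                                         colnames(m2)))
  expect_equal(nrow(lefse_lite(st2)), 0L)
})

test_that("the planted enriched fungus attains the top effect size", {
  st <- make_case_control(study_design(seed = 53))
  ef <- lefse_lite(st)
  expect_equal(ef$species[1], "Malassezia_globosa")
  expect_equal(ef$enriched_group[1], "case")
  expect_true(all(ef$kw_p < 0.05))
})

test_that("random-forest importance ranks a separating feature first", {
  set.seed(54)
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 30
    m <- matrix(runif(50 * n), nrow = 50,
                dimnames = list(paste0("sp", sprintf("%02d", 1:50)),
                                paste0("s", 1:n)))
    grp <- rep(c("case", "control"), each = n / 2)
    # one perfectly separating feature among 49 noise features
    m["sp01", ] <- ifelse(grp == "case", runif(n, 0.8, 1), runif(n, 0, 0.2))
    m <- sweep(m, 2, colSums(m), "/")
    st <- toy_study(m, groups = setNames(grp, colnames(m)))
    imp <- ensemble_importance(st, n_trees = 300, seed = 1000 + s)
    by_acc <- imp[order(-imp$mean_decrease_accuracy, imp$species), ]
    if (imp$species[1] == "sp01" && by_acc$species[1] == "sp01") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("importance is deterministic given a seed and centred at zero for noise", {
  st <- make_case_control(study_design(n_case = 8, n_control = 8, seed = 55))
  i1 <- ensemble_importance(st, n_trees = 200, seed = 7)
  i2 <- ensemble_importance(st, n_trees = 200, seed = 7)
  expect_identical(i1, i2)

  set.seed(56)
  n <- 24
  m <- matrix(runif(50 * n), nrow = 50,
              dimnames = list(paste0("sp", 1:50), paste0("s", 1:n)))
  m <- sweep(m, 2, colSums(m), "/")
  null_st <- toy_study(m, groups = setNames(rep(c("a", "b"), each = n / 2),
                                            colnames(m)))
  imp <- ensemble_importance(null_st, n_trees = 300, seed = 8)
  expect_lt(abs(mean(imp$mean_decrease_accuracy)), 0.01)
})

test_that("AUC follows the rank formulation with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("case", "case", "control", "control"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("case", "control"), 3))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 0),
                       c("case", "case", "control", "control"))$auc, 0.75)
  expect_error(roc_auc(1:4, rep("case", 4)), "two classes")

  # complement symmetry for tie-free scores, and agreement with pROC
  set.seed(57)
  sc <- rnorm(30)
  lab <- rep(c("case", "control"), 15)
  a1 <- roc_auc(sc, lab)$auc
  a2 <- roc_auc(-sc, lab)$auc
  expect_equal(a1 + a2, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("control", "case"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(a1, ref, tolerance = 1e-12)
})

test_that("the ROC curve sweeps observed thresholds monotonically", {
  set.seed(58)
  sc <- c(runif(10, 0.4, 1), runif(10, 0, 0.6))
  lab <- rep(c("case", "control"), each = 10)
  roc <- roc_auc(sc, lab)
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
  expect_equal(nrow(roc$curve), length(unique(sc)))
})
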