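test_that("alpha diversity closed forms hold and match vegan", {
  expect_equal(chao1(c(4, 3, 2, 1, 1)), 5.5)
  expect_equal(chao1(c(4, 3, 2)), 3)          # no singletons -> S_obs
  expect_equal(chao1(c(0, 0, 0)), 0)
  expect_error(chao1(c(0.4, 0.6)), "integer")
  expect_error(chao1(c(-1, 2)), "non-negative")

  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(simpson(c(0.5, 0.5)), 0.5)
  expect_equal(simpson(c(1, 0)), 0)
  expect_error(shannon(c(-0.1, 1.1)), "non-negative")

  set.seed(41)
  x <- rpois(40, 3)
  expect_equal(chao1(x), unname(vegan::estimateR(x)["S.chao1"]))
  expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")))
  expect_equal(simpson(x), unname(vegan::diversity(x, "simpson")))
})

test_that("shannon is maximal at uniformity and simpson stays in [0,1)", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(8); p <- p / sum(p)
    expect_lte(shannon(p), log(8) + 1e-12)
    expect_gte(simpson(p), 0)
    expect_lt(simpson(p), 1)
  }
})

test_that("beta distances honour their definitions and are valid matrices", {
  m <- cbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0.5, 0), s3 = c(0, 0.5, 0.5))
  rownames(m) <- c("a", "b", "c")
  st <- toy_study(m, groups = c(s1 = "g1", s2 = "g1", s3 = "g2"))

  bc <- beta_distance(st, "bray_curtis")
  expect_equal(bc["s1", "s2"], 0)
  jc <- beta_distance(st, "jaccard_binary")
  expect_equal(jc["s1", "s3"], 2 / 3)  # {a,b} vs {b,c}
  expect_error(beta_distance(st, "chebyshev"))

  # disjoint species sets
  m2 <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(m2) <- c("a", "b")
  st2 <- toy_study(m2, groups = c(s1 = "x", s2 = "y"))
  expect_equal(beta_distance(st2, "bray_curtis")["s1", "s2"], 1)
  expect_equal(beta_distance(st2, "jaccard_binary")["s1", "s2"], 1)

  # hand formula check for Bray-Curtis, plus matrix validity on a random study
  st3 <- make_case_control(study_design(n_case = 4, n_control = 4, seed = 8))
  b3 <- beta_distance(st3, "bray_curtis")
  x <- st3$matrix[, 1]; y <- st3$matrix[, 2]
  expect_equal(b3[1, 2], sum(abs(x - y)) / sum(x + y))
  e3 <- beta_distance(st3, "euclidean")
  expect_equal(e3[1, 2], sqrt(sum((x - y)^2)))
  for (d in list(b3, e3, beta_distance(st3, "jaccard_binary"))) {
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
  }
})

test_that("permanova pseudo-F matches adonis2 and its p hits the permutation floor", {
  st <- make_case_control(study_design(n_case = 13, n_control = 13, seed = 9))
  dm <- beta_distance(st, "bray_curtis")
  grp <- setNames(as.character(st$groups), colnames(st$matrix))

  pm <- permanova(dm, grp, n_perm = 999, seed = 1)
  ad <- vegan::adonis2(as.dist(dm) ~ g,
                       data = data.frame(g = factor(grp[rownames(dm)])),
                       permutations = 99)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)

  # extreme separation: p reaches the minimal attainable 1/(n_perm+1)
  expect_equal(pm$p_value, 0.001)

  expect_error(permanova(dm, setNames(c("a", rep("b", nrow(dm) - 1L)),
                                      rownames(dm)),
                         n_perm = 9),
               "at least 2 samples")
})

test_that("permanova F is invariant under distance-preserving relabeling", {
  st <- make_case_control(study_design(n_case = 5, n_control = 5, seed = 10))
  dm <- beta_distance(st, "bray_curtis")
  grp <- setNames(as.character(st$groups), colnames(st$matrix))
  f1 <- permanova(dm, grp, n_perm = 9, seed = 1)$pseudo_F
  set.seed(99)
  ord <- sample(rownames(dm))
  f2 <- permanova(dm[ord, ord], grp[ord], n_perm = 9, seed = 1)$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("rank-sum test enumerates exactly for small groups", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)  # 2 * 1/choose(6,3)... = 2/20
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
  expect_error(rank_sum_test(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("rank-sum test has power against a 1-SD shift at n = 20 per group", {
  set.seed(43)
  rej <- mean(replicate(200, {
    rank_sum_test(rnorm(20), rnorm(20, 1))$p_value < 0.05
  }))
  expect_gt(rej, 0.5)
})

test_that("venn counts partition species by group detection", {
  m <- cbind(c1 = c(0.5, 0.5, 0, 0), c2 = c(0.4, 0.3, 0.3, 0),
             k1 = c(0.6, 0, 0, 0.4), k2 = c(0.7, 0, 0, 0.3))
  rownames(m) <- c("both", "case_only", "case_only2", "ctrl_only")
  st <- toy_study(m, groups = c(c1 = "case", c2 = "case",
                                k1 = "control", k2 = "control"))
  vc <- venn_counts(st)
  expect_equal(unname(vc$counts),
               c(1L, 2L, 1L))
  expect_equal(unname(vc$percent[1]), 25)
  expect_equal(unname(vc$species["both"]), "shared")
})

test_that("spearman correlation network finds monotone relationships", {
  n <- 12
  b <- seq(0.1, 0.4, length.out = n)
  up <- b / 2              # perfectly increasing with b
  down <- rev(b) / 2       # perfectly decreasing
  rest <- 1 - b - up - down
  m <- rbind(Bact_x = b, Fung_up = up, Fung_down = down, Bact_rest = rest)
  colnames(m) <- paste0("s", 1:n)
  tax <- data.frame(species = rownames(m),
                    kingdom = c("bacteria", "fungi", "fungi", "bacteria"),
                    genus = rownames(m), stringsAsFactors = FALSE)
  st <- toy_study(m, groups = setNames(rep("case", n), colnames(m)),
                  taxonomy = tax)
  net <- correlation_network(st, level = "genus")
  expect_equal(net$rho[net$taxon1 == "Bact_x" & net$taxon2 == "Fung_up"], 1)
  expect_equal(net$rho[net$taxon1 == "Bact_x" & net$taxon2 == "Fung_down"], -1)
  expect_error(correlation_network(st, level = "family"), "absent")
})

test_that("correlation is centred at zero for independent taxa", {
  set.seed(44)
  nb <- 20; nf <- 25; ns <- 30
  m <- matrix(runif(ns * (nb + nf)), nrow = nb + nf,
              dimnames = list(c(paste0("B", 1:nb), paste0("F", 1:nf)),
                              paste0("s", 1:ns)))
  m <- sweep(m, 2, colSums(m), "/")
  tax <- data.frame(species = rownames(m),
                    kingdom = rep(c("bacteria", "fungi"), c(nb, nf)),
                    genus = rownames(m), stringsAsFactors = FALSE)
  st <- toy_study(m, groups = setNames(rep("g", ns), colnames(m)),
                  taxonomy = tax)
  net <- correlation_network(st, level = "genus")
  expect_equal(nrow(net), nb * nf)  # 500 independent pairs
  expect_lt(abs(mean(net$rho)), 0.05)
})
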