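test_that("shape clustering recovers separated groups and respects k", {
  set.seed(1)
  blobs <- rbind(matrix(rnorm(60, 0), ncol = 3),
                 matrix(rnorm(60, 6), ncol = 3),
                 matrix(rnorm(60, -6), ncol = 3))
  rownames(blobs) <- sprintf("c%02d", 1:60)
  truth <- rep(1:3, each = 20)
  cl <- cluster_shapes(blobs, k = 3, restarts = 10, seed = 2)
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(cl, truth))), 3)
  cl1 <- cluster_shapes(blobs, k = 1, restarts = 2, seed = 2)
  expect_equal(attr(cl1, "tot.withinss"),
               sum(scale(blobs)[, 1:3]^2), tolerance = 1e-8)
  # duplicated rows co-assign
  dup <- blobs[c(1, 1, 30, 30, 50, 50), ]
  cld <- cluster_shapes(dup, k = 3, restarts = 5, seed = 3)
  expect_equal(cld[1], cld[2], ignore_attr = TRUE)
  expect_error(cluster_shapes(blobs[1:2, ], k = 3), "k exceeds")
})

test_that("count filtering applies the CPM rule with an inclusive boundary", {
  set.seed(4)
  counts <- matrix(rpois(100 * 14, 50), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100), NULL))
  counts[1, ] <- 0                               # all-zero gene
  counts[2, ] <- c(rep(40, 8), rep(0, 6))        # passes in exactly 8
  kept <- filter_counts(counts, cpm_min = 0.5, min_samples = 8)
  expect_false("g001" %in% rownames(kept))
  expect_true("g002" %in% rownames(kept))
  # planted failures are all removed
  counts[3:42, ] <- 0
  kept2 <- filter_counts(counts, cpm_min = 0.5, min_samples = 8)
  expect_equal(nrow(kept2), 100 - 41)
})

test_that("size factors and the NB Wald test behave on exact and null data", {
  # expected counts with equal means: log2fc is exactly 0
  counts <- matrix(100, nrow = 10, ncol = 8,
                   dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:8)))
  expect_equal(unname(size_factors(counts)), rep(1, 8))
  de <- nb_differential_expression(counts, sprintf("s%d", 1:4))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$se > 0))
  expect_error(nb_differential_expression(counts, "s1"), ">= 2")
})

test_that("regulon activity is signed correctly and antisymmetric in the statistics", {
  stats <- setNames(seq(4, -4, length.out = 100), sprintf("g%03d", 1:100))
  top <- names(stats)[1:10]
  regs <- list(
    act = list(activated = top, repressed = character(0),
               unknown = character(0)),
    rep = list(activated = character(0), repressed = top,
               unknown = character(0)))
  res <- regulon_activity(stats, regs)
  expect_gt(res$nes[res$name == "act"], 0)
  expect_lt(res$p[res$name == "act"], 0.01)
  expect_lt(res$nes[res$name == "rep"], 0)
  res_neg <- regulon_activity(-stats, regs)
  expect_equal(res_neg$nes, -res$nes, tolerance = 1e-12)
  # module activity: plain gene lists act as all-activated regulons
  resm <- regulon_activity(stats, list(mod = top))
  expect_equal(resm$nes, res$nes[res$name == "act"], tolerance = 1e-12)
  # sparse regulons are skipped
  res_skip <- regulon_activity(stats, list(tiny = list(
    activated = c("g001", "zzz"), repressed = character(0),
    unknown = character(0))))
  expect_equal(nrow(res_skip), 0)
})

test_that("regulon activity is standard normal under random regulons", {
  set.seed(6)
  stats <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  nes <- replicate(1000, {
    reg <- list(r = list(activated = sample(names(stats), 20),
                         repressed = character(0), unknown = character(0)))
    regulon_activity(stats, reg)$nes
  })
  expect_lt(abs(mean(nes)), 0.1)
  expect_gt(sd(nes), 0.9)
  expect_lt(sd(nes), 1.1)
})

test_that("Kendall activity correlation filters by significance and is rank-invariant", {
  set.seed(7)
  n <- 20
  mod <- data.frame(sample = sprintf("s%02d", 1:n), nes = rnorm(n),
                    fdr = 0.01)
  tfa <- rbind(
    data.frame(sample = mod$sample, tf = "same", nes = mod$nes, fdr = 0.01),
    data.frame(sample = mod$sample, tf = "mono", nes = exp(mod$nes),
               fdr = 0.01),
    data.frame(sample = mod$sample, tf = "starved", nes = rnorm(n),
               fdr = 0.5))
  res <- kendall_activity_correlation(mod, tfa, sig_alpha = 0.05)
  expect_equal(res$tau[res$tf == "same"], 1)
  expect_equal(res$tau[res$tf == "mono"], 1)     # monotone transform
  expect_true(is.na(res$tau[res$tf == "starved"]))
  expect_match(res$reason[res$tf == "starved"], "min_n")
})

test_that("KS group differences hit the degenerate extremes", {
  v <- c(rnorm(10), rnorm(10))
  names(v) <- sprintf("s%02d", 1:20)
  same <- ks_group_difference(rep(v[1:10], 2),
                              rep(c("a", "b"), each = 10))
  expect_equal(same$D, 0)
  disjoint <- ks_group_difference(c(1:10, 101:110),
                                  rep(c("a", "b"), each = 10))
  expect_equal(disjoint$D, 1)
  expect_error(ks_group_difference(v[1:6], c(rep("a", 5), "b")), ">= 5")
})

test_that("one-way ANOVA with Tukey HSD detects shifts and covers null contrasts", {
  set.seed(8)
  cells <- data.frame(f1 = c(rnorm(30), rnorm(30), rnorm(30, 5)),
                      f2 = rnorm(90))
  cl <- rep(c("a", "b", "c"), each = 30)
  res <- anova_shape(cells, cl)
  expect_lt(res$anova$p[res$anova$feature == "f1"], 1e-6)
  tk <- res$tukey[res$tukey$feature == "f1" & res$tukey$comparison == "b-a", ]
  expect_true(tk$lwr <= 0 & tk$upr >= 0)   # identical groups: CI covers 0
})
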