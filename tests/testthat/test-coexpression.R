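test_that("soft-thresholded adjacency hits its closed-form values and is monotone", {
  # three exactly collinear / anti-collinear / orthogonal profiles
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  a <- wgcna_adjacency(x, beta = 9, log2_transform = FALSE)
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 0)
  grid <- seq(-1, 1, by = 0.05)
  vals <- abs((1 + grid) / 2)^9
  expect_true(all(diff(vals) >= 0))
  expect_equal(abs((1 + 0) / 2)^9, 0.001953125)
  expect_error(wgcna_adjacency(x, beta = 0), "beta")
})

test_that("topological overlap matches the hand case and a triple-loop oracle", {
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  t3 <- topological_overlap(a3)
  expect_equal(t3[1, 2], 0.5)        # (0.25 + 0.5) / (1 + 1 - 0.5)
  a0 <- matrix(0, 2, 2)
  expect_equal(topological_overlap(a0)[1, 2], 0)

  set.seed(101)
  for (rep in 1:50) {
    n <- sample(8:12, 1)
    m <- matrix(runif(n * n), n)
    a <- (m + t(m)) / 2
    diag(a) <- 0
    expect_lt(max(abs(topological_overlap(a) - tom_oracle(a))), 1e-12)
  }
})

test_that("gene filtering applies the coding and expression rules", {
  set.seed(1)
  expr <- matrix(2, nrow = 200, ncol = 5,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  expr[1:30, ] <- 0.9                       # below threshold everywhere
  kept <- filter_genes(expr, rownames(expr), fpkm_min = 1)
  expect_equal(nrow(kept), 170)
  expect_identical(rownames(kept), sprintf("g%03d", 31:200))
  kept2 <- filter_genes(expr, sprintf("g%03d", 31:40), fpkm_min = 1)
  expect_equal(nrow(kept2), 10)
  expect_error(filter_genes(expr, character(0)), "survive")
})

test_that("eigengene is the dominant PC, unit variance, oriented to the mean profile", {
  cfg <- tiny_config()
  ge <- gen_expression(cfg)
  genes <- ge$truth$module_genes$M1
  eg <- eigengene(ge$expression, genes)
  expect_equal(sd(eg), 1)
  z <- t(scale(t(log2(ge$expression[genes, ] + 1))))
  expect_gte(cor(eg, colMeans(z)), 0)
  # explains at least as much variance as any single member profile
  var_along <- function(v) sum((z %*% v / sqrt(sum(v^2)))^2)
  ev_eg <- var_along(eg)
  for (i in seq_len(nrow(z))) expect_gte(ev_eg + 1e-8, var_along(z[i, ]))
  # identical standardized genes: eigengene equals that profile
  flat <- matrix(rep(2^seq(1, 4, length.out = 10), each = 3), nrow = 3,
                 byrow = FALSE, dimnames = list(c("x", "y", "z"), NULL))
  ef <- eigengene(flat, c("x", "y", "z"), log2_transform = FALSE)
  prof <- scale(flat[1, ])[, 1]
  expect_equal(unname(ef), prof / sd(prof), tolerance = 1e-10)
  expect_error(eigengene(ge$expression, genes[1]), ">= 2")
})

test_that("module detection recovers planted blocks and applies size and merge rules", {
  cfg <- synth_config(n_background_genes = 60, module_sizes = c(50, 50),
                      n_samples = 60, eigengene_shape_corr = c(0.7, 0.7),
                      within_module_corr = 0.9, rng_seed = 21)
  ge <- gen_expression(cfg)
  ms <- coexpression_modules(ge$expression, ge$coding_genes)
  bm <- best_match_jaccard(ms$modules, ge$truth$module_genes)
  expect_gte(mean(bm$jaccard), 0.8)

  # block below the minimum size goes to the unassigned pool
  cfg_small <- synth_config(n_background_genes = 60, module_sizes = c(50, 10),
                            n_samples = 60, eigengene_shape_corr = c(0.7, 0),
                            within_module_corr = 0.9, rng_seed = 22)
  ges <- gen_expression(cfg_small)
  mss <- coexpression_modules(ges$expression, ges$coding_genes)
  expect_equal(length(mss$modules), 1)
  expect_true(all(ges$truth$module_genes$M2 %in% mss$unassigned))

  # two clusters driven by one latent factor merge at eigengene corr 1
  set.seed(9)
  f <- rnorm(30)
  expr <- rbind(matrix(rep(f, 4), nrow = 4, byrow = TRUE),
                matrix(rep(f, 4), nrow = 4, byrow = TRUE))
  rownames(expr) <- sprintf("g%d", 1:8)
  diss <- matrix(1, 8, 8, dimnames = list(rownames(expr), rownames(expr)))
  diss[1:4, 1:4] <- 0.1; diss[5:8, 5:8] <- 0.1; diag(diss) <- 0
  ms2 <- detect_modules(diss, 2^expr - 1,
                        coexpression_params(min_module_size = 2,
                                            cut_height = 0.5))
  expect_equal(length(ms2$modules), 1)
  expect_setequal(ms2$modules[[1]], rownames(expr))
})

test_that("module-shape correlation flags planted pairs and assigns extreme permutation p", {
  cfg <- synth_config(n_background_genes = 40, module_sizes = c(40),
                      n_samples = 100, eigengene_shape_corr = c(0.8),
                      rng_seed = 31)
  ge <- gen_expression(cfg)
  ms <- coexpression_modules(ge$expression, ge$coding_genes)
  B <- 200
  res <- correlate_modules_shape(ms$eigengenes, ge$shape, B = B, seed = 1)
  expect_true(res$significant[1, "feat01"])
  expect_true(all(abs(res$pcc) <= 1))
  expect_true(all(res$p_perm >= 1 / (B + 1) & res$p_perm <= 1))
  expect_true(all(res$ci_lo <= res$p_perm + 1e-9 &
                    res$p_perm <= res$ci_hi + 1e-9))

  # a feature equal to an eigengene: r = 1 and the minimum attainable p
  shape2 <- ge$shape
  shape2$feat05 <- ms$eigengenes[, 1]
  res2 <- correlate_modules_shape(ms$eigengenes, shape2, B = B, seed = 1)
  expect_equal(res2$pcc[1, "feat05"], 1)
  expect_equal(res2$p_perm[1, "feat05"], 1 / (B + 1))
  expect_error(correlate_modules_shape(ms$eigengenes, ge$shape, B = 50),
               "B must be")
})

test_that("jackknife reports full stability for clean planted modules", {
  cfg <- synth_config(n_background_genes = 20, module_sizes = c(30, 30),
                      n_samples = 25, eigengene_shape_corr = c(0.7, 0.7),
                      within_module_corr = 0.95, rng_seed = 41)
  ge <- gen_expression(cfg)
  kept <- filter_genes(ge$expression, ge$coding_genes)
  st <- jackknife_modules(kept)
  expect_equal(nrow(st), 2)          # one row per original module
  expect_true(all(st$min_jaccard >= 0.9))
})
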