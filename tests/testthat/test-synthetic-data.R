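test_that("generators are deterministic given the seed and validate their config", {
  cfg <- tiny_config()
  expect_identical(gen_expression(cfg), gen_expression(cfg))
  expect_identical(gen_prior_network(cfg)$edges, gen_prior_network(cfg)$edges)
  expect_error(synth_config(within_module_corr = 0), "within_module_corr")
  expect_error(synth_config(eigengene_shape_corr = c(1.2)), "\\[-1, 1\\]")
  expect_error(synth_config(nb_dispersion = -1), "dispersion")
})

test_that("planted expression structure matches the configured geometry", {
  cfg <- synth_config(n_background_genes = 100, module_sizes = c(50, 50),
                      n_samples = 200, eigengene_shape_corr = c(0.8, 0.8),
                      rng_seed = 7)
  ge <- gen_expression(cfg)
  expect_equal(nrow(ge$expression), 200)   # 100 module + 100 background rows
  expect_equal(ncol(ge$expression), 200)
  expect_setequal(unique(ge$truth$module_assignment),
                  c("M1", "M2", "unassigned"))

  # noiseless module: all within-module pairwise correlations are 1
  cfg1 <- synth_config(n_background_genes = 4, module_sizes = c(5),
                       n_samples = 30, eigengene_shape_corr = c(0.5),
                       within_module_corr = 1, rng_seed = 3)
  ge1 <- gen_expression(cfg1)
  block <- log2(ge1$expression[ge1$truth$module_genes$M1, ])
  cc <- cor(t(block))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)

  # realized factor-feature correlation near the configured 0.8 target
  r <- cor(ge$truth$factors[, 1], ge$shape$feat01)
  expect_lt(abs(abs(r) - 0.8), 0.1)
})

test_that("negative-binomial counts carry the planted fold change", {
  cfg <- synth_config(n_background_genes = 400, module_sizes = c(50),
                      n_samples = 100, eigengene_shape_corr = c(0.5),
                      planted_lfc = 1, nb_mean = 100, de_frac = 0.3,
                      rng_seed = 11)
  groups <- setNames(rep(c("A", "B"), each = 50), sprintf("S%03d", 1:100))
  cnt <- gen_counts(cfg, groups)
  lib <- cnt$size_factors_true
  norm <- sweep(cnt$counts, 2, lib, `/`)
  de_up <- names(which(cnt$truth$de_genes == 1))
  ratio <- rowMeans(norm[de_up, groups == "A"]) /
    rowMeans(norm[de_up, groups == "B"])
  expect_gt(mean(ratio), 1.8)
  expect_lt(mean(ratio), 2.2)
  null_genes <- names(which(cnt$truth$de_genes == 0))
  lr <- log2(rowMeans(norm[null_genes, groups == "A"]) /
               rowMeans(norm[null_genes, groups == "B"]))
  expect_lt(abs(mean(lr)), 0.05)
  expect_error(gen_counts(cfg, setNames(rep("A", 100), names(groups))),
               "2 groups")
})

test_that("prior network has heavy-tailed out-degree, valid signs and source counts", {
  cfg <- synth_config(network_nodes = 500, n_regulons = 20,
                      n_background_genes = 400, module_sizes = c(50, 50),
                      n_samples = 20, eigengene_shape_corr = c(0.5, 0.5),
                      rng_seed = 5)
  pr <- gen_prior_network(cfg)
  outdeg <- table(pr$edges$source)
  expect_gt(max(outdeg), median(outdeg) * 5)
  expect_true(all(pr$edges$sign %in% c(-1L, 1L)))
  expect_true(all(pr$edges$n_sources >= 1 & pr$edges$n_sources <= 25))
  expect_true(all(pr$edges$source != pr$edges$target))
  # node names overlap the measured gene universe by construction
  expect_gt(length(intersect(pr$nodes, gene_universe(cfg))), 0)
  # edge_prob = 0 yields an empty edge set
  cfg0 <- tiny_config(network_edge_prob = 0)
  expect_equal(nrow(gen_prior_network(cfg0)$edges), 0)
})

test_that("regulons respect sign structure and planted-module overlap", {
  cfg <- tiny_config(unknown_sign_frac = 0)
  ge <- gen_expression(cfg)
  reg <- gen_regulons(cfg, ge$truth)
  expect_true(all(vapply(reg$regulons, function(r) length(r$unknown) == 0,
                         logical(1))))
  # positive-control regulon sits inside a planted module: hypergeometric
  # tail is far below 0.1
  r1 <- reg$regulons[[1]]
  targets <- unlist(r1)
  m1 <- ge$truth$module_genes$M1
  expect_true(all(targets %in% m1))
  ft <- fisher_overlap(targets, m1, gene_universe(cfg))
  expect_lt(ft$p, 0.1)
  # disjoint sets within each TF
  expect_true(all(vapply(reg$regulons, function(r) {
    length(intersect(r$activated, r$repressed)) == 0
  }, logical(1))))
  expect_error(gen_regulons(tiny_config(regulon_size = 10000), ge$truth),
               "universe")
})

test_that("generated ontology is a single-rooted DAG with complete annotation", {
  cfg <- tiny_config(ontology_depth = 3, ontology_branching = 2)
  onto <- gen_ontology(cfg)
  expect_equal(length(onto$terms) >= 1 + 2 + 4, TRUE)   # tree + cross-links
  expect_identical(onto$root, "T1")
  non_root <- setdiff(onto$terms, onto$root)
  expect_true(all(vapply(non_root, function(t) {
    length(setdiff(onto$ancestors[[t]], t)) >= 1
  }, logical(1))))
  expect_true(all(c(gene_universe(cfg), sprintf("TF%02d", 1:8)) %in%
                    names(onto$gene_terms)))
  # depth 1: only the root exists, so every gene is annotated at the root
  o1 <- gen_ontology(tiny_config(ontology_depth = 1))
  expect_identical(o1$terms, "T1")
  expect_true(all(vapply(o1$gene_terms, identical, logical(1), "T1")))
})
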