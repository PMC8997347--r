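test_that("ontology information content is zero at the root and grows toward leaves", {
  onto <- tiny_ontology()
  expect_equal(unname(onto$ic["T1"]), 0)
  expect_gte(onto$ic["T4"], onto$ic["T2"])
  expect_gte(onto$ic["T2"], onto$ic["T1"])
  bad <- data.frame(child = c("T1", "T2"), parent = c(NA, NA))
  expect_error(build_ontology(bad, data.frame(gene = "g", term = "T1")),
               "exactly one root")
})

test_that("Resnik BMA matches trivial cases, is symmetric, and equals the brute-force oracle", {
  onto <- tiny_ontology()
  # identical single annotation: similarity is that term's IC
  one <- build_ontology(onto$parents_df,
                        data.frame(gene = c("x", "y", "z"),
                                   term = c("T4", "T4", "T5")))
  expect_equal(resnik_bma(one, "x", "y"), unname(one$ic["T4"]))
  # both only at the root: zero
  root_only <- build_ontology(onto$parents_df,
                              data.frame(gene = c("x", "y"),
                                         term = c("T1", "T1")))
  expect_equal(resnik_bma(root_only, "x", "y"), 0)
  expect_warning(s <- resnik_bma(onto, "gA", "missing"), "not annotated")
  expect_equal(s, 0)

  set.seed(12)
  cfg <- tiny_config(ontology_depth = 4, ontology_branching = 2)
  g_onto <- gen_ontology(cfg)
  genes <- sample(names(g_onto$gene_terms), 8)
  for (i in 1:6) {
    pair <- sample(genes, 2)
    ours <- resnik_bma(g_onto, pair[1], pair[2])
    expect_equal(ours, resnik_bma(g_onto, pair[2], pair[1]))   # symmetry
    expect_equal(ours,
                 resnik_oracle(g_onto$parents_df, g_onto$annotations_df,
                               pair[1], pair[2]), tolerance = 1e-12)
  }
})

test_that("semantic reweighting scales to [-1, 1] with supernode edges untouched", {
  net <- toy_network()
  onto <- build_ontology(
    tiny_ontology()$parents_df,
    data.frame(gene = c("TF1", "TF1", "A", "A", "B", "C"),
               term = c("T4", "T6", "T4", "T6", "T4", "T7")))
  rw <- reweight_edges(net, onto)
  pp <- rw$edges[rw$edges$origin == "pcsf", ]
  expect_true(all(abs(pp$weight) <= 1))
  # maximum-similarity edge maps to +1 (activating) and the inhibiting edge
  # carries a negative weight
  expect_equal(max(pp$weight[pp$sign == 1]), 1)
  expect_true(all(pp$weight[pp$sign == -1] <= 0))
  expect_true(all(rw$edges$weight[rw$edges$origin != "pcsf"] == 1))
  expect_true(all(rw$edges$capacity >= 0 & rw$edges$capacity <= 1))
})

test_that("random walk with restart conserves mass and matches the linear solve", {
  net <- toy_network()
  p <- rwr(net, seeds = c(TF1 = 1), r = 0.95)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))

  # single isolated node
  iso <- assembled_network(
    data.frame(node = "only", type = "protein", prize = 0),
    data.frame(source = character(0), target = character(0),
               sign = integer(0), weight = numeric(0), origin = character(0)))
  expect_warning(p1 <- rwr(iso, c(only = 1)), "seed distribution")
  expect_equal(unname(p1), 1)

  # random strongly-connected instances vs the closed form
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    nodes <- sprintf("v%02d", 1:n)
    # ring plus random chords ensures no dangling nodes
    ed <- data.frame(source = nodes, target = nodes[c(2:n, 1)],
                     sign = 1L, weight = runif(n, 0.2, 1), origin = "pcsf")
    extra <- data.frame(source = sample(nodes, n), target = sample(nodes, n),
                        sign = 1L, weight = runif(n, 0.2, 1), origin = "pcsf")
    extra <- extra[extra$source != extra$target, ]
    ed <- rbind(ed, extra)
    ed <- ed[!duplicated(ed[, 1:2]), ]
    net_i <- assembled_network(
      data.frame(node = nodes, type = "protein", prize = 0), ed)
    seeds <- setNames(runif(2), sample(nodes, 2))
    r <- 0.9
    p_iter <- rwr(net_i, seeds, r = r)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (j in seq_len(nrow(ed))) W[ed$source[j], ed$target[j]] <- ed$weight[j]
    W <- W / rowSums(W)
    s <- setNames(numeric(n), nodes)
    s[names(seeds)] <- seeds / sum(seeds)
    p_exact <- rwr_closed_form(W, s, r)
    expect_lt(max(abs(p_iter - p_exact)), 1e-8)
    expect_equal(sum(p_iter), 1, tolerance = 1e-12)
  }
})

test_that("concentrating the restart raises the mass retained on the seeds", {
  net <- toy_network()
  seeds <- c(TF1 = 1)
  mass <- vapply(c(0.5, 0.7, 0.9, 0.95),
                 function(r) sum(rwr(net, seeds, r = r)[names(seeds)]),
                 numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("seed significance flags a hub fed by its leaves and bounds p from below", {
  # star center fed by 3 seeded leaves, embedded among 60 chain nodes so
  # random seed sets rarely touch the star; the center's null affinity
  # exceeds the observed one essentially only when the center itself is
  # drawn as a seed (probability ~ 3/64)
  n_far <- 60
  nodes <- c("hub", sprintf("leaf%d", 1:3), sprintf("far%02d", 1:n_far))
  ed <- rbind(
    data.frame(source = sprintf("leaf%d", 1:3), target = "hub", sign = 1L,
               weight = 1, origin = "pcsf"),
    data.frame(source = sprintf("far%02d", 1:(n_far - 1)),
               target = sprintf("far%02d", 2:n_far), sign = 1L,
               weight = 1, origin = "pcsf"))
  net <- assembled_network(
    data.frame(node = nodes, type = "protein", prize = 0), ed)
  seeds <- setNames(rep(1 / 3, 3), sprintf("leaf%d", 1:3))
  res <- seed_significance(net, seeds, n_rand = 1000, alpha = 0.1, seed = 5)
  hub <- res[res$node == "hub", ]
  expect_true(hub$significant)
  expect_lt(hub$p, 0.1)
  expect_true(all(res$p >= 1 / 1001, na.rm = TRUE))   # counting lower bound
  expect_error(seed_significance(net, seeds, n_rand = 50), "n_rand")
})

test_that("shortest-path subgraphs collect all tied geodesics", {
  # chain: source -> a -> target
  ed <- data.frame(source = c("s", "a"), target = c("a", "t"),
                   sign = 1L, weight = 0.5, origin = "pcsf")
  net <- assembled_network(
    data.frame(node = c("s", "a", "t"), type = "protein", prize = 0), ed)
  sg <- shortest_path_subgraph(net, "s", "t")
  expect_setequal(sg$nodes, c("s", "a", "t"))
  expect_equal(nrow(sg$edges), 2)

  # two equal-cost parallel paths: both included
  ed2 <- data.frame(source = c("s", "a", "s", "b"),
                    target = c("a", "t", "b", "t"),
                    sign = 1L, weight = 0.5, origin = "pcsf")
  net2 <- assembled_network(
    data.frame(node = c("s", "a", "b", "t"), type = "protein", prize = 0),
    ed2)
  sg2 <- shortest_path_subgraph(net2, "s", "t")
  expect_setequal(sg2$nodes, c("s", "a", "b", "t"))
  expect_equal(nrow(sg2$edges), 4)

  # unreachable source is reported, empty subgraph warns
  ed3 <- rbind(ed2, data.frame(source = "x", target = "y", sign = 1L,
                               weight = 0.5, origin = "pcsf"))
  net3 <- assembled_network(
    data.frame(node = c("s", "a", "b", "t", "x", "y"), type = "protein",
               prize = 0), ed3)
  sg3 <- shortest_path_subgraph(net3, c("s", "y"), "t")
  expect_identical(sg3$unreachable, "y")
  expect_warning(shortest_path_subgraph(net3, "y", "s"), "no source")
})

test_that("geodesic distances agree with an independent Dijkstra on random graphs", {
  set.seed(14)
  for (i in 1:5) {
    n <- 15
    nodes <- sprintf("v%02d", 1:n)
    ed <- data.frame(source = sample(nodes, 30, TRUE),
                     target = sample(nodes, 30, TRUE), sign = 1L,
                     weight = runif(30, 0.1, 0.9), origin = "pcsf")
    ed <- ed[ed$source != ed$target, ]
    ed <- ed[!duplicated(ed[, 1:2]), ]
    net <- assembled_network(
      data.frame(node = nodes, type = "protein", prize = 0), ed)
    g <- igraph::graph_from_data_frame(ed[, 1:2], vertices = nodes)
    dvec <- pmax(1 - abs(ed$weight), 1e-6)
    dm <- igraph::distances(g, mode = "out", weights = dvec)
    src <- nodes[1]; tgt <- nodes[n]
    if (!is.finite(dm[src, tgt])) next
    sg <- shortest_path_subgraph(net, src, tgt)
    # every edge on a returned path lies on a geodesic of the same length
    gsub <- igraph::graph_from_data_frame(sg$edges[, 1:2],
                                          vertices = sg$nodes)
    dsub <- igraph::distances(gsub, mode = "out",
                              weights = pmax(1 - abs(sg$edges$weight), 1e-6))
    expect_equal(dsub[src, tgt], dm[src, tgt], tolerance = 1e-12)
  }
})
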