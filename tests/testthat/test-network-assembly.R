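test_that("edge costs decrease with source counts and hit the scaling endpoints", {
  ed <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"),
                   sign = 1L, n_sources = c(1L, 2L, 4L))
  costs <- edge_costs(prior_network(ed))
  expect_equal(costs, c(1, 1 / 3, 0))
  expect_equal(costs[which.max(ed$n_sources)], 0)
  expect_equal(costs[which.min(ed$n_sources)], 1)
  ed$n_sources <- 3L
  expect_equal(edge_costs(prior_network(ed)), rep(0.5, 3))
})

test_that("prize collection unions the inputs and applies the hub penalty", {
  ed <- data.frame(source = "hub", target = sprintf("x%d", 1:10),
                   sign = 1L, n_sources = 1L)
  prior <- prior_network(ed)
  pz <- collect_prizes(c("hub", "x1"), "x2", character(0), prior,
                       pcsf_params(mu = 0))
  expect_equal(unname(pz), rep(100, 3))
  pz2 <- collect_prizes("hub", character(0), character(0), prior,
                        pcsf_params(mu = 0.005))
  expect_equal(unname(pz2), 100 - 0.005 * 10)
  # a degree-20000 hub at mu = 0.005 is fully penalized
  expect_equal(max(1 * 100 - 0.005 * 20000, 0), 0)
  expect_warning(collect_prizes("ghost", character(0), character(0), prior),
                 "absent")
  expect_length(collect_prizes(character(0), character(0), character(0),
                               prior), 0)
})

test_that("PCSF solves the worked path instance and the degenerate cases", {
  ed <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   sign = 1L, n_sources = 1L)
  prior <- prior_network(ed)
  params <- pcsf_params(w = 40)
  sol <- pcsf_solve(prior, costs = c(1, 1),
                    prizes = c(A = 100, C = 100), params)
  expect_setequal(sol$nodes, c("A", "B", "C"))
  expect_equal(nrow(sol$edges), 2)
  expect_equal(sol$objective, 2 + 40)      # both edges + one tree

  # prize below its connection cost: node dropped entirely
  sol2 <- pcsf_solve(prior, costs = c(1, 1), prizes = c(A = 0.1), params)
  expect_length(sol2$nodes, 0)
  expect_equal(sol2$objective, 0.1)

  # a single prize worth more than w survives as a singleton tree
  sol3 <- pcsf_solve(prior, costs = c(1, 1), prizes = c(B = 100), params)
  expect_identical(sol3$nodes, "B")
  expect_equal(nrow(sol3$edges), 0)
  expect_equal(sol3$objective, 40)

  expect_equal(pcsf_solve(prior, c(1, 1), numeric(0), params)$nodes,
               character(0))
})

test_that("PCSF heuristic is near-optimal on random instances and exact on trees", {
  worst <- 0
  for (i in 1:50) {
    is_tree <- i <= 20
    inst <- random_pcsf_instance(n_nodes = sample(6:9, 1),
                                 n_extra_edges = if (is_tree) 0 else 3,
                                 n_prizes = sample(2:4, 1), seed = 1000 + i)
    w <- 0.8
    opt <- pcsf_enum_oracle(inst$nodes, inst$edges, inst$prizes, w)
    ap <- as_prior(inst)
    sol <- pcsf_solve(ap$prior, ap$costs, inst$prizes, pcsf_params(w = w))
    expect_lte(sol$objective, sum(inst$prizes) + 1e-9)  # never worse than empty
    if (is_tree) {
      expect_equal(sol$objective, opt, tolerance = 1e-9)
    } else {
      expect_lte(sol$objective, opt * 1.10 + 1e-9)
      worst <- max(worst, sol$objective / opt)
    }
  }
})

test_that("randomized union is a superset of single runs and reproducible", {
  inst <- random_pcsf_instance(10, 4, 4, seed = 77)
  ap <- as_prior(inst)
  p0 <- pcsf_params(w = 0.8, noise_frac = 0, iterations = 5, seed = 3)
  base <- pcsf_solve(ap$prior, ap$costs, inst$prizes, p0)
  un0 <- pcsf_union(ap$prior, ap$costs, inst$prizes, p0)
  expect_identical(un0$edges, base$edges)    # zero noise: union == single run

  pn <- pcsf_params(w = 0.8, noise_frac = 0.3, iterations = 20, seed = 3)
  un <- pcsf_union(ap$prior, ap$costs, inst$prizes, pn)
  expect_true(all(base$nodes %in% un$nodes))
  un_again <- pcsf_union(ap$prior, ap$costs, inst$prizes, pn)
  expect_identical(un, un_again)             # idempotent given the seed
})

test_that("noisy union recovers near-tied parallel paths", {
  # two parallel two-edge paths with near-equal costs between prizes S, T
  ed <- data.frame(source = c("S", "m1", "S", "m2"),
                   target = c("m1", "T", "m2", "T"),
                   sign = 1L, n_sources = 1L)
  prior <- prior_network(ed)
  costs <- c(0.50, 0.50, 0.505, 0.505)
  pn <- pcsf_params(w = 5, noise_frac = 0.05, iterations = 30, seed = 11)
  un <- pcsf_union(prior, costs, c(S = 100, T = 100), pn)
  expect_true(all(c("m1", "m2") %in% un$nodes))
})

test_that("supernode wiring applies its threshold rules exactly", {
  ed <- data.frame(source = c("TF1", "A", "TF2"),
                   target = c("A", "B", "B"),
                   sign = c(1L, 1L, -1L), n_sources = c(3L, 2L, 1L))
  prior <- prior_network(ed)
  sol <- pcsf_solve(prior, edge_costs(prior),
                    c(TF1 = 100, TF2 = 100, B = 100), pcsf_params(w = 40))
  mods <- list(GEM01 = c("A", "B", sprintf("m%d", 1:8)))
  uni <- c("A", "B", sprintf("m%d", 1:8), sprintf("bg%d", 1:90))
  regs <- list(TF1 = list(activated = c("A", "B", sprintf("m%d", 1:3)),
                          repressed = character(0), unknown = character(0)),
               TF2 = list(activated = sprintf("bg%d", 1:5),
                          repressed = character(0), unknown = character(0)))
  pcc <- matrix(c(0.8, 0.4), 1, 2,
                dimnames = list("GEM01", c("featA", "featB")))
  ps <- matrix(c(0.001, 0.001), 1, 2, dimnames = dimnames(pcc))
  shape_corr <- structure(list(pcc = pcc, p_student = ps),
                          class = "module_shape_correlation")
  net <- add_supernodes(sol, mods, regs, shape_corr, universe = uni)
  eo <- paste(net$edges$origin, net$edges$source, net$edges$target)
  expect_true("tf_gem TF1 GEM01" %in% eo)      # enriched regulon: edge
  expect_false("tf_gem TF2 GEM01" %in% eo)     # background regulon: none
  expect_true("gem_phenotype GEM01 featA" %in% eo)  # |r| = 0.8 qualifies
  expect_false("gem_phenotype GEM01 featB" %in% eo) # |r| = 0.4 does not
  # feedback only to members inside the network, weight exactly 1
  fb <- net$edges[net$edges$origin == "gem_feedback", ]
  expect_setequal(fb$target, c("A", "B"))
  expect_true(all(fb$weight == 1))
  # every supernode has at least one incident edge
  for (sn in net$nodes$node[net$nodes$type != "protein"]) {
    expect_true(sn %in% c(net$edges$source, net$edges$target))
  }
})

test_that("network statistics match hand-enumerated centralities and coverage", {
  # path of five: the middle node lies on 4 shortest source-target pairs
  ed <- data.frame(source = c("a", "b", "c", "d"),
                   target = c("b", "c", "d", "e"),
                   sign = 1L, weight = 1, origin = "pcsf")
  nd <- data.frame(node = letters[1:5], type = "protein",
                   prize = c(100, 0, 0, 0, 100))
  net <- assembled_network(nd, ed)
  ns <- network_stats(net)
  expect_equal(ns$node_stats$betweenness[ns$node_stats$node == "c"], 4)
  expect_equal(ns$prize_coverage, 1)
  # star: the hub has maximal betweenness
  ed2 <- data.frame(source = "hub", target = sprintf("l%d", 1:5),
                    sign = 1L, weight = 1, origin = "pcsf")
  nd2 <- data.frame(node = c("hub", sprintf("l%d", 1:5)), type = "protein",
                    prize = 0)
  ns2 <- network_stats(assembled_network(nd2, ed2),
                       prizes = c(hub = 100, ghost = 100))
  expect_identical(ns2$node_stats$node[1], "hub")
  expect_equal(ns2$prize_coverage, 0.5)    # ghost prize not in solution
})
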