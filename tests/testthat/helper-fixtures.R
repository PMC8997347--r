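# Small in-code fixtures shared by the tests.

tiny_config <- function(...) {
  args <- list(n_background_genes = 40, module_sizes = c(30, 30),
               n_samples = 40, eigengene_shape_corr = c(0.8, -0.8),
               network_nodes = 60, n_regulons = 8, regulon_size = 10,
               n_drugs = 20, rng_seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# A hand-built assembled network: chain TF1 -> A -> B -> C with a module
# supernode fed by TF1 and feeding back to A.
toy_network <- function() {
  nodes <- data.frame(
    node = c("TF1", "A", "B", "C", "GEM01"),
    type = c("protein", "protein", "protein", "protein", "gem_supernode"),
    prize = c(100, 0, 0, 0, 0), stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("TF1", "A", "B", "TF1", "GEM01"),
    target = c("A", "B", "C", "GEM01", "A"),
    sign = c(1L, 1L, -1L, 1L, 1L),
    weight = c(0.9, 0.8, -0.7, 1, 1),
    origin = c("pcsf", "pcsf", "pcsf", "tf_gem", "gem_feedback"),
    stringsAsFactors = FALSE)
  assembled_network(nodes, edges)
}

# Random connected undirected instance for PCSF oracle comparisons.
random_pcsf_instance <- function(n_nodes, n_extra_edges, n_prizes, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  # random spanning tree first, then extra edges
  edges <- data.frame(u = character(0), v = character(0), cost = numeric(0),
                      stringsAsFactors = FALSE)
  for (i in 2:n_nodes) {
    j <- sample(i - 1L, 1)
    edges <- rbind(edges, data.frame(u = nodes[j], v = nodes[i],
                                     cost = round(stats::runif(1, 0.1, 1), 3)))
  }
  tries <- 0
  while (n_extra_edges > 0 && tries < 50) {
    ij <- sort(sample(n_nodes, 2))
    key <- paste(nodes[ij[1]], nodes[ij[2]])
    have <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
    if (!(key %in% have)) {
      edges <- rbind(edges, data.frame(u = nodes[ij[1]], v = nodes[ij[2]],
                                       cost = round(stats::runif(1, 0.1, 1), 3)))
      n_extra_edges <- n_extra_edges - 1
    }
    tries <- tries + 1
  }
  prizes <- stats::setNames(round(stats::runif(n_prizes, 0.5, 4), 3),
                            sample(nodes, n_prizes))
  list(nodes = nodes, edges = edges, prizes = prizes)
}

# Convert an oracle-style instance into a prior_network + cost vector.
as_prior <- function(inst) {
  ed <- data.frame(source = inst$edges$u, target = inst$edges$v,
                   sign = 1L, n_sources = 1L, stringsAsFactors = FALSE)
  list(prior = prior_network(ed, nodes = inst$nodes),
       costs = inst$edges$cost)
}

# Tiny ontology: root T1 with two branches of two leaves each.
tiny_ontology <- function() {
  parents <- data.frame(
    child = c("T1", "T2", "T3", "T4", "T5", "T6", "T7"),
    parent = c(NA, "T1", "T1", "T2", "T2", "T3", "T3"),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    gene = c("gA", "gA", "gB", "gC", "gD", "gE"),
    term = c("T4", "T6", "T4", "T5", "T6", "T7"),
    stringsAsFactors = FALSE)
  build_ontology(parents, ann)
}
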