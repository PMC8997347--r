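# Phenotype-specific network assembly: edge costs from citation counts,
# prize collection with hub penalization, a randomized prize-collecting
# Steiner forest heuristic (virtual root + metric-closure MST + strong
# pruning), supernode augmentation and basic network statistics.

#' PCSF parameters
#'
#' @param prize_value prize assigned to every selected node (default 100).
#' @param b prize tuning multiplier (default 1).
#' @param w virtual-root edge cost controlling forest fragmentation
#'   (default 40).
#' @param mu hub-penalization coefficient on prior-network degree
#'   (default 0.005).
#' @param noise_frac multiplicative edge-cost noise per randomized run
#'   (default 0.05).
#' @param iterations randomized runs whose union is returned (default 30).
#' @param seed RNG seed for the noisy runs.
#' @return list of class `pcsf_params`.
#' @export
pcsf_params <- function(prize_value = 100, b = 1, w = 40, mu = 0.005,
                        noise_frac = 0.05, iterations = 30, seed = NULL) {
  check_that(all(c(prize_value, b, w, mu, noise_frac) >= 0),
             "PCSF parameters must be non-negative")
  check_that(iterations >= 1, "iterations must be >= 1")
  structure(list(prize_value = prize_value, b = b, w = w, mu = mu,
                 noise_frac = noise_frac, iterations = iterations,
                 seed = seed), class = "pcsf_params")
}

#' Edge costs from citation counts
#'
#' The reliability score of an edge is the inverse of its source count,
#' `s_e = 1 / n_sources`, min-max scaled to `[0, 1]`: well-documented edges
#' are cheap (the global maximum source count maps to cost 0, a single
#' source to cost 1). When all edges tie, every cost is 0.5.
#'
#' @param prior a `prior_network`.
#' @return numeric cost vector aligned with `prior$edges`.
#' @export
edge_costs <- function(prior) {
  stopifnot(inherits(prior, "prior_network"))
  s <- 1 / prior$edges$n_sources
  rng <- range(s)
  if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else
    rep(0.5, length(s))
}

#' Collect node prizes with hub penalization
#'
#' The prize set is the union of module-regulating TFs, differentially
#' active TFs and enriched-pathway member proteins; each gets
#' `prize_value`. The effective prize is `b * prize - mu * degree` (degree
#' in the full prior network), floored at zero. Prize nodes absent from the
#' prior network are kept with a warning (they may stay unreachable).
#'
#' @param tf_module_hits,de_tf_hits,pathway_proteins character node sets.
#' @param prior a `prior_network`.
#' @param params a [pcsf_params()].
#' @return named numeric vector of effective prizes.
#' @export
collect_prizes <- function(tf_module_hits, de_tf_hits, pathway_proteins,
                           prior, params = pcsf_params()) {
  nodes <- unique(c(tf_module_hits, de_tf_hits, pathway_proteins))
  if (length(nodes) == 0L) return(stats::setNames(numeric(0), character(0)))
  absent <- setdiff(nodes, prior$nodes)
  if (length(absent) > 0L) {
    warning(sprintf("%d prize node(s) absent from the prior network: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")),
            call. = FALSE)
  }
  deg <- table(c(prior$edges$source, prior$edges$target))
  d <- ifelse(nodes %in% names(deg), as.numeric(deg[nodes]), 0)
  prize <- pmax(params$b * params$prize_value - params$mu * d, 0)
  stats::setNames(prize, nodes)
}

# Undirected igraph view of the prior network with per-edge cost.
prior_undirected <- function(prior, costs) {
  ed <- data.frame(from = prior$edges$source, to = prior$edges$target,
                   cost = costs, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = prior$nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(cost = "min"))
}

# Exact prize-collecting forest on a tree/forest prior by dynamic
# programming. State per vertex: excluded (pay prize) vs included in an
# open component (w charged when the component closes at its top).
pcsf_tree_dp <- function(g, prizes, w) {
  vn <- igraph::V(g)$name
  n <- length(vn)
  p <- ifelse(vn %in% names(prizes), unname(prizes[vn]), 0)
  adj <- igraph::as_adj_list(g)
  f0 <- f1 <- rep(NA_real_, n)
  comp <- igraph::components(g)
  total <- 0
  keep <- logical(n)
  sel_edges <- matrix(character(0), ncol = 2)
  for (ci in seq_len(comp$no)) {
    ridx <- which(comp$membership == ci)[1]
    # BFS order
    parent <- rep(NA_integer_, n); ord <- ridx
    seen <- logical(n); seen[ridx] <- TRUE
    head <- 1L
    while (head <= length(ord)) {
      v <- ord[head]; head <- head + 1L
      for (u in as.integer(adj[[v]])) if (!seen[u]) {
        seen[u] <- TRUE; parent[u] <- v; ord <- c(ord, u)
      }
    }
    ecost <- function(a, b) {
      igraph::E(g)$cost[igraph::get_edge_ids(g, c(a, b))]
    }
    children <- split(ord[-1][!is.na(parent[ord[-1]])],
                      parent[ord[-1]])
    for (v in rev(ord)) {
      kids <- children[[as.character(v)]]
      c0 <- p[v]; c1 <- 0
      for (c in kids) {
        closed <- min(f0[c], f1[c] + w)
        c0 <- c0 + closed
        c1 <- c1 + min(ecost(v, c) + f1[c], closed)
      }
      f0[v] <- c0; f1[v] <- c1
    }
    total <- total + min(f0[ridx], f1[ridx] + w)
    # reconstruct
    include <- rep(NA, n)
    include[ridx] <- f1[ridx] + w < f0[ridx]
    keep[ridx] <- include[ridx]
    for (v in ord) {
      kids <- children[[as.character(v)]]
      for (c in kids) {
        closed <- min(f0[c], f1[c] + w)
        join <- include[v] && (ecost(v, c) + f1[c] < closed)
        if (join) {
          include[c] <- TRUE
          sel_edges <- rbind(sel_edges, c(vn[v], vn[c]))
        } else {
          include[c] <- f1[c] + w < f0[c]
        }
        keep[c] <- include[c]
      }
    }
  }
  list(nodes = vn[keep], el = sel_edges, objective = total)
}

# Strong pruning of a tree (igraph, rooted): returns names of kept vertices.
# A child subtree is kept when its pruned worth exceeds the connecting edge
# cost; W(v) = prize(v) + sum over kept children of (W(c) - cost(v, c)).
strong_prune <- function(tree, root, prizes) {
  n <- igraph::vcount(tree)
  vn <- igraph::V(tree)$name
  prize_of <- ifelse(vn %in% names(prizes), unname(prizes[vn]), 0)
  adj <- igraph::as_adj_list(tree)
  ridx <- which(vn == root)
  parent <- rep(NA_integer_, n)
  ord <- integer(0)
  queue <- ridx
  seen <- logical(n)
  seen[ridx] <- TRUE
  while (length(queue) > 0) {          # BFS order: parents before children
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (u in as.integer(adj[[v]])) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  worth <- prize_of
  keep_edge <- rep(TRUE, n)   # keep_edge[v]: edge (parent[v], v) retained
  for (v in rev(ord)) {
    p <- parent[v]
    if (is.na(p)) next
    eid <- igraph::get_edge_ids(tree, c(p, v))
    ecost <- igraph::E(tree)$cost[eid]
    if (worth[v] - ecost > 0) {
      worth[p] <- worth[p] + worth[v] - ecost
    } else {
      keep_edge[v] <- FALSE
    }
  }
  kept <- logical(n)
  kept[ridx] <- TRUE
  for (v in ord) {
    if (v == ridx) next
    kept[v] <- kept[parent[v]] && keep_edge[v]
  }
  vn[kept]
}

#' Solve one prize-collecting Steiner forest instance
#'
#' Heuristic on the undirected view of the prior network: a virtual root is
#' connected to every positive-prize node at cost `w`; the shortest-path
#' metric closure over the terminals is spanned by a minimum spanning tree,
#' expanded back to graph paths, re-spanned, and strongly pruned so that
#' subtrees whose collected prize does not cover their connection cost are
#' dropped. The returned forest approximately minimizes
#' `sum(edge costs) + w * (number of trees) + sum(prizes of excluded
#' nodes)`. Edge directions and signs are restored from the prior network.
#'
#' @param prior a `prior_network`.
#' @param costs per-edge costs in `[0, 1]` aligned with `prior$edges`.
#' @param prizes named non-negative prize vector.
#' @param params a [pcsf_params()] (only `w` is used here).
#' @return list with `nodes`, `edges` (prior rows restored, plus `cost`),
#'   and `objective`.
#' @export
pcsf_solve <- function(prior, costs, prizes, params = pcsf_params()) {
  stopifnot(inherits(prior, "prior_network"))
  check_that(all(costs >= 0), "costs must be non-negative")
  check_that(all(prizes >= 0), "prizes must be non-negative")
  prizes <- prizes[prizes > 0]
  terminals <- intersect(names(prizes), prior$nodes)
  empty <- list(nodes = character(0),
                edges = cbind(prior$edges[0, ], cost = numeric(0)),
                objective = sum(prizes))
  if (length(terminals) == 0L) return(empty)

  g0 <- prior_undirected(prior, costs)
  if (igraph::is_forest(g0)) {
    # a forest prior admits the exact dynamic program
    best <- pcsf_tree_dp(g0, prizes, params$w)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    sel_keys <- if (nrow(best$el) > 0) key(best$el[, 1], best$el[, 2]) else
      character(0)
    hit <- key(prior$edges$source, prior$edges$target) %in% sel_keys
    out_edges <- cbind(prior$edges[hit, , drop = FALSE], cost = costs[hit])
    rownames(out_edges) <- NULL
    return(list(nodes = best$nodes, edges = out_edges,
                objective = best$objective))
  }
  g <- g0
  root <- "..root.."
  g <- igraph::add_vertices(g, 1, name = root)
  g <- igraph::add_edges(g, as.vector(rbind(root, terminals)),
                         cost = params$w)

  # candidate Steiner trees: (a) expansion of the metric-closure MST over
  # the terminals, which exploits terminal-terminal proximity; (b) the
  # union of direct root-to-terminal shortest paths, which lets strong
  # pruning judge each prize against its own connection cost. Each
  # candidate is spanned, strongly pruned, and scored; the better forest
  # wins.
  terms <- c(root, terminals)
  dmat <- igraph::distances(g, v = terms, to = terms,
                            weights = igraph::E(g)$cost)
  dmat <- (dmat + t(dmat)) / 2        # exact symmetry at floating point
  closure <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                 weighted = TRUE,
                                                 diag = FALSE)
  mst_c <- igraph::mst(closure, weights = igraph::E(closure)$weight)
  path_eids <- function(pairs) {
    eids <- integer(0)
    for (i in seq_len(nrow(pairs))) {
      sp <- igraph::shortest_paths(g, from = pairs[i, 1], to = pairs[i, 2],
                                   weights = igraph::E(g)$cost,
                                   output = "epath")$epath[[1]]
      eids <- union(eids, as.integer(sp))
    }
    eids
  }
  cand_a <- path_eids(igraph::as_edgelist(mst_c))
  cand_b <- path_eids(cbind(root, terminals))
  mst_g <- igraph::mst(g, weights = igraph::E(g)$cost)
  cand_c <- as.integer(igraph::get_edge_ids(
    g, as.vector(t(igraph::as_edgelist(mst_g)))))

  evaluate <- function(eids) {
    sub <- igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
    tree <- igraph::mst(sub, weights = igraph::E(sub)$cost)
    kept <- strong_prune(tree, root, prizes)
    tr_kept <- igraph::induced_subgraph(tree,
                                        intersect(kept,
                                                  igraph::V(tree)$name))
    el_kept <- igraph::as_edgelist(tr_kept)
    ecost <- igraph::E(tr_kept)$cost
    real <- el_kept[, 1] != root & el_kept[, 2] != root
    n_trees <- sum(el_kept[, 1] == root | el_kept[, 2] == root)
    kept_net <- setdiff(kept, root)
    obj <- sum(ecost[real]) + params$w * n_trees +
      sum(prizes[setdiff(names(prizes), kept_net)])
    list(nodes = kept_net, el = el_kept[real, , drop = FALSE],
         objective = obj)
  }
  sols <- list(evaluate(cand_a), evaluate(union(cand_a, cand_b)),
               evaluate(cand_b), evaluate(cand_c))
  best <- sols[[which.min(vapply(sols, `[[`, numeric(1), "objective"))]]

  # one refinement pass: rebuild the closure over the terminals that
  # survived pruning (dropped low-value prizes no longer distort the tree)
  surv <- intersect(best$nodes, terminals)
  if (length(surv) > 0 && length(surv) < length(terminals)) {
    terms2 <- c(root, surv)
    d2 <- dmat[terms2, terms2, drop = FALSE]
    d2 <- (d2 + t(d2)) / 2
    cl2 <- igraph::graph_from_adjacency_matrix(d2, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
    mst2 <- igraph::mst(cl2, weights = igraph::E(cl2)$weight)
    # evaluate() charges every excluded prize, so objectives are comparable
    ref <- evaluate(path_eids(igraph::as_edgelist(mst2)))
    if (ref$objective < best$objective) best <- ref
  }

  # restore directed signed prior edges between selected pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  sel_keys <- if (nrow(best$el) > 0) key(best$el[, 1], best$el[, 2]) else
    character(0)
  pe <- prior$edges
  pk <- key(pe$source, pe$target)
  hit <- pk %in% sel_keys
  out_edges <- cbind(pe[hit, , drop = FALSE], cost = costs[hit])
  rownames(out_edges) <- NULL
  list(nodes = best$nodes, edges = out_edges, objective = best$objective)
}

#' Randomized PCSF union
#'
#' Runs [pcsf_solve()] `iterations` times, multiplying every edge cost by
#' `1 + u`, `u ~ Uniform(-noise_frac, noise_frac)`, and returns the union
#' of the node and edge sets. Deterministic given the seed.
#'
#' @inheritParams pcsf_solve
#' @return list with `nodes`, `edges` (union over runs, base costs) and
#'   `objective` (of the noiseless base solution).
#' @export
pcsf_union <- function(prior, costs, prizes, params = pcsf_params()) {
  base <- pcsf_solve(prior, costs, prizes, params)
  if (params$iterations == 1L || params$noise_frac == 0) return(base)
  nodes <- base$nodes
  edges <- base$edges
  with_seed(params$seed, {
    for (it in seq_len(params$iterations - 1L)) {
      noisy <- costs * (1 + stats::runif(length(costs), -params$noise_frac,
                                         params$noise_frac))
      sol <- pcsf_solve(prior, noisy, prizes, params)
      nodes <- union(nodes, sol$nodes)
      new <- !(paste(sol$edges$source, sol$edges$target) %in%
                 paste(edges$source, edges$target))
      if (any(new)) {
        add <- sol$edges[new, , drop = FALSE]
        # report base costs, not the noisy ones
        idx <- match(paste(add$source, add$target),
                     paste(prior$edges$source, prior$edges$target))
        add$cost <- costs[idx]
        edges <- rbind(edges, add)
      }
    }
  })
  list(nodes = nodes, edges = edges, objective = base$objective)
}

#' Construct an assembled network
#'
#' @param nodes data.frame with columns `node`, `type` (one of `protein`,
#'   `gem_supernode`, `phenotype`), `prize`.
#' @param edges data.frame with columns `source`, `target`, `sign`,
#'   `weight`, `origin` (one of `pcsf`, `tf_gem`, `gem_phenotype`,
#'   `gem_feedback`); `gem_phenotype` edges are undirected, the rest
#'   directed.
#' @return object of class `assembled_network`.
#' @export
assembled_network <- function(nodes, edges) {
  check_that(all(c("node", "type", "prize") %in% colnames(nodes)),
             "nodes need columns node, type, prize")
  check_that(all(c("source", "target", "sign", "weight", "origin") %in%
                   colnames(edges)),
             "edges need columns source, target, sign, weight, origin")
  check_that(all(edges$origin %in% c("pcsf", "tf_gem", "gem_phenotype",
                                     "gem_feedback")),
             "unknown edge origin")
  check_that(all(edges$weight[edges$origin == "gem_feedback"] == 1),
             "feedback edges must have weight exactly 1")
  structure(list(nodes = nodes, edges = edges), class = "assembled_network")
}

#' @export
print.assembled_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat(sprintf("Assembled network: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(tt), tt), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' igraph view of an assembled network
#'
#' Directed view duplicates the undirected `gem_phenotype` edges in both
#' directions; the undirected view collapses everything.
#'
#' @param net an `assembled_network`.
#' @param directed logical.
#' @return an igraph graph with edge attributes `weight`, `sign`, `origin`
#'   (and `capacity` if present).
#' @export
as_igraph <- function(net, directed = TRUE) {
  ed <- net$edges
  if (directed) {
    undir <- ed[ed$origin == "gem_phenotype", , drop = FALSE]
    if (nrow(undir) > 0) {
      rev <- undir
      rev$source <- undir$target
      rev$target <- undir$source
      ed <- rbind(ed, rev)
    }
  }
  cols <- intersect(c("sign", "weight", "origin", "capacity"), colnames(ed))
  igraph::graph_from_data_frame(
    cbind(ed[, c("source", "target")], ed[, cols, drop = FALSE]),
    directed = directed,
    vertices = data.frame(name = net$nodes$node))
}

#' Augment a PCSF solution with module and phenotype supernodes
#'
#' Adds one supernode per module, with incoming edges from in-network TFs
#' whose regulon overlaps the module (one-sided Fisher p below `alpha_tf`);
#' phenotype nodes connected undirected to modules with `|PCC| > r_min`
#' and Student p below `p_max`; and feedback edges of weight exactly 1 from
#' each supernode to its member proteins present in the network. Supernodes
#' that end up with no incident edge are dropped with a message.
#'
#' @param pcsf_net result of [pcsf_union()] / [pcsf_solve()].
#' @param modules a `module_set` (or named list of gene vectors).
#' @param regulons regulon list as in [regulon_module_enrichment()].
#' @param shape_corr a `module_shape_correlation` (or `NULL` to skip
#'   phenotype nodes).
#' @param prizes named prize vector used for the node table.
#' @param universe gene universe for the overlap tests.
#' @param alpha_tf TF-overlap threshold (default 0.1).
#' @param r_min,p_max phenotype-edge thresholds (defaults 0.5, 0.05).
#' @return an `assembled_network`.
#' @export
add_supernodes <- function(pcsf_net, modules, regulons, shape_corr = NULL,
                           prizes = numeric(0), universe = NULL,
                           alpha_tf = 0.1, r_min = 0.5, p_max = 0.05) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  base_edges <- data.frame(source = pcsf_net$edges$source,
                           target = pcsf_net$edges$target,
                           sign = pcsf_net$edges$sign,
                           weight = 1,
                           origin = "pcsf", stringsAsFactors = FALSE)
  net_nodes <- union(pcsf_net$nodes,
                     union(base_edges$source, base_edges$target))
  extra <- list()
  used_supernodes <- character(0)
  used_phenotypes <- character(0)

  in_net_tfs <- intersect(names(regulons), net_nodes)
  if (length(in_net_tfs) > 0 && length(mods) > 0) {
    enr <- regulon_module_enrichment(mods, regulons[in_net_tfs], universe,
                                     alpha = alpha_tf)
    hits <- enr[enr$significant, , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("tf", "module")]), , drop = FALSE]
    if (nrow(hits) > 0) {
      extra[[length(extra) + 1L]] <- data.frame(
        source = hits$tf, target = hits$module, sign = 1L, weight = 1,
        origin = "tf_gem", stringsAsFactors = FALSE)
      used_supernodes <- union(used_supernodes, hits$module)
    }
  }
  for (m in setdiff(names(mods), used_supernodes)) {
    msg(sprintf("module %s has no qualifying TF; unconnected so far", m))
  }

  if (!is.null(shape_corr)) {
    sig <- which(abs(shape_corr$pcc) > r_min & shape_corr$p_student < p_max,
                 arr.ind = TRUE)
    if (nrow(sig) > 0) {
      extra[[length(extra) + 1L]] <- data.frame(
        source = rownames(shape_corr$pcc)[sig[, 1]],
        target = colnames(shape_corr$pcc)[sig[, 2]],
        sign = ifelse(shape_corr$pcc[sig] >= 0, 1L, -1L),
        weight = 1, origin = "gem_phenotype", stringsAsFactors = FALSE)
      used_supernodes <- union(used_supernodes,
                               rownames(shape_corr$pcc)[sig[, 1]])
      used_phenotypes <- unique(colnames(shape_corr$pcc)[sig[, 2]])
    }
  }

  for (m in names(mods)) {
    members_in <- intersect(mods[[m]], net_nodes)
    if (length(members_in) > 0) {
      extra[[length(extra) + 1L]] <- data.frame(
        source = m, target = members_in, sign = 1L, weight = 1,
        origin = "gem_feedback", stringsAsFactors = FALSE)
      used_supernodes <- union(used_supernodes, m)
    }
  }

  dropped <- setdiff(names(mods), used_supernodes)
  if (length(dropped) > 0) {
    msg(sprintf("dropping isolated supernode(s): %s",
                paste(dropped, collapse = ", ")))
  }
  edges <- rbind(base_edges, do.call(rbind, extra))
  nodes <- data.frame(
    node = c(net_nodes, intersect(names(mods), used_supernodes),
             used_phenotypes),
    type = c(rep("protein", length(net_nodes)),
             rep("gem_supernode", length(intersect(names(mods),
                                                   used_supernodes))),
             rep("phenotype", length(used_phenotypes))),
    stringsAsFactors = FALSE)
  nodes$prize <- ifelse(nodes$node %in% names(prizes),
                        prizes[nodes$node], 0)
  assembled_network(nodes, edges)
}

#' Basic statistics of an assembled network
#'
#' Degree per node, betweenness centrality (shortest paths with
#' `|weight|`, floored at 1e-6, as distances) and the fraction of prize
#' nodes included in the network.
#'
#' @param net an `assembled_network`.
#' @param prizes named prize vector (defaults to the node table's prizes).
#' @return list with `node_stats` (data.frame `node`, `degree`,
#'   `betweenness`, sorted by betweenness) and `prize_coverage`.
#' @export
network_stats <- function(net, prizes = NULL) {
  check_that(nrow(net$nodes) > 0, "empty network")
  g <- as_igraph(net, directed = FALSE)
  dist_w <- pmax(abs(igraph::E(g)$weight), 1e-6)
  bt <- igraph::betweenness(g, weights = dist_w, directed = FALSE)
  deg <- igraph::degree(g)
  if (is.null(prizes)) {
    prizes <- stats::setNames(net$nodes$prize, net$nodes$node)
    prizes <- prizes[prizes > 0]
  }
  cov <- if (length(prizes) == 0L) NA_real_ else
    mean(names(prizes) %in% net$nodes$node)
  ns <- data.frame(node = names(bt), degree = as.integer(deg[names(bt)]),
                   betweenness = as.numeric(bt), stringsAsFactors = FALSE)
  list(node_stats = ns[order(-ns$betweenness), ], prize_coverage = cov)
}
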