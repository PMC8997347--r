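# Semantic-similarity edge reweighting and network propagation: Resnik
# best-match-average similarity over a flat ontology, random walk with
# restart from TF-activity seeds, empirical seed-randomization
# significance, and shortest-path explanation subgraphs.

#' Build an ontology object
#'
#' Constructs a rooted DAG from a parent-child table and gene-term
#' annotations, precomputing ancestor closures and information content:
#' `IC(t) = -ln(fraction of annotated genes annotated to t or a
#' descendant)`. A single root (the only term with no parent) is required
#' and has IC 0.
#'
#' @param parents_df data.frame with columns `child`, `parent` (root rows
#'   may carry `NA` parent).
#' @param annotations_df data.frame with columns `gene`, `term`.
#' @return object of class `ontology` with elements `terms`, `root`,
#'   `ancestors` (named list, each including the term itself), `ic`,
#'   `gene_terms`, plus the raw tables for round-tripping.
#' @export
build_ontology <- function(parents_df, annotations_df) {
  pc <- parents_df[!is.na(parents_df$parent), , drop = FALSE]
  terms <- union(parents_df$child, pc$parent)
  roots <- setdiff(terms, pc$child)
  check_that(length(roots) == 1, "ontology must have exactly one root")
  root <- roots
  parent_of <- split(pc$parent, pc$child)

  ancestors <- stats::setNames(vector("list", length(terms)), terms)
  anc <- function(t) {
    if (!is.null(ancestors[[t]])) return(ancestors[[t]])
    ps <- parent_of[[t]]
    out <- if (is.null(ps)) t else
      unique(c(t, unlist(lapply(ps, anc))))
    ancestors[[t]] <<- out
    out
  }
  for (t in terms) anc(t)

  bad <- setdiff(annotations_df$term, terms)
  check_that(length(bad) == 0,
             sprintf("annotations reference unknown terms: %s",
                     paste(utils::head(bad, 3), collapse = ", ")))
  gene_terms <- lapply(split(annotations_df$term, annotations_df$gene), unique)

  n_genes <- length(gene_terms)
  counts <- stats::setNames(integer(length(terms)), terms)
  for (g in names(gene_terms)) {
    covered <- unique(unlist(ancestors[gene_terms[[g]]]))
    counts[covered] <- counts[covered] + 1L
  }
  ic <- ifelse(counts > 0, -log(counts / n_genes), 0)
  ic[root] <- 0
  structure(list(terms = terms, root = root, ancestors = ancestors,
                 ic = ic, gene_terms = gene_terms,
                 parents_df = parents_df, annotations_df = annotations_df),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms (root %s), %d annotated genes\n",
              length(x$terms), x$root, length(x$gene_terms)))
  invisible(x)
}

# IC of the most-informative common ancestor of two terms.
mica_ic <- function(ontology, t1, t2) {
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  if (length(common) == 0L) return(0)
  max(ontology$ic[common])
}

#' Resnik best-match-average semantic similarity
#'
#' Pairwise term similarity is the information content of the
#' most-informative common ancestor; the gene-level score is the
#' best-match average: half the mean (over A's terms) of the best match in
#' B plus half the symmetric quantity. An unannotated gene yields
#' similarity 0 with a warning.
#'
#' @param ontology an `ontology`.
#' @param gene_a,gene_b gene identifiers.
#' @return non-negative similarity (symmetric in its arguments).
#' @export
resnik_bma <- function(ontology, gene_a, gene_b) {
  ta <- ontology$gene_terms[[gene_a]]
  tb <- ontology$gene_terms[[gene_b]]
  if (is.null(ta) || is.null(tb)) {
    warning(sprintf("gene '%s' not annotated; similarity 0",
                    if (is.null(ta)) gene_a else gene_b), call. = FALSE)
    return(0)
  }
  simmat <- outer(ta, tb, Vectorize(function(x, y) mica_ic(ontology, x, y)))
  (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2
}

#' Reweight network edges by semantic similarity
#'
#' Protein-protein (`pcsf`) edges get the Resnik BMA similarity of their
#' endpoints, min-max scaled to `[0, 1]` across those edges and then
#' signed by the prior-network interaction sign, yielding weights in
#' `[-1, 1]`; the unsigned scaled similarity is stored as `capacity`.
#' Supernode and feedback edges keep weight and capacity 1.
#'
#' @param net an `assembled_network`.
#' @param ontology an `ontology`.
#' @return the network with updated `weight` and added `capacity` columns.
#' @export
reweight_edges <- function(net, ontology) {
  ed <- net$edges
  is_pp <- ed$origin == "pcsf"
  sims <- rep(NA_real_, nrow(ed))
  if (any(is_pp)) {
    sims[is_pp] <- suppressWarnings(
      mapply(function(a, b) resnik_bma(ontology, a, b),
             ed$source[is_pp], ed$target[is_pp]))
    rng <- range(sims[is_pp])
    scaled <- if (rng[2] > rng[1]) (sims[is_pp] - rng[1]) / (rng[2] - rng[1])
              else rep(0.5, sum(is_pp))
    ed$weight[is_pp] <- scaled * ed$sign[is_pp]
    ed$capacity <- 1
    ed$capacity[is_pp] <- scaled
  } else {
    ed$capacity <- 1
  }
  net$edges <- ed
  net
}

# Row-normalized transition structure for the walk; returns the transition
# matrix (rows = from) and the dangling-node indicator.
rwr_transition <- function(net, negative = c("zero", "abs")) {
  negative <- match.arg(negative)
  g <- as_igraph(net, directed = TRUE)
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  w <- if (negative == "zero") pmax(w, 0) else abs(w)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(el))) {
    W[el[i, 1], el[i, 2]] <- W[el[i, 1], el[i, 2]] + w[i]
  }
  rs <- rowSums(W)
  dangling <- rs == 0
  W[!dangling, ] <- W[!dangling, , drop = FALSE] / rs[!dangling]
  list(W = W, dangling = dangling, nodes = nodes)
}

#' Random walk with restart
#'
#' Iterates `p <- r * s + (1 - r) * (t(W) p + mass_on_dangling * s)` until
#' the L1 change drops below `tol`; transitions use the positive part of
#' the edge weights (or their absolute value with `negative = "abs"`), row
#' normalized, and dangling nodes restart fully. The result equals the
#' closed-form solve of the linear system.
#'
#' @param net an `assembled_network` (weights in `[-1, 1]`).
#' @param seeds named non-negative seed masses (normalized internally).
#' @param r restart probability (default 0.95).
#' @param negative handling of negative weights: `"zero"` (default) or
#'   `"abs"`.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @return named steady-state probability vector (sums to 1).
#' @export
rwr <- function(net, seeds, r = 0.95, negative = c("zero", "abs"),
                tol = 1e-10) {
  tr <- rwr_transition(net, negative)
  rwr_solve(tr, seeds, r, tol)
}

# Core solver on a precomputed transition structure (reused by the
# randomization loop).
rwr_solve <- function(tr, seeds, r = 0.95, tol = 1e-10) {
  check_that(all(seeds >= 0) && sum(seeds) > 0,
             "seed masses must be non-negative with positive sum")
  check_that(all(names(seeds) %in% tr$nodes), "unknown seed node")
  n <- length(tr$nodes)
  s <- stats::setNames(numeric(n), tr$nodes)
  s[names(seeds)] <- seeds / sum(seeds)
  if (all(rowSums(tr$W) == 0)) {
    warning("no positive-weight transitions; returning the seed distribution",
            call. = FALSE)
    return(s)
  }
  p <- s
  Wt <- t(tr$W)
  repeat {
    p_new <- r * s + (1 - r) * (as.vector(Wt %*% p) + sum(p[tr$dangling]) * s)
    if (sum(abs(p_new - p)) < tol) break
    p <- p_new
  }
  stats::setNames(as.vector(p_new), tr$nodes)
}

#' Empirical significance of propagation affinities
#'
#' Runs the observed walk, then `n_rand` walks whose seed masses are
#' reassigned to uniformly sampled node sets of the same size (values
#' preserved). For each non-seed node,
#' `p = (1 + #\{random affinity >= observed\}) / (n_rand + 1)`; nodes with
#' p below `alpha` are flagged significant.
#'
#' @inheritParams rwr
#' @param n_rand number of randomizations (>= 100; default 10000).
#' @param alpha significance level (default 0.1).
#' @param seed RNG seed.
#' @return data.frame of class `rwr_result`: `node`, `probability`,
#'   `is_seed`, `p`, `significant`.
#' @export
seed_significance <- function(net, seeds, n_rand = 10000, alpha = 0.1,
                              r = 0.95, negative = c("zero", "abs"),
                              seed = NULL) {
  check_that(n_rand >= 100, "n_rand must be >= 100")
  tr <- rwr_transition(net, negative)
  check_that(length(seeds) < length(tr$nodes),
             "seeds must not cover every node")
  obs <- rwr_solve(tr, seeds, r)
  masses <- as.numeric(seeds)
  k <- length(masses)
  exceed <- stats::setNames(integer(length(tr$nodes)), tr$nodes)
  with_seed(seed, {
    for (b in seq_len(n_rand)) {
      loc <- sample(tr$nodes, k)
      rnd <- rwr_solve(tr, stats::setNames(masses, loc), r)
      exceed <- exceed + (rnd >= obs)
    }
  })
  p <- (1 + exceed) / (n_rand + 1)
  is_seed <- tr$nodes %in% names(seeds)
  p[is_seed] <- NA_real_
  out <- data.frame(node = tr$nodes, probability = as.numeric(obs),
                    is_seed = is_seed, p = as.numeric(p),
                    significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("rwr_result", class(out))
  out[order(-out$probability), ]
}

#' Per-seed decomposition of a random walk
#'
#' Runs [rwr()] once per seed (each seed alone, full mass).
#'
#' @inheritParams rwr
#' @return matrix, nodes x seeds, of steady-state probabilities.
#' @export
rwr_per_seed <- function(net, seeds, r = 0.95, negative = c("zero", "abs")) {
  tr <- rwr_transition(net, negative)
  out <- vapply(names(seeds), function(sd) {
    rwr_solve(tr, stats::setNames(seeds[sd], sd), r)
  }, numeric(length(tr$nodes)))
  rownames(out) <- tr$nodes
  out
}

#' Union of all shortest paths from sources to a target
#'
#' Edge distance is `1 - |weight|`, floored at 1e-6. All shortest paths
#' from every source to the target are collected; unreachable sources are
#' reported. An empty subgraph is returned (with a warning) when no source
#' reaches the target.
#'
#' @param net an `assembled_network`.
#' @param sources character vector of source nodes (e.g. TFs).
#' @param target target node.
#' @return list with `edges` (data.frame `source`, `target`, `weight`),
#'   `nodes`, and `unreachable` sources.
#' @export
shortest_path_subgraph <- function(net, sources, target) {
  g <- as_igraph(net, directed = TRUE)
  check_that(target %in% igraph::V(g)$name, "target not in network")
  sources <- intersect(sources, igraph::V(g)$name)
  dist_w <- pmax(1 - abs(igraph::E(g)$weight), 1e-6)
  eids <- integer(0)
  unreachable <- character(0)
  for (s in sources) {
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = target,
                                 weights = dist_w))
    paths <- sp$vpaths %||% sp$res
    if (length(paths) == 0L) {
      unreachable <- c(unreachable, s)
      next
    }
    for (pt in paths) {
      vs <- as.integer(pt)
      if (length(vs) >= 2) {
        ep <- igraph::get_edge_ids(g, as.vector(rbind(vs[-length(vs)],
                                                      vs[-1])))
        eids <- union(eids, as.integer(ep))
      }
    }
  }
  if (length(eids) == 0L) {
    warning("no source reaches the target", call. = FALSE)
    return(list(edges = data.frame(source = character(0),
                                   target = character(0),
                                   weight = numeric(0)),
                nodes = character(0), unreachable = unreachable))
  }
  el <- igraph::as_edgelist(g)[eids, , drop = FALSE]
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      weight = igraph::E(g)$weight[eids],
                      stringsAsFactors = FALSE)
  list(edges = edges, nodes = union(edges$source, edges$target),
       unreachable = unreachable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
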