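# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles and
# share no code with the package internals.

# Topological overlap by explicit triple loop.
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  t_out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    t_out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  t_out
}

# Hypergeometric upper-tail by explicit summation of choose() terms.
hyper_tail_oracle <- function(k, n_ref, n_universe, n_query) {
  kmax <- min(n_ref, n_query)
  if (k > kmax) return(0)
  total <- choose(n_universe, n_query)
  sum(vapply(k:kmax, function(x) {
    choose(n_ref, x) * choose(n_universe - n_ref, n_query - x) / total
  }, numeric(1)))
}

# Exhaustive prize-collecting Steiner forest optimum. Enumerates all
# acyclic edge subsets; objective = edge costs + w per tree + excluded
# prizes, where uncovered prize nodes contribute min(prize, w) (kept as a
# singleton tree when cheaper than forfeiting the prize).
pcsf_enum_oracle <- function(nodes, edges, prizes, w) {
  m <- nrow(edges)
  p <- ifelse(nodes %in% names(prizes), prizes[nodes], 0)
  names(p) <- nodes
  best <- sum(pmin(p, w))      # empty forest (singletons where worthwhile)
  for (mask in seq_len(2^m) - 1L) {
    if (mask == 0L) next
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    # union-find acyclicity + component count
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) {
      while (parent[[x]] != x) {
        parent[[x]] <<- parent[[parent[[x]]]]
        x <- parent[[x]]
      }
      x
    }
    acyclic <- TRUE
    for (e in sel) {
      ra <- find(edges$u[e]); rb <- find(edges$v[e])
      if (ra == rb) { acyclic <- FALSE; break }
      parent[[ra]] <- rb
    }
    if (!acyclic) next
    covered <- unique(c(edges$u[sel], edges$v[sel]))
    roots <- unique(vapply(covered, find, character(1)))
    obj <- sum(edges$cost[sel]) + w * length(roots) +
      sum(pmin(p[setdiff(nodes, covered)], w))
    if (obj < best) best <- obj
  }
  best
}

# PageRank by damped power iteration on the undirected weighted view.
pagerank_oracle <- function(nodes, edges_w, damping = 0.85, tol = 1e-14) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges_w))) {
    a <- edges_w$source[i]; b <- edges_w$target[i]; w <- edges_w$w[i]
    A[a, b] <- A[a, b] + w
    A[b, a] <- A[b, a] + w
  }
  rs <- rowSums(A)
  pr <- rep(1 / n, n)
  repeat {
    contrib <- rep(0, n)
    for (i in seq_len(n)) {
      if (rs[i] > 0) contrib <- contrib + pr[i] * A[i, ] / rs[i]
      else contrib <- contrib + pr[i] / n
    }
    pr_new <- (1 - damping) / n + damping * contrib
    if (sum(abs(pr_new - pr)) < tol) break
    pr <- pr_new
  }
  stats::setNames(pr_new, nodes)
}

# Closed-form random walk with restart (no dangling nodes expected).
rwr_closed_form <- function(W_rownorm, s, r) {
  n <- nrow(W_rownorm)
  as.vector(r * solve(diag(n) - (1 - r) * t(W_rownorm), s))
}

# Resnik BMA by exhaustive recursion over term pairs, recomputing
# ancestors independently of the package's closure.
resnik_oracle <- function(parents_df, annotations_df, g1, g2) {
  pc <- parents_df[!is.na(parents_df$parent), ]
  anc <- function(t) {
    ps <- pc$parent[pc$child == t]
    unique(c(t, unlist(lapply(ps, anc))))
  }
  genes <- unique(annotations_df$gene)
  term_count <- new.env()
  for (g in genes) {
    covered <- unique(unlist(lapply(
      annotations_df$term[annotations_df$gene == g], anc)))
    for (t in covered) {
      assign(t, (if (exists(t, term_count)) get(t, term_count) else 0) + 1,
             term_count)
    }
  }
  ic <- function(t) {
    cnt <- if (exists(t, term_count)) get(t, term_count) else 0
    if (cnt == 0) 0 else -log(cnt / length(genes))
  }
  mica <- function(t1, t2) {
    common <- intersect(anc(t1), anc(t2))
    if (length(common) == 0) return(0)
    max(vapply(common, ic, numeric(1)))
  }
  ta <- annotations_df$term[annotations_df$gene == g1]
  tb <- annotations_df$term[annotations_df$gene == g2]
  m <- outer(ta, tb, Vectorize(mica))
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# Minimum s-t cut by enumeration of all source-side subsets.
min_cut_oracle <- function(nodes, edges_cap, source, sink) {
  others <- setdiff(nodes, c(source, sink))
  best <- Inf
  for (mask in 0:(2^length(others) - 1L)) {
    side <- c(source, others[bitwAnd(mask, 2^(seq_along(others) - 1L)) > 0])
    cut <- sum(edges_cap$cap[edges_cap$from %in% side &
                               !(edges_cap$to %in% side)])
    if (cut < best) best <- cut
  }
  best
}
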