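# Over-representation and gene-set enrichment: one-sided Fisher tests for
# regulon-module overlap, TF-pathway enrichment with a rank-permutation
# combined score, a resampled-module pathway-bias null, and preranked GSEA.

#' One-sided Fisher overlap test
#'
#' Over-representation p-value for the overlap of `query` and `reference`
#' within `universe` (hypergeometric upper tail), and the sample odds ratio
#' with a Haldane 0.5 correction when any cell of the 2x2 table is zero.
#'
#' @param query,reference,universe character vectors; both sets must lie in
#'   the universe.
#' @return list with `p`, `odds_ratio`, `overlap` (character vector).
#' @export
fisher_overlap <- function(query, reference, universe) {
  check_that(length(universe) > 0, "empty universe")
  query <- unique(query); reference <- unique(reference)
  check_that(all(query %in% universe) && all(reference %in% universe),
             "query and reference must be subsets of the universe")
  ov <- intersect(query, reference)
  k <- length(ov)
  if (length(query) == 0L) {
    return(list(p = 1, odds_ratio = 0, overlap = character(0)))
  }
  N <- length(universe)
  p <- stats::phyper(k - 1, length(reference), N - length(reference),
                     length(query), lower.tail = FALSE)
  a <- k
  b <- length(query) - k
  cc <- length(reference) - k
  d <- N - length(query) - length(reference) + k
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(p = p, odds_ratio = (a * d) / (b * cc), overlap = ov)
}

#' Regulon-module overlap enrichment
#'
#' For each (TF, module) pair runs two one-sided Fisher tests: activated
#' plus unknown-sign targets, and repressed plus unknown-sign targets,
#' against the module's gene content. Pairs with p below `alpha` in either
#' direction are flagged significant.
#'
#' @param modules a `module_set` or named list of gene vectors.
#' @param regulons named list; per TF a list with `activated`, `repressed`,
#'   `unknown` character vectors.
#' @param universe gene universe for the tests (defaults to all module and
#'   regulon genes).
#' @param alpha significance threshold (default 0.1).
#' @return data.frame: `tf`, `module`, `direction`, `p`, `odds_ratio`,
#'   `n_overlap`, `significant`.
#' @export
regulon_module_enrichment <- function(modules, regulons, universe = NULL,
                                      alpha = 0.1) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  if (is.null(universe)) {
    universe <- union(unlist(modules), unlist(lapply(regulons, unlist)))
  }
  rows <- list()
  for (tf in names(regulons)) {
    reg <- regulons[[tf]]
    if (length(unlist(reg)) == 0L) {
      msg(sprintf("TF %s has no targets; skipped", tf))
      next
    }
    for (dir in c("activatory", "inhibitory")) {
      tset <- if (dir == "activatory") union(reg$activated, reg$unknown)
              else union(reg$repressed, reg$unknown)
      tset <- intersect(tset, universe)
      if (length(tset) == 0L) next
      for (mod in names(modules)) {
        modg <- intersect(modules[[mod]], universe)
        ft <- fisher_overlap(tset, modg, universe)
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, module = mod, direction = dir, p = ft$p,
          odds_ratio = ft$odds_ratio, n_overlap = length(ft$overlap),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(0), module = character(0),
                      direction = character(0), p = numeric(0),
                      odds_ratio = numeric(0), n_overlap = integer(0))
  }
  out$significant <- out$p < alpha
  out
}

#' TF-pathway enrichment with rank-permutation combined score
#'
#' Fisher over-representation p per pathway for a TF query set, combined
#' with a z-score measuring the deviation of the pathway's observed p-rank
#' from its expected rank over `B_rank` random query sets of matched size:
#' `combined_score = -ln(p) * z`. FDR is Benjamini-Hochberg across
#' pathways.
#'
#' @param tfs character query set.
#' @param genesets named list of pathway gene sets.
#' @param universe universe for the Fisher tests.
#' @param B_rank number of rank permutations (default 200).
#' @param seed RNG seed.
#' @return data.frame `term`, `p`, `odds_ratio`, `z`, `combined_score`,
#'   `fdr`, `n_overlap`, sorted by combined score.
#' @export
tf_pathway_enrichment <- function(tfs, genesets, universe, B_rank = 200,
                                  seed = NULL) {
  tfs <- intersect(tfs, universe)
  check_that(length(tfs) > 0, "query TFs must intersect the universe")
  path_p <- function(query) {
    vapply(genesets, function(gs) {
      fisher_overlap(query, intersect(gs, universe), universe)$p
    }, numeric(1))
  }
  obs <- lapply(names(genesets), function(nm) {
    fisher_overlap(tfs, intersect(genesets[[nm]], universe), universe)
  })
  p_obs <- vapply(obs, `[[`, numeric(1), "p")
  or_obs <- vapply(obs, `[[`, numeric(1), "odds_ratio")
  n_ov <- vapply(obs, function(o) length(o$overlap), integer(1))
  obs_rank <- rank(p_obs, ties.method = "average")
  null_ranks <- matrix(NA_real_, nrow = B_rank, ncol = length(genesets))
  with_seed(seed, {
    for (b in seq_len(B_rank)) {
      q <- sample(universe, length(tfs))
      null_ranks[b, ] <- rank(path_p(q), ties.method = "average")
    }
  })
  mu <- colMeans(null_ranks)
  sdv <- apply(null_ranks, 2, stats::sd)
  z <- ifelse(sdv > 0, (mu - obs_rank) / sdv, 0)
  combined <- -log(p_obs) * z
  out <- data.frame(term = names(genesets), p = p_obs, odds_ratio = or_obs,
                    z = z, combined_score = combined,
                    fdr = stats::p.adjust(p_obs, "BH"), n_overlap = n_ov,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$combined_score), ]
}

#' Pathway-bias null from resampled modules
#'
#' Repeats the TF-overlap -> pathway-enrichment chain on `B` random module
#' sets matched for the size profile of the observed modules, building a
#' per-pathway null distribution of enrichment p-values; chains in which no
#' TF is enriched contribute p = 1 for every pathway. The observed pathway
#' p is compared against its null, giving an empirical p with the +1
#' correction, FDR-adjusted across pathways.
#'
#' @param modules a `module_set` or named list (observed modules).
#' @param regulons regulon list as in [regulon_module_enrichment()].
#' @param genesets pathway sets.
#' @param universe gene universe the random modules are drawn from.
#' @param tf_universe universe for the pathway-level Fisher tests
#'   (defaults to `universe` plus all TF names).
#' @param B number of resampled module sets (>= 50; default 1000).
#' @param alpha_tf TF-overlap significance threshold (default 0.1).
#' @param seed RNG seed.
#' @return list with `observed_p`, `empirical_p`, `fdr`, `null_p`
#'   (B x pathways matrix) and `significant` (empirical FDR < 0.05).
#' @export
resampled_pathway_null <- function(modules, regulons, genesets, universe,
                                   tf_universe = NULL, B = 1000,
                                   alpha_tf = 0.1, seed = NULL) {
  check_that(B >= 50, "B must be >= 50 (unstable null otherwise)")
  if (inherits(modules, "module_set")) modules <- modules$modules
  sizes <- lengths(modules)
  if (is.null(tf_universe)) tf_universe <- union(universe, names(regulons))
  chain_p <- function(mods) {
    enr <- regulon_module_enrichment(mods, regulons, universe, alpha_tf)
    sig_tfs <- unique(enr$tf[enr$significant])
    if (length(sig_tfs) == 0L) {
      return(stats::setNames(rep(1, length(genesets)), names(genesets)))
    }
    vapply(genesets, function(gs) {
      fisher_overlap(sig_tfs, intersect(gs, tf_universe), tf_universe)$p
    }, numeric(1))
  }
  observed_p <- chain_p(modules)
  null_p <- matrix(NA_real_, nrow = B, ncol = length(genesets),
                   dimnames = list(NULL, names(genesets)))
  with_seed(seed, {
    for (b in seq_len(B)) {
      rand_mods <- list()
      pool <- universe
      for (i in seq_along(sizes)) {
        take <- sample(pool, min(sizes[i], length(pool)))
        rand_mods[[i]] <- take
        pool <- setdiff(pool, take)
      }
      names(rand_mods) <- names(sizes)
      null_p[b, ] <- chain_p(rand_mods)
    }
  })
  emp <- vapply(seq_along(genesets), function(j) {
    (1 + sum(null_p[, j] <= observed_p[j])) / (B + 1)
  }, numeric(1))
  names(emp) <- names(genesets)
  fdr <- stats::p.adjust(emp, "BH")
  list(observed_p = observed_p, empirical_p = emp, fdr = fdr,
       null_p = null_p, significant = fdr < 0.05)
}

# Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1).
gsea_es <- function(stat_sorted, in_set) {
  nr <- sum(abs(stat_sorted[in_set]))
  n <- length(stat_sorted)
  nh <- sum(in_set)
  if (nr == 0 || nh == n) return(0)
  steps <- ifelse(in_set, abs(stat_sorted) / nr, -1 / (n - nh))
  dev <- cumsum(steps)
  dev[which.max(abs(dev))]
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1) with a
#' gene-permutation null: `n_perm` random member sets of matched size are
#' drawn from the ranked universe. `NES = ES / mean(|null ES| of the same
#' sign)`; the p-value counts null scores at least as extreme in absolute
#' value, with the +1 correction; FDR is Benjamini-Hochberg across the
#' query sets.
#'
#' @param stats named numeric vector, gene-level statistics (finite).
#' @param genesets named list of gene sets (each with >= 2 members in the
#'   universe).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return data.frame `term`, `size`, `es`, `nes`, `p`, `fdr`.
#' @export
preranked_gsea <- function(stats, genesets, n_perm = 1000, seed = NULL) {
  check_that(all(is.finite(stats)), "gene statistics must be finite")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  gn <- names(s)
  n <- length(s)
  res <- with_seed(seed, {
    lapply(names(genesets), function(nm) {
      memb <- intersect(genesets[[nm]], gn)
      if (length(memb) < 2L) stop(sprintf("gene set '%s' has < 2 genes in the ranking", nm),
                                  call. = FALSE)
      in_set <- gn %in% memb
      es <- gsea_es(s, in_set)
      nh <- length(memb)
      null_es <- vapply(seq_len(n_perm), function(b) {
        idx <- logical(n)
        idx[sample.int(n, nh)] <- TRUE
        gsea_es(s, idx)
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same) > 0 && mean(abs(same)) > 0) {
        es / mean(abs(same))
      } else es
      p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
      data.frame(term = nm, size = nh, es = es, nes = nes, p = p,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out
}
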