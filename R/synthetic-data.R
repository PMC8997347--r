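# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with planted ground truth: latent-factor coexpression
# modules whose eigengenes correlate with shape features at configured
# strengths, negative-binomial counts with planted fold changes, a
# scale-free-ish signed prior network with citation counts, regulons and
# pathways with planted enrichment, a toy ontology, and a drug screen whose
# morphological effects scale with network influence.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions used throughout the test-suite:
#' three planted modules of 40 genes among 120 background genes, 100
#' samples, within-module correlation 0.8, module eigengenes correlated with
#' the first three shape features at 0.8, -0.8 and 0.7, a 300-node signed
#' prior network grown by preferential attachment, 20 regulons of 15 targets
#' and negative-binomial counts with mean 100 and dispersion 0.05.
#'
#' @param n_background_genes number of unassigned noise genes.
#' @param module_sizes integer vector of planted module sizes.
#' @param n_samples number of samples (cell lines).
#' @param shape_feature_count number of morphology features (default 10).
#' @param eigengene_shape_corr target Pearson correlation between each
#'   module's latent factor and its paired shape feature; one entry per
#'   module, in `[-1, 1]`.
#' @param within_module_corr target pairwise correlation of genes within a
#'   module, in `(0, 1]`.
#' @param low_expressed_frac fraction of background genes generated below
#'   the FPKM filter threshold.
#' @param nb_mean,nb_dispersion negative-binomial mean and dispersion for
#'   count generation.
#' @param planted_lfc log2 fold change planted in differential genes.
#' @param de_frac fraction of genes planted as differential.
#' @param network_nodes node count of the prior network.
#' @param network_edge_prob if non-`NULL`, use an Erdos-Renyi model with
#'   this edge probability instead of preferential attachment.
#' @param attachment_m edges added per node under preferential attachment.
#' @param n_regulons,regulon_size regulon count and size.
#' @param regulon_module_frac fraction of regulons planted inside modules
#'   (positive controls for overlap enrichment).
#' @param unknown_sign_frac fraction of regulon targets with unknown sign.
#' @param n_pathways,pathway_size pathway gene-set count and size.
#' @param ontology_depth,ontology_branching levels (including the root) and
#'   children per term of the generated ontology tree.
#' @param n_drugs number of drugs in the synthetic screen.
#' @param drug_effect_slope mean morphological effect per unit of scaled
#'   network influence; 0 disables the planted association.
#' @param drug_noise_sd per-cell Gaussian noise on log10 fold changes.
#' @param cells_per_drug cells imaged per drug (and per control batch).
#' @param rng_seed master seed; all generators are deterministic given it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_background_genes = 120,
                         module_sizes = c(40, 40, 40),
                         n_samples = 100,
                         shape_feature_count = 10,
                         eigengene_shape_corr = c(0.8, -0.8, 0.7),
                         within_module_corr = 0.8,
                         low_expressed_frac = 0.1,
                         nb_mean = 100,
                         nb_dispersion = 0.05,
                         planted_lfc = 1,
                         de_frac = 0.1,
                         network_nodes = 300,
                         network_edge_prob = NULL,
                         attachment_m = 2,
                         n_regulons = 20,
                         regulon_size = 15,
                         regulon_module_frac = 0.5,
                         unknown_sign_frac = 0.2,
                         n_pathways = 10,
                         pathway_size = 25,
                         ontology_depth = 4,
                         ontology_branching = 3,
                         n_drugs = 40,
                         drug_effect_slope = 1,
                         drug_noise_sd = 0.2,
                         cells_per_drug = 15,
                         rng_seed = 20220401) {
  cfg <- as.list(environment())
  check_that(all(c(n_background_genes, module_sizes, n_samples,
                   shape_feature_count, network_nodes, n_regulons,
                   regulon_size, ontology_depth, ontology_branching,
                   n_drugs, cells_per_drug) >= 1),
             "all counts must be >= 1")
  check_that(all(abs(eigengene_shape_corr) <= 1),
             "eigengene_shape_corr entries must lie in [-1, 1]")
  check_that(within_module_corr > 0 && within_module_corr <= 1,
             "within_module_corr must be in (0, 1]")
  check_that(nb_dispersion > 0, "nb_dispersion must be positive")
  check_that(length(eigengene_shape_corr) <= length(module_sizes),
             "more shape-correlation targets than modules")
  check_that(shape_feature_count >= length(eigengene_shape_corr),
             "need at least one shape feature per correlation target")
  class(cfg) <- "synth_config"
  cfg
}

module_gene_names <- function(config) {
  k <- length(config$module_sizes)
  lapply(seq_len(k), function(m) {
    sprintf("M%d_G%03d", m, seq_len(config$module_sizes[m]))
  })
}

background_gene_names <- function(config) {
  sprintf("BG_G%03d", seq_len(config$n_background_genes))
}

#' Synthetic gene universe
#'
#' All gene names produced by [gen_expression()]: planted module genes
#' followed by background genes.
#' @param config a [synth_config()].
#' @return character vector.
#' @export
gene_universe <- function(config) {
  c(unlist(module_gene_names(config)), background_gene_names(config))
}

tf_names <- function(config) sprintf("TF%02d", seq_len(config$n_regulons))

#' Generate an FPKM-like expression matrix with planted modules
#'
#' Each planted module is driven by one latent factor: on the log2 scale a
#' member gene is `sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving
#' within-module pairwise correlation `rho`. Shape features are linear
#' combinations of the latent factors calibrated so the realized
#' factor-feature correlation matches the configured target; remaining
#' features are independent noise. Background genes are independent, with a
#' configured fraction generated below the FPKM filter threshold.
#'
#' @param config a [synth_config()].
#' @return list with `expression` (FPKM-scale matrix, genes x samples),
#'   `shape` (data.frame, one row per sample, `shape_feature_count` feature
#'   columns), `coding_genes` (character; here the full universe) and
#'   `truth` (module assignment and the latent factors).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  check_that(config$n_samples >= 4, "need at least 4 samples")
  check_that(all(config$module_sizes >= 2), "module sizes must be >= 2")
  with_seed(derive_seed(config$rng_seed, 1L), {
    n <- config$n_samples
    k <- length(config$module_sizes)
    rho <- config$within_module_corr
    factors <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
    mod_names <- module_gene_names(config)

    gene_block <- function(m) {
      sz <- config$module_sizes[m]
      eps <- matrix(stats::rnorm(n * sz), nrow = n, ncol = sz)
      z <- sqrt(rho) * factors[, m] + sqrt(1 - rho) * eps
      t(z)                                   # genes x samples, log2 scale
    }
    planted <- do.call(rbind, lapply(seq_len(k), gene_block))
    rownames(planted) <- unlist(mod_names)

    nb <- config$n_background_genes
    n_low <- floor(nb * config$low_expressed_frac)
    bg <- matrix(stats::rnorm(n * nb), nrow = nb, ncol = n)
    rownames(bg) <- background_gene_names(config)
    log2_mean <- rep(5, nb)
    if (n_low > 0) log2_mean[seq_len(n_low)] <- -3    # below FPKM = 1
    logmat <- rbind(planted + 5, bg + log2_mean)

    # shape features: feature j tracks module j's factor at the target corr
    targets <- config$eigengene_shape_corr
    check_that(all(abs(targets) <= 1), "infeasible correlation target")
    p <- config$shape_feature_count
    shape <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    for (j in seq_along(targets)) {
      cj <- targets[j]
      shape[, j] <- cj * factors[, j] + sqrt(1 - cj^2) * shape[, j]
    }
    colnames(shape) <- sprintf("feat%02d", seq_len(p))
    shape_df <- data.frame(sample = sprintf("S%03d", seq_len(n)), shape,
                           stringsAsFactors = FALSE)

    fpkm <- 2^logmat
    colnames(fpkm) <- shape_df$sample

    assignment <- c(rep(sprintf("M%d", seq_len(k)), config$module_sizes),
                    rep("unassigned", nb))
    names(assignment) <- rownames(fpkm)
    list(expression = fpkm,
         shape = shape_df,
         coding_genes = rownames(fpkm),
         truth = list(module_assignment = assignment,
                      factors = factors,
                      module_genes = stats::setNames(mod_names,
                                                     sprintf("M%d", seq_len(k))),
                      shape_feature_module = seq_along(targets),
                      target_corr = targets))
  })
}

#' Generate negative-binomial counts with planted fold changes
#'
#' Counts are drawn `NB(mean, dispersion)` with per-sample library-size
#' factors in `[0.7, 1.3]`. A `de_frac` fraction of genes is planted as
#' differential: their mean in the group of interest (the first group label,
#' alphabetically) is multiplied by `2^planted_lfc`, with random sign.
#'
#' @param config a [synth_config()].
#' @param groups named character vector, sample -> group label.
#' @return list with `counts` (integer matrix), `size_factors_true` and
#'   `truth` (`de_genes` named sign vector, zero for null genes).
#' @export
gen_counts <- function(config, groups) {
  stopifnot(inherits(config, "synth_config"))
  tab <- table(groups)
  check_that(length(tab) >= 2, "need at least 2 groups")
  check_that(all(tab >= 2), "each group needs >= 2 samples")
  with_seed(derive_seed(config$rng_seed, 2L), {
    genes <- gene_universe(config)
    g <- length(genes)
    n <- length(groups)
    focal <- sort(unique(groups))[1]
    n_de <- floor(g * config$de_frac)
    de_idx <- sample.int(g, n_de)
    de_sign <- integer(g)
    de_sign[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    lib <- stats::runif(n, 0.7, 1.3)
    mu <- matrix(config$nb_mean, nrow = g, ncol = n)
    fc <- 2^(config$planted_lfc * de_sign)
    mu[, groups == focal] <- mu[, groups == focal] * fc
    mu <- sweep(mu, 2, lib, `*`)
    counts <- matrix(stats::rnbinom(g * n, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = g, ncol = n)
    rownames(counts) <- genes
    colnames(counts) <- names(groups)
    list(counts = counts,
         size_factors_true = lib,
         truth = list(de_genes = stats::setNames(de_sign, genes),
                      focal_group = focal))
  })
}

#' Generate a signed, directed prior-knowledge network
#'
#' Grown by out-degree preferential attachment (each new node receives
#' `attachment_m` incoming edges from existing nodes chosen proportionally
#' to out-degree + 1), which yields a heavy-tailed out-degree distribution;
#' or by an Erdos-Renyi model when `network_edge_prob` is set. Node names
#' are transcription factors plus a sample of the expression gene universe,
#' so network nodes overlap gene names by construction. Each edge carries a
#' sign (+1 with probability 0.7) and a citation count drawn from a
#' geometric distribution truncated at 25.
#'
#' @param config a [synth_config()].
#' @return a `prior_network`: list with `edges` (data.frame `source`,
#'   `target`, `sign`, `n_sources`) and `nodes` (character).
#' @export
gen_prior_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  check_that(config$network_nodes >= 2, "network needs >= 2 nodes")
  with_seed(derive_seed(config$rng_seed, 3L), {
    tfs <- tf_names(config)
    n_nodes <- config$network_nodes
    check_that(n_nodes > length(tfs), "network_nodes must exceed n_regulons")
    genes <- gene_universe(config)
    n_gene_nodes <- n_nodes - length(tfs)
    gene_nodes <- sample(genes, min(n_gene_nodes, length(genes)))
    n_pad <- n_gene_nodes - length(gene_nodes)
    # signaling proteins outside the measured gene universe, as a real
    # prior-knowledge interactome would contain
    pad <- if (n_pad > 0) sprintf("SIG_%03d", seq_len(n_pad)) else character(0)
    nodes <- sample(c(tfs, gene_nodes, pad))   # random growth order

    if (!is.null(config$network_edge_prob)) {
      p <- config$network_edge_prob
      if (p <= 0) {
        edges <- data.frame(source = character(0), target = character(0),
                            sign = integer(0), n_sources = integer(0))
      } else {
        pairs <- which(matrix(stats::runif(n_nodes^2), n_nodes) < p &
                         !diag(n_nodes), arr.ind = TRUE)
        edges <- data.frame(source = nodes[pairs[, 1]],
                            target = nodes[pairs[, 2]],
                            stringsAsFactors = FALSE)
      }
    } else {
      m <- config$attachment_m
      src <- integer(0); dst <- integer(0)
      outdeg <- rep(0L, n_nodes)
      for (v in 2:n_nodes) {
        n_new <- min(m, v - 1L)
        w <- outdeg[seq_len(v - 1L)] + 1
        from <- sample.int(v - 1L, n_new, prob = w)
        src <- c(src, from); dst <- c(dst, rep(v, n_new))
        outdeg[from] <- outdeg[from] + 1L
      }
      edges <- data.frame(source = nodes[src], target = nodes[dst],
                          stringsAsFactors = FALSE)
    }
    ne <- nrow(edges)
    edges$sign <- ifelse(stats::runif(ne) < 0.7, 1L, -1L)
    edges$n_sources <- pmin(stats::rgeom(ne, prob = 0.35) + 1L, 25L)
    prior_network(edges, nodes = nodes)
  })
}

#' Construct a prior network object
#'
#' @param edges data.frame with columns `source`, `target`, `sign`,
#'   `n_sources` (directed edges; self-loops are rejected).
#' @param nodes optional node universe (defaults to nodes seen in edges).
#' @return object of class `prior_network`.
#' @export
prior_network <- function(edges, nodes = NULL) {
  required <- c("source", "target", "sign", "n_sources")
  check_that(all(required %in% colnames(edges)),
             "edges need columns source, target, sign, n_sources")
  check_that(!any(edges$source == edges$target), "self-loops not allowed")
  check_that(all(edges$n_sources >= 1), "n_sources must be >= 1")
  check_that(all(edges$sign %in% c(-1L, 1L)), "sign must be +1 or -1")
  if (is.null(nodes)) nodes <- union(edges$source, edges$target)
  structure(list(edges = edges, nodes = nodes), class = "prior_network")
}

#' @export
print.prior_network <- function(x, ...) {
  cat(sprintf("Prior network: %d nodes, %d signed directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Generate TF regulons with planted module overlap
#'
#' A `regulon_module_frac` fraction of regulons draws its targets from
#' inside one planted module (cycling over modules) -- positive controls for
#' regulon-module overlap enrichment; the rest draw targets uniformly from
#' the gene universe. Targets are split into activated / repressed, with an
#' `unknown_sign_frac` fraction left unsigned. Planted TFs receive a nonzero
#' true activity of alternating sign.
#'
#' @param config a [synth_config()].
#' @param truth the `truth` element from [gen_expression()].
#' @return list with `regulons` (per TF: `activated`, `repressed`,
#'   `unknown`) and `true_tf_activity` (named numeric).
#' @export
gen_regulons <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_universe(config)
  check_that(config$regulon_size <= length(genes),
             "regulon_size exceeds gene universe")
  with_seed(derive_seed(config$rng_seed, 4L), {
    tfs <- tf_names(config)
    n_pos <- floor(length(tfs) * config$regulon_module_frac)
    mod_genes <- truth$module_genes
    k <- length(mod_genes)
    activity <- stats::setNames(numeric(length(tfs)), tfs)
    regulons <- stats::setNames(vector("list", length(tfs)), tfs)
    for (i in seq_along(tfs)) {
      if (i <= n_pos && k > 0) {
        pool <- mod_genes[[((i - 1L) %% k) + 1L]]
        targets <- sample(pool, min(config$regulon_size, length(pool)))
        activity[i] <- 2 * (-1)^(i + 1)
      } else {
        targets <- sample(genes, config$regulon_size)
      }
      n_unknown <- floor(length(targets) * config$unknown_sign_frac)
      unknown <- if (n_unknown > 0) targets[seq_len(n_unknown)] else character(0)
      signed <- setdiff(targets, unknown)
      n_act <- ceiling(length(signed) * 0.7)
      regulons[[i]] <- list(activated = signed[seq_len(n_act)],
                            repressed = signed[-seq_len(n_act)],
                            unknown = unknown)
    }
    list(regulons = regulons, true_tf_activity = activity)
  })
}

#' Generate pathway gene sets
#'
#' Pathways partition part of the combined universe (genes plus TFs) into
#' named sets; the first pathway is planted TF-heavy so that TF-pathway
#' enrichment has a positive control.
#'
#' @param config a [synth_config()].
#' @return named list of character vectors.
#' @export
gen_genesets <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(derive_seed(config$rng_seed, 5L), {
    universe <- c(gene_universe(config), tf_names(config))
    sets <- stats::setNames(vector("list", config$n_pathways),
                            sprintf("PW%02d", seq_len(config$n_pathways)))
    tfs <- tf_names(config)
    n_tf_in <- min(length(tfs), ceiling(config$pathway_size / 2))
    sets[[1]] <- c(sample(tfs, n_tf_in),
                   sample(setdiff(universe, tfs),
                          config$pathway_size - n_tf_in))
    for (i in seq_len(config$n_pathways)[-1]) {
      sets[[i]] <- sample(universe, config$pathway_size)
    }
    sets
  })
}

#' Generate a rooted ontology with gene annotations
#'
#' A complete tree with `ontology_branching` children per term and
#' `ontology_depth` levels (level 1 is the root alone), plus a few random
#' cross-links giving some terms a second parent. Every gene and TF is
#' annotated to one to three terms, biased toward deep terms.
#'
#' @param config a [synth_config()].
#' @return an `ontology` object (see [build_ontology()]).
#' @export
gen_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  check_that(config$ontology_depth >= 1 && config$ontology_branching >= 1,
             "ontology depth and branching must be >= 1")
  with_seed(derive_seed(config$rng_seed, 6L), {
    b <- config$ontology_branching
    d <- config$ontology_depth
    terms <- "T1"
    parents <- data.frame(child = "T1", parent = NA_character_,
                          stringsAsFactors = FALSE)
    level <- list("T1")
    idx <- 1L
    if (d > 1) for (lev in 2:d) {
      prev <- level[[lev - 1L]]
      kids <- character(0)
      for (p in prev) {
        for (j in seq_len(b)) {
          idx <- idx + 1L
          id <- sprintf("T%d", idx)
          kids <- c(kids, id)
          parents <- rbind(parents, data.frame(child = id, parent = p,
                                               stringsAsFactors = FALSE))
        }
      }
      level[[lev]] <- kids
      terms <- c(terms, kids)
    }
    # occasional cross-links: a term gains a second parent one level up
    if (d > 2) {
      deep <- level[[d]]
      extra <- sample(deep, max(1L, length(deep) %/% 10))
      for (t in extra) {
        cand <- setdiff(level[[d - 1L]], parents$parent[parents$child == t])
        if (length(cand) > 0) {
          parents <- rbind(parents,
                           data.frame(child = t, parent = sample(cand, 1),
                                      stringsAsFactors = FALSE))
        }
      }
    }
    genes <- gene_universe(config)
    n_pad <- max(0L, config$network_nodes - config$n_regulons - length(genes))
    pad <- if (n_pad > 0) sprintf("SIG_%03d", seq_len(n_pad)) else character(0)
    universe <- c(genes, tf_names(config), pad)
    depth_of <- rep(seq_len(d), vapply(level, length, integer(1)))
    ann <- do.call(rbind, lapply(universe, function(g) {
      n_t <- min(sample(1:3, 1), length(terms))
      picked <- sample(terms, n_t, prob = depth_of^2)
      data.frame(gene = g, term = picked, stringsAsFactors = FALSE)
    }))
    build_ontology(parents, ann)
  })
}

#' Expand per-line shape medians into per-cell measurements
#'
#' Draws `cells_per_line` cells per sample, Gaussian around the line
#' median with standard deviation `noise_sd`, for ANOVA-style per-cell
#' analyses.
#'
#' @param shape data.frame with `sample` column and feature columns (line
#'   medians).
#' @param cells_per_line cells per sample (default 30).
#' @param noise_sd cell-level noise standard deviation (default 0.5).
#' @param seed RNG seed.
#' @return data.frame with `cell_id`, `sample` and feature columns.
#' @export
gen_cell_shapes <- function(shape, cells_per_line = 30, noise_sd = 0.5,
                            seed = NULL) {
  feat_cols <- setdiff(colnames(shape), c("sample", "batch"))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(shape)), function(i) {
      m <- matrix(stats::rnorm(cells_per_line * length(feat_cols),
                               mean = as.numeric(shape[i, feat_cols]),
                               sd = noise_sd),
                  nrow = cells_per_line, byrow = TRUE)
      colnames(m) <- feat_cols
      data.frame(cell_id = sprintf("%s_c%03d", shape$sample[i],
                                   seq_len(cells_per_line)),
                 sample = shape$sample[i], m, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic kinase-inhibitor screen
#'
#' Each drug receives one to five class-1 targets, sampled from inside the
#' assembled network or from an external kinase pool. The drug's true
#' influence is its network influence score; per-cell morphology log10 fold
#' changes for the modeled features are drawn around
#' `drug_effect_slope * influence / max(influence)` (random sign per drug),
#' unmodeled features around zero, and control cells around zero for every
#' feature.
#'
#' @param network an `assembled_network` (see [add_supernodes()]).
#' @param config a [synth_config()].
#' @param n_modeled_features how many features respond to network influence
#'   (default 5 of the configured `shape_feature_count`).
#' @return list with `targets` (drug-target table), `morphology` (per-cell
#'   response table), and `truth` (`influence` per drug, `in_network` flag,
#'   `modeled_features`).
#' @export
gen_drug_screen <- function(network, config, n_modeled_features = 5) {
  stopifnot(inherits(network, "assembled_network"),
            inherits(config, "synth_config"))
  protein_nodes <- network$nodes$node[network$nodes$type == "protein"]
  check_that(length(protein_nodes) > 0, "network has no protein nodes")
  with_seed(derive_seed(config$rng_seed, 7L), {
    out_pool <- sprintf("KIN_OUT_%02d", seq_len(30))
    drugs <- sprintf("DRUG%03d", seq_len(config$n_drugs))
    target_rows <- lapply(seq_along(drugs), function(i) {
      k <- sample(1:5, 1)
      inside <- i %% 2 == 0     # alternate in-network / out-of-network drugs
      pool <- if (inside) protein_nodes else out_pool
      data.frame(drug = drugs[i], target = sample(pool, min(k, length(pool))),
                 binding_class = 1L, stringsAsFactors = FALSE)
    })
    targets <- do.call(rbind, target_rows)

    profiles <- filter_drug_targets(targets)
    network <- with_pagerank(network)
    influence <- vapply(profiles, function(p) influence_score(p, network),
                        numeric(1))
    influence <- stats::setNames(influence[match(drugs, names(influence))], drugs)
    influence[is.na(influence)] <- 0
    s_max <- max(influence)
    scaled <- if (s_max > 0) influence / s_max else influence
    effect <- config$drug_effect_slope * scaled *
      sample(c(-1, 1), length(drugs), replace = TRUE)

    p <- config$shape_feature_count
    modeled <- seq_len(min(n_modeled_features, p))
    feat_names <- sprintf("feat%02d", seq_len(p))
    ncell <- config$cells_per_drug
    baseline <- 100          # raw feature scale; cancels in the LFC step
    one_drug <- function(d, mu) {
      m <- matrix(stats::rnorm(ncell * p, sd = config$drug_noise_sd),
                  nrow = ncell)
      m[, modeled] <- m[, modeled] + mu
      m <- baseline * 10^m   # raw values; log10 vs control mean ~ mu + noise
      colnames(m) <- feat_names
      data.frame(cell_id = sprintf("%s_C%02d", d, seq_len(ncell)), drug = d,
                 batch = "B1", m, stringsAsFactors = FALSE)
    }
    morph <- do.call(rbind, c(lapply(seq_along(drugs), function(i) {
      one_drug(drugs[i], effect[i])
    }), list(one_drug("control", 0))))

    list(targets = targets, morphology = morph,
         truth = list(influence = influence,
                      effect = stats::setNames(effect, drugs),
                      in_network = vapply(drugs, function(d) {
                        any(targets$target[targets$drug == d] %in% protein_nodes)
                      }, logical(1)),
                      modeled_features = feat_names[modeled]))
  })
}
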