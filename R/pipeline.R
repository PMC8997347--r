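# End-to-end pipeline driver over the synthetic inputs: coexpression ->
# enrichment -> clustering/DE/activity -> network assembly -> propagation
# -> drug validation -> max flow. Each stage writes plain-text outputs and
# an .rds checkpoint so a rerun can resume; a manifest records parameters
# and stage status. Everything is deterministic given the configured seed.

#' Pipeline parameters
#'
#' Numeric parameters of every stage with their standard defaults:
#' soft-threshold 9, minimum module size 30, 1000 correlation
#' permutations, k = 3 shape clusters, prizes of 100 with b = 1, w = 40,
#' mu = 0.005, 5% cost noise over 30 PCSF iterations, restart probability
#' 0.95 with 10000 seed randomizations, and the 99th flow percentile.
#'
#' @param beta,min_module_size,cut_height,merge_corr coexpression stage;
#'   see [coexpression_params()].
#' @param B_perm module-shape correlation permutations.
#' @param k,restarts shape clustering.
#' @param B_rank rank permutations for the pathway combined score.
#' @param B_null resampled module sets for the pathway-bias null.
#' @param alpha_tf TF-module overlap threshold.
#' @param alpha_pathway pathway enrichment threshold.
#' @param alpha_de_tf differential TF-activity threshold.
#' @param prize_value,b,w,mu,noise_frac,iterations PCSF stage; see
#'   [pcsf_params()].
#' @param r restart probability for propagation.
#' @param n_rand seed randomizations for propagation significance.
#' @param percentile flow percentile for subnetwork extraction.
#' @param jackknife run the leave-one-out module stability check.
#' @param seed master seed; `NULL` defers to the synthetic config's seed.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(beta = 9, min_module_size = 30,
                            cut_height = 0.9, merge_corr = 0.85,
                            B_perm = 1000, k = 3, restarts = 50,
                            B_rank = 200, B_null = 1000,
                            alpha_tf = 0.1, alpha_pathway = 0.05,
                            alpha_de_tf = 0.1,
                            prize_value = 100, b = 1, w = 40, mu = 0.005,
                            noise_frac = 0.05, iterations = 30,
                            r = 0.95, n_rand = 10000, percentile = 99,
                            jackknife = TRUE, seed = NULL) {
  structure(as.list(environment()), class = "pipeline_params")
}

stage_path <- function(out_dir, stage) file.path(out_dir, stage)

run_stage <- function(out_dir, stage, resume, fun) {
  dir <- stage_path(out_dir, stage)
  rds <- file.path(dir, ".checkpoint.rds")
  if (resume && file.exists(rds)) {
    msg(sprintf("stage %s: resumed from checkpoint", stage))
    return(readRDS(rds))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch(fun(dir), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  saveRDS(res, rds)
  res
}

#' Run the full phenotype-network pipeline on synthetic inputs
#'
#' Generates every input from the synthetic config, then executes the
#' seven analysis stages in order, writing per-stage TSV outputs under
#' `out_dir` plus a `manifest.tsv` with stage status and a parameter echo.
#' With `resume = TRUE`, stages whose checkpoint exists are skipped.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param params a [pipeline_params()].
#' @param resume skip stages with existing checkpoints (default TRUE).
#' @return invisible list with all stage results and the manifest path.
#' @export
run_pipeline <- function(config = synth_config(), out_dir,
                         params = pipeline_params(), resume = TRUE) {
  stopifnot(inherits(config, "synth_config"),
            inherits(params, "pipeline_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed0 <- if (is.null(params$seed)) config$rng_seed else params$seed
  config$rng_seed <- seed0
  completed <- character(0)

  inputs <- run_stage(out_dir, "00_inputs", resume, function(dir) {
    ge <- gen_expression(config)
    prior <- gen_prior_network(config)
    reg <- gen_regulons(config, ge$truth)
    gs <- gen_genesets(config)
    onto <- gen_ontology(config)
    write_expression_tsv(ge$expression, file.path(dir, "expression.tsv"))
    write_shape_tsv(ge$shape, file.path(dir, "shape.tsv"))
    write_edge_list(prior$edges, file.path(dir, "prior_edges.tsv"))
    regsets <- unlist(lapply(names(reg$regulons), function(tf) {
      r <- reg$regulons[[tf]]
      stats::setNames(list(r$activated, r$repressed, r$unknown),
                      paste0(tf, c("+", "-", "?")))
    }), recursive = FALSE)
    write_gmt(regsets[lengths(regsets) > 0], file.path(dir, "regulons.gmt"))
    write_gmt(gs, file.path(dir, "genesets.gmt"))
    write_ontology_tsv(onto, file.path(dir, "ontology_terms.tsv"),
                       file.path(dir, "ontology_annotations.tsv"))
    list(ge = ge, prior = prior, reg = reg, gs = gs, onto = onto)
  })
  ge <- inputs$ge; prior <- inputs$prior; reg <- inputs$reg
  gs <- inputs$gs; onto <- inputs$onto
  universe_all <- c(gene_universe(config), names(reg$regulons))

  cx <- run_stage(out_dir, "01_coexpress", resume, function(dir) {
    cp <- coexpression_params(params$beta, params$min_module_size,
                              params$cut_height, params$merge_corr)
    kept <- filter_genes(ge$expression, ge$coding_genes, 1)
    modules <- coexpression_modules(kept, params = cp)
    corr <- correlate_modules_shape(modules$eigengenes, ge$shape,
                                    B = params$B_perm,
                                    seed = derive_seed(seed0, 11L))
    stability <- if (isTRUE(params$jackknife)) {
      jackknife_modules(kept, cp, reference = modules)
    } else NULL
    write_gmt(modules$modules, file.path(dir, "modules.gmt"))
    write_table_tsv(data.frame(sample = rownames(ge$shape),
                               modules$eigengenes, check.names = FALSE),
                    file.path(dir, "eigengenes.tsv"))
    write_table_tsv(as.data.frame(corr$pcc), file.path(dir, "module_shape_pcc.tsv"))
    write_table_tsv(as.data.frame(corr$p_perm), file.path(dir, "module_shape_p_perm.tsv"))
    if (!is.null(stability)) {
      write_table_tsv(stability, file.path(dir, "jackknife.tsv"))
    }
    list(filtered = kept, modules = modules, corr = corr,
         stability = stability)
  })
  completed <- c(completed, "coexpress")

  en <- run_stage(out_dir, "02_enrich", resume, function(dir) {
    gene_univ <- rownames(cx$filtered)
    rme <- regulon_module_enrichment(cx$modules, reg$regulons,
                                     universe = gene_univ,
                                     alpha = params$alpha_tf)
    sig_tfs <- unique(rme$tf[rme$significant])
    pw <- if (length(sig_tfs) > 0) {
      tf_pathway_enrichment(sig_tfs, gs, universe = universe_all,
                            B_rank = params$B_rank,
                            seed = derive_seed(seed0, 12L))
    } else NULL
    null_res <- resampled_pathway_null(cx$modules, reg$regulons, gs,
                                       universe = gene_univ,
                                       tf_universe = universe_all,
                                       B = params$B_null,
                                       alpha_tf = params$alpha_tf,
                                       seed = derive_seed(seed0, 13L))
    write_table_tsv(rme, file.path(dir, "regulon_module_enrichment.tsv"))
    if (!is.null(pw)) write_table_tsv(pw, file.path(dir, "tf_pathway_enrichment.tsv"))
    write_table_tsv(data.frame(term = names(null_res$empirical_p),
                               observed_p = null_res$observed_p,
                               empirical_p = null_res$empirical_p,
                               fdr = null_res$fdr),
                    file.path(dir, "pathway_bias_null.tsv"))
    list(regulon_module = rme, tf_module_hits = sig_tfs, pathways = pw,
         pathway_null = null_res)
  })
  completed <- c(completed, "enrich")

  act <- run_stage(out_dir, "03_activity", resume, function(dir) {
    clusters <- cluster_shapes(ge$shape, k = params$k,
                               restarts = params$restarts,
                               seed = derive_seed(seed0, 14L))
    groups <- stats::setNames(sprintf("C%d", clusters), names(clusters))
    cnt <- gen_counts(config, groups)
    filtered <- filter_counts(cnt$counts, 0.5,
                              min_samples = min(8, floor(ncol(cnt$counts) / 2)))
    focal <- names(groups)[groups == sort(unique(groups))[1]]
    de <- nb_differential_expression(filtered, focal)
    stats_vec <- stats::setNames(de$wald_z, de$gene)
    tf_act <- regulon_activity(stats_vec, reg$regulons)
    mod_act <- regulon_activity(stats_vec, cx$modules$modules)
    de_tfs <- tf_act$name[tf_act$p < params$alpha_de_tf]

    # per-sample activities (gene-standardized log2 expression as the
    # per-sample statistic) for the activity-correlation analyses
    z <- t(scale(t(log2(cx$filtered + 1))))
    z[is.na(z)] <- 0
    per_sample <- lapply(colnames(z), function(s) {
      st <- stats::setNames(z[, s], rownames(z))
      ta <- regulon_activity(st, reg$regulons)
      ma <- regulon_activity(st, cx$modules$modules)
      list(sample = s, tf = ta, mod = ma)
    })
    tf_long <- do.call(rbind, lapply(per_sample, function(x) {
      data.frame(sample = x$sample, tf = x$tf$name, nes = x$tf$nes,
                 fdr = x$tf$fdr, stringsAsFactors = FALSE)
    }))
    mod1 <- names(cx$modules$modules)[1]
    mod_long <- do.call(rbind, lapply(per_sample, function(x) {
      i <- match(mod1, x$mod$name)
      data.frame(sample = x$sample, nes = x$mod$nes[i], fdr = x$mod$fdr[i],
                 stringsAsFactors = FALSE)
    }))
    kendall <- kendall_activity_correlation(mod_long, tf_long,
                                            sig_alpha = 0.5)
    ks <- ks_group_difference(stats::setNames(mod_long$nes, mod_long$sample),
                              groups[mod_long$sample], min_n = 2)
    cells <- gen_cell_shapes(ge$shape, seed = derive_seed(seed0, 15L))
    av <- anova_shape(cells, groups[cells$sample])

    write_table_tsv(data.frame(sample = names(groups), cluster = groups),
                    file.path(dir, "clusters.tsv"))
    write_table_tsv(de, file.path(dir, "differential_expression.tsv"))
    write_table_tsv(tf_act, file.path(dir, "tf_activity.tsv"))
    write_table_tsv(mod_act, file.path(dir, "module_activity.tsv"))
    write_table_tsv(kendall, file.path(dir, "kendall_tf_module.tsv"))
    write_table_tsv(ks, file.path(dir, "ks_module_activity.tsv"))
    write_table_tsv(av$anova, file.path(dir, "anova_shape.tsv"))
    list(clusters = groups, counts = cnt, de = de, tf_activity = tf_act,
         module_activity = mod_act, de_tfs = de_tfs, kendall = kendall,
         ks = ks, anova = av)
  })
  completed <- c(completed, "activity")

  asm <- run_stage(out_dir, "04_assemble", resume, function(dir) {
    costs <- edge_costs(prior)
    pw_hits <- if (!is.null(en$pathways)) {
      en$pathways$term[en$pathways$p < params$alpha_pathway]
    } else character(0)
    pathway_proteins <- intersect(unique(unlist(gs[pw_hits])), prior$nodes)
    pp <- pcsf_params(params$prize_value, params$b, params$w, params$mu,
                      params$noise_frac, params$iterations,
                      seed = derive_seed(seed0, 16L))
    prizes <- suppressWarnings(
      collect_prizes(en$tf_module_hits, act$de_tfs, pathway_proteins,
                     prior, pp))
    sol <- pcsf_union(prior, costs, prizes, pp)
    net <- add_supernodes(sol, cx$modules, reg$regulons, cx$corr,
                          prizes = prizes,
                          universe = rownames(cx$filtered),
                          alpha_tf = params$alpha_tf)
    ns <- network_stats(net, prizes)
    write_edge_list(net$edges, file.path(dir, "network_edges.tsv"))
    write_table_tsv(net$nodes, file.path(dir, "network_nodes.tsv"))
    write_table_tsv(ns$node_stats, file.path(dir, "betweenness.tsv"))
    writeLines(sprintf("prize_coverage\t%.6f", ns$prize_coverage),
               file.path(dir, "coverage.tsv"))
    list(prizes = prizes, solution = sol, network = net, stats = ns)
  })
  completed <- c(completed, "assemble")

  prop <- run_stage(out_dir, "05_propagate", resume, function(dir) {
    net <- reweight_edges(asm$network, onto)
    tfa <- act$tf_activity
    in_net <- tfa$name %in% net$nodes$node
    up <- tfa[in_net & tfa$nes > 0 & tfa$p < params$alpha_de_tf, ]
    dn <- tfa[in_net & tfa$nes < 0 & tfa$p < params$alpha_de_tf, ]
    if (nrow(up) == 0) up <- utils::head(tfa[in_net & tfa$nes > 0, ], 3)
    if (nrow(dn) == 0) dn <- utils::head(tfa[in_net & tfa$nes < 0, ], 3)
    run_set <- function(df, label) {
      if (nrow(df) == 0) return(NULL)
      seeds <- abs(df$nes) / sum(abs(df$nes))
      names(seeds) <- df$name
      seed_significance(net, seeds, n_rand = params$n_rand,
                        r = params$r, seed = derive_seed(seed0, 17L))
    }
    res_up <- run_set(up, "activated")
    res_dn <- run_set(dn, "deactivated")
    gem <- net$nodes$node[net$nodes$type == "gem_supernode"][1]
    sp <- if (!is.na(gem) && nrow(up) > 0) {
      suppressWarnings(shortest_path_subgraph(net, up$name, gem))
    } else NULL
    if (!is.null(res_up)) write_table_tsv(res_up, file.path(dir, "rwr_activated.tsv"))
    if (!is.null(res_dn)) write_table_tsv(res_dn, file.path(dir, "rwr_deactivated.tsv"))
    if (!is.null(sp) && nrow(sp$edges) > 0) {
      write_table_tsv(sp$edges, file.path(dir, "shortest_paths.tsv"))
    }
    list(network = net, activated = res_up, deactivated = res_dn,
         subgraph = sp)
  })
  completed <- c(completed, "propagate")

  drugs <- run_stage(out_dir, "06_drugs", resume, function(dir) {
    screen <- gen_drug_screen(prop$network, config)
    profiles <- filter_drug_targets(screen$targets)
    lfcs <- morphology_lfc(screen$morphology)
    netp <- with_pagerank(prop$network)
    scores <- vapply(profiles, function(p) influence_score(p, netp),
                     numeric(1))
    cmp <- compare_in_vs_out(lfcs, profiles, netp)
    corr <- correlate_influence(lfcs, scores)
    write_table_tsv(screen$targets, file.path(dir, "drug_targets.tsv"))
    write_table_tsv(data.frame(drug = names(scores), influence = scores),
                    file.path(dir, "influence_scores.tsv"))
    write_table_tsv(cmp, file.path(dir, "in_vs_out_tests.tsv"))
    write_table_tsv(corr, file.path(dir, "influence_correlation.tsv"))
    list(screen = screen, profiles = profiles, lfcs = lfcs,
         scores = scores, compare = cmp, correlation = corr)
  })
  completed <- c(completed, "validate_drugs")

  fl <- run_stage(out_dir, "07_flow", resume, function(dir) {
    net <- prop$network
    gems <- net$nodes$node[net$nodes$type == "gem_supernode"]
    if (length(gems) == 0) {
      msg("no supernode available; skipping flow analysis")
      return(NULL)
    }
    src <- gems[1]
    g <- as_igraph(net, directed = TRUE)
    reach <- setdiff(
      igraph::V(g)$name[as.integer(
        igraph::subcomponent(g, src, mode = "out"))], src)
    reach <- intersect(reach, net$nodes$node[net$nodes$type == "protein"])
    if (length(reach) == 0) {
      msg("supernode reaches no protein node; skipping flow analysis")
      return(NULL)
    }
    pr <- network_pagerank(net)
    # candidate sinks by decreasing centrality; keep the first with
    # positive attainable flow (min-max scaled capacities can zero out a
    # bottleneck edge for the top candidate)
    cand <- reach[order(-pr[reach])]
    res <- NULL; sink <- cand[1]
    for (s in utils::head(cand, 10)) {
      r <- max_flow(net, src, s)
      if (is.null(res) || r$value > res$value) { res <- r; sink <- s }
      if (res$value > 0) break
    }
    top <- if (res$value > 0) {
      top_flow_subnetwork(res, percentile = params$percentile)
    } else res$edges[0, ]
    write_table_tsv(res$edges, file.path(dir, "flow_edges.tsv"))
    write_table_tsv(top, file.path(dir, "top_flow_subnetwork.tsv"))
    writeLines(sprintf("source\t%s\nsink\t%s\nflow\t%.10g", src, sink,
                       res$value), file.path(dir, "flow_summary.tsv"))
    list(source = src, sink = sink, flow = res, top = top)
  })
  completed <- c(completed, "flow")

  manifest <- data.frame(stage = completed,
                         status = "completed",
                         stringsAsFactors = FALSE)
  write_table_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  echo <- c(sprintf("seed\t%d", seed0),
            sprintf("%s\t%s", names(unclass(params)),
                    vapply(unclass(params), function(v)
                      paste(format(v), collapse = ","), character(1))))
  writeLines(echo, file.path(out_dir, "parameters.tsv"))
  invisible(list(inputs = inputs, coexpress = cx, enrich = en,
                 activity = act, assemble = asm, propagate = prop,
                 drugs = drugs, flow = fl,
                 manifest = file.path(out_dir, "manifest.tsv")))
}
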