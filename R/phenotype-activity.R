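# Phenotype-level analyses: k-means clustering of shape-feature medians,
# a simplified negative-binomial Wald test for differential expression,
# rank-based regulon/module activity scores, and the downstream activity
# correlation and group-difference statistics.

#' Cluster samples by shape features
#'
#' k-means on z-scored features; the best of `restarts` random
#' initializations by within-cluster sum of squares is returned,
#' deterministically for a given seed.
#'
#' @param medians data.frame with a `sample` column and numeric feature
#'   columns (per-line medians), or a numeric matrix with rownames.
#' @param k number of clusters (default 3).
#' @param restarts random initializations (default 50).
#' @param seed RNG seed.
#' @return named integer vector of cluster labels with attribute
#'   `tot.withinss`.
#' @export
cluster_shapes <- function(medians, k = 3, restarts = 50, seed = NULL) {
  if (is.data.frame(medians)) {
    ids <- medians$sample
    m <- as.matrix(medians[, setdiff(colnames(medians), c("sample", "batch")),
                           drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(medians)
  }
  check_that(nrow(m) >= k, "k exceeds the number of samples")
  z <- scale(m)
  z[, apply(m, 2, stats::sd) == 0] <- 0
  fit <- with_seed(seed, stats::kmeans(z, centers = k, nstart = restarts,
                                       iter.max = 100))
  out <- stats::setNames(fit$cluster, rownames(m))
  attr(out, "tot.withinss") <- fit$tot.withinss
  out
}

#' Filter count matrix by CPM and coding status
#'
#' Keeps coding genes with counts-per-million above `cpm_min` in at least
#' `min_samples` samples (boundary inclusive on the sample count).
#'
#' @param counts integer matrix, genes x samples.
#' @param cpm_min CPM threshold (default 0.5).
#' @param min_samples minimum number of passing samples (default 8).
#' @param coding coding gene names (defaults to all genes).
#' @return filtered count matrix.
#' @export
filter_counts <- function(counts, cpm_min = 0.5, min_samples = 8,
                          coding = rownames(counts)) {
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib / 1e6, `/`)
  keep <- rownames(counts) %in% coding &
    rowSums(cpm > cpm_min) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  check_that(any(use), "no gene has all-positive counts")
  sf <- apply(counts, 2, function(cj) {
    exp(stats::median(log(cj[use]) - lg[use]))
  })
  check_that(all(sf > 0), "group with all-zero library")
  sf
}

#' Simplified negative-binomial Wald differential expression
#'
#' Median-of-ratios normalization; per-gene pooled method-of-moments
#' dispersion (floored at 1e-8); log2 fold change of normalized group means
#' with pseudo-count 0.5 (group of interest in the numerator); delta-method
#' standard error; two-sided Wald p against a t reference with residual
#' degrees of freedom (the plug-in dispersion is noisy at small n) and
#' Benjamini-Hochberg FDR.
#'
#' @param counts integer matrix, genes x samples.
#' @param group_of_interest column names (or logical/integer index) of the
#'   numerator group.
#' @param rest columns of the control group (defaults to the complement).
#' @return data.frame `gene`, `base_mean`, `log2fc`, `se`, `wald_z`, `p`,
#'   `fdr`.
#' @export
nb_differential_expression <- function(counts, group_of_interest,
                                       rest = NULL) {
  if (is.character(group_of_interest)) {
    g1 <- colnames(counts) %in% group_of_interest
  } else if (is.logical(group_of_interest)) {
    g1 <- group_of_interest
  } else {
    g1 <- seq_len(ncol(counts)) %in% group_of_interest
  }
  g2 <- if (is.null(rest)) !g1 else {
    if (is.character(rest)) colnames(counts) %in% rest else
      seq_len(ncol(counts)) %in% rest
  }
  check_that(sum(g1) >= 2 && sum(g2) >= 2, "each group needs >= 2 samples")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  # pooled method-of-moments NB dispersion: var = mu + alpha mu^2
  alpha1 <- (v1 - m1) / m1^2
  alpha2 <- (v2 - m2) / m2^2
  w <- c(n1 - 1, n2 - 1) / (n1 + n2 - 2)
  alpha <- pmax(w[1] * alpha1 + w[2] * alpha2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  pc <- 0.5
  log2fc <- log2((m1 + pc) / (m2 + pc))
  var_mean <- function(m, n) (m + alpha * m^2) / n
  se <- sqrt(var_mean(m1, n1) / ((m1 + pc)^2) +
               var_mean(m2, n2) / ((m2 + pc)^2)) / log(2)
  se <- pmax(se, 1e-8)
  z <- log2fc / se
  # t reference with residual df: the plug-in dispersion makes the Wald
  # statistic heavier-tailed than normal at small n
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)
  data.frame(gene = rownames(counts),
             base_mean = rowMeans(norm), log2fc = log2fc, se = se,
             wald_z = z, p = p, fdr = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-based regulon activity
#'
#' Gene statistics are converted to normal scores via rank quantiles,
#' `z_i = qnorm(rank_i / (n + 1))`; the activity of a regulon is
#' `NES = sum(mode_i * z_i) / sqrt(n_targets)` with mode +1 for activated
#' and unknown-sign targets and -1 for repressed targets. p-values come
#' from the standard normal; FDR is Benjamini-Hochberg across regulons.
#' Module activity uses the same score with all modes +1.
#'
#' @param stats named numeric vector of signed gene statistics (>= 50
#'   genes).
#' @param regulons named list per TF with `activated`, `repressed`,
#'   `unknown`; or (for module activity) a named list of plain gene
#'   vectors.
#' @param min_targets regulons with fewer covered targets are skipped
#'   (default 3).
#' @return data.frame `name`, `n_targets`, `nes`, `p`, `fdr`.
#' @export
regulon_activity <- function(stats, regulons, min_targets = 3) {
  check_that(length(stats) >= 50, "need statistics for >= 50 genes")
  z <- stats::qnorm(rank(stats, ties.method = "average") / (length(stats) + 1))
  names(z) <- names(stats)
  rows <- lapply(names(regulons), function(nm) {
    reg <- regulons[[nm]]
    if (is.list(reg)) {
      tg <- c(reg$activated, reg$unknown, reg$repressed)
      mode <- c(rep(1, length(reg$activated) + length(reg$unknown)),
                rep(-1, length(reg$repressed)))
    } else {
      tg <- reg
      mode <- rep(1, length(tg))
    }
    ok <- tg %in% names(z)
    if (sum(ok) < min_targets) {
      msg(sprintf("regulon %s covers < %d genes; skipped", nm, min_targets))
      return(NULL)
    }
    nes <- sum(mode[ok] * z[tg[ok]]) / sqrt(sum(ok))
    data.frame(name = nm, n_targets = sum(ok), nes = nes,
               p = 2 * stats::pnorm(-abs(nes)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(name = character(0), n_targets = integer(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0)))
  }
  out$fdr <- stats::p.adjust(out$p, "BH")
  out
}

#' Kendall correlation between module and TF activities
#'
#' Per TF, keeps the samples in which both the module and the TF activity
#' are significant (FDR below `sig_alpha`), then computes the tie-corrected
#' Kendall tau-b with its normal-approximation p-value; FDR across TFs.
#' TFs with fewer than `min_n` surviving samples are reported as `NA` with
#' a reason.
#'
#' @param module_act data.frame with columns `sample`, `nes`, `fdr` for one
#'   module across samples.
#' @param tf_act data.frame with columns `sample`, `tf`, `nes`, `fdr`.
#' @param sig_alpha activity significance cutoff (default 0.05).
#' @param min_n minimum surviving samples (default 8).
#' @return data.frame `tf`, `n`, `tau`, `p`, `fdr`, `reason`.
#' @export
kendall_activity_correlation <- function(module_act, tf_act,
                                         sig_alpha = 0.05, min_n = 8) {
  rows <- lapply(split(tf_act, tf_act$tf), function(df) {
    merged <- merge(module_act, df, by = "sample",
                    suffixes = c("_mod", "_tf"))
    keep <- merged$fdr_mod < sig_alpha & merged$fdr_tf < sig_alpha
    merged <- merged[keep, ]
    if (nrow(merged) < min_n) {
      return(data.frame(tf = df$tf[1], n = nrow(merged), tau = NA_real_,
                        p = NA_real_, reason = "fewer than min_n significant samples",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(merged$nes_mod, merged$nes_tf,
                                           method = "kendall"))
    data.frame(tf = df$tf[1], n = nrow(merged), tau = unname(ct$estimate),
               p = ct$p.value, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out[, c("tf", "n", "tau", "p", "fdr", "reason")]
}

#' Two-sample Kolmogorov-Smirnov tests between groups
#'
#' @param values named numeric vector (per sample).
#' @param groups named group labels aligned with `values`.
#' @param min_n minimum group size (default 5).
#' @return data.frame `group1`, `group2`, `D`, `p` for each group pair.
#' @export
ks_group_difference <- function(values, groups, min_n = 5) {
  gs <- split(values, groups)
  check_that(all(lengths(gs) >= min_n),
             sprintf("each group needs >= %d values", min_n))
  nms <- names(gs)
  pairs <- utils::combn(nms, 2)
  rows <- apply(pairs, 2, function(pr) {
    kt <- suppressWarnings(stats::ks.test(gs[[pr[1]]], gs[[pr[2]]]))
    data.frame(group1 = pr[1], group2 = pr[2], D = unname(kt$statistic),
               p = kt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA with Tukey HSD per shape feature
#'
#' @param per_cell data.frame with numeric feature columns and rows as
#'   cells.
#' @param clusters factor/vector of cluster labels, one per row.
#' @param features feature columns to test (default: all numeric columns
#'   except `sample`/`batch`/`cell_id`/`drug`).
#' @return list with `anova` (data.frame `feature`, `F`, `p`) and `tukey`
#'   (data.frame of pairwise differences with confidence intervals).
#' @export
anova_shape <- function(per_cell, clusters, features = NULL) {
  cl <- factor(clusters)
  check_that(nlevels(cl) >= 2, "need >= 2 clusters")
  check_that(all(table(cl) >= 2), "each cluster needs >= 2 cells")
  if (is.null(features)) {
    features <- setdiff(colnames(per_cell)[vapply(per_cell, is.numeric,
                                                  logical(1))],
                        c("sample", "batch", "cell_id", "drug"))
  }
  a_rows <- list(); t_rows <- list()
  for (f in features) {
    y <- per_cell[[f]]
    wvar <- tapply(y, cl, stats::var)
    if (all(wvar == 0)) msg(sprintf("feature %s: zero within-group variance", f))
    fit <- stats::aov(y ~ cl)
    sm <- summary(fit)[[1]]
    a_rows[[f]] <- data.frame(feature = f, F = sm$`F value`[1],
                              p = sm$`Pr(>F)`[1], stringsAsFactors = FALSE)
    tk <- stats::TukeyHSD(fit)$cl
    t_rows[[f]] <- data.frame(feature = f, comparison = rownames(tk),
                              diff = tk[, "diff"], lwr = tk[, "lwr"],
                              upr = tk[, "upr"], p_adj = tk[, "p adj"],
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  list(anova = do.call(rbind, c(a_rows, list(make.row.names = FALSE))),
       tukey = do.call(rbind, c(t_rows, list(make.row.names = FALSE))))
}
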