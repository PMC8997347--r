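# Signed weighted coexpression analysis: soft-thresholded adjacency,
# topological overlap, average-linkage module detection with eigengene
# merging, and module-shape correlation with a rank-based permutation
# multiple-testing procedure.

#' Coexpression parameters
#'
#' @param beta soft-threshold power applied to the transformed correlation
#'   (default 9).
#' @param min_module_size smallest cluster retained as a module (default 30).
#' @param cut_height static tree-cut height as a fraction of the maximum
#'   merge height, in `(0, 1]` (default 0.9).
#' @param merge_corr eigengene correlation above which modules are merged,
#'   in `(0, 1)` (default 0.85).
#' @return list of class `coexpression_params`.
#' @export
coexpression_params <- function(beta = 9, min_module_size = 30,
                                cut_height = 0.9, merge_corr = 0.85) {
  check_that(beta >= 1, "beta must be >= 1")
  check_that(min_module_size >= 2, "min_module_size must be >= 2")
  check_that(cut_height > 0 && cut_height <= 1, "cut_height must be in (0,1]")
  check_that(merge_corr > 0 && merge_corr < 1, "merge_corr must be in (0,1)")
  structure(list(beta = beta, min_module_size = min_module_size,
                 cut_height = cut_height, merge_corr = merge_corr),
            class = "coexpression_params")
}

#' Filter genes by coding status and expression level
#'
#' Keeps genes from the coding set whose value exceeds `fpkm_min` in at
#' least one sample; gene order is preserved.
#'
#' @param expr non-negative matrix, genes x samples (FPKM scale).
#' @param coding character vector of coding gene names.
#' @param fpkm_min expression threshold (default 1).
#' @return filtered matrix. An empty result raises an error.
#' @export
filter_genes <- function(expr, coding, fpkm_min = 1) {
  check_that(all(expr >= 0), "expression must be non-negative")
  keep <- rownames(expr) %in% coding &
    apply(expr, 1, function(x) any(x > fpkm_min))
  if (!any(keep)) stop("no genes survive filtering", call. = FALSE)
  expr[keep, , drop = FALSE]
}

#' Signed soft-thresholded adjacency
#'
#' Computes `a_ij = |(1 + cor(x_i, x_j)) / 2|^beta` on the log2-transformed
#' expression. Negative correlation maps toward adjacency 0, positive
#' toward 1 (a signed network). Genes that are constant across samples get
#' correlation 0 (adjacency `(1/2)^beta`) with a message.
#'
#' @param expr matrix, genes x samples, FPKM scale (log2 taken internally
#'   with pseudo-count 1) or set `log2_transform = FALSE` if already logged.
#' @param beta soft-threshold power (>= 1).
#' @param log2_transform take log2(x + 1) first (default TRUE).
#' @return symmetric adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
wgcna_adjacency <- function(expr, beta = 9, log2_transform = TRUE) {
  check_that(beta >= 1, "beta must be >= 1")
  check_that(ncol(expr) >= 3, "need at least 3 samples")
  x <- if (log2_transform) log2(expr + 1) else expr
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    msg(sprintf("%d constant gene(s); correlation set to 0", sum(sds == 0)))
  }
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[is.na(cc)] <- 0
  a <- abs((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

#' Unsigned topological overlap matrix
#'
#' `t_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and `t_ii = 1`; the sum excludes `u = i, j` (the
#' zero diagonal takes care of this in the matrix product).
#'
#' @param adjacency symmetric matrix in `[0, 1]`, zero diagonal.
#' @return symmetric TOM in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  check_that(isTRUE(all.equal(a, t(a))), "adjacency must be symmetric")
  check_that(all(a >= 0 & a <= 1), "adjacency entries must be in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Module eigengene
#'
#' First principal component of the gene-standardized submatrix across
#' samples, scaled to unit variance and sign-oriented to correlate
#' non-negatively with the module's mean standardized profile.
#'
#' @param expr matrix, genes x samples (log2 scale used internally).
#' @param genes character vector of module members (>= 2).
#' @param log2_transform take log2(x + 1) first (default TRUE).
#' @return numeric vector of length `ncol(expr)`.
#' @export
eigengene <- function(expr, genes, log2_transform = TRUE) {
  check_that(length(genes) >= 2, "eigengene needs >= 2 genes")
  x <- expr[genes, , drop = FALSE]
  if (log2_transform) x <- log2(x + 1)
  z <- t(scale(t(x)))                    # standardize each gene
  z[is.na(z)] <- 0                       # constant genes contribute nothing
  if (all(z == 0)) stop("rank-0 module submatrix", call. = FALSE)
  sv <- svd(t(z), nu = 1, nv = 0)
  eg <- sv$u[, 1]
  mp <- colMeans(z)
  if (stats::cor(eg, mp) < 0) eg <- -eg
  eg <- eg / stats::sd(eg)
  stats::setNames(eg, colnames(expr))
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with a
#' static cut at `cut_height` of the maximum merge height; clusters smaller
#' than `min_module_size` go to the unassigned pool; modules whose
#' eigengenes correlate above `merge_corr` are merged iteratively until a
#' fixed point.
#'
#' @param dissimilarity square matrix, `1 - TOM`.
#' @param expr expression matrix (genes x samples) used for eigengenes.
#' @param params a [coexpression_params()].
#' @param log2_transform passed to [eigengene()].
#' @return a `module_set`: list with `modules` (label -> gene vector),
#'   `eigengenes` (samples x modules matrix) and `unassigned`.
#' @export
detect_modules <- function(dissimilarity, expr, params = coexpression_params(),
                           log2_transform = TRUE) {
  check_that(nrow(dissimilarity) == ncol(dissimilarity),
             "dissimilarity must be square")
  genes <- rownames(dissimilarity)
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  h <- params$cut_height * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  groups <- split(genes, cl)
  big <- groups[lengths(groups) >= params$min_module_size]
  unassigned <- unlist(groups[lengths(groups) < params$min_module_size],
                       use.names = FALSE)
  if (length(big) == 0L) {
    msg("no module reached the minimum size; all genes unassigned")
    return(module_set(list(), matrix(numeric(0), nrow = ncol(expr), ncol = 0),
                      genes))
  }
  names(big) <- sprintf("GEM%02d", seq_along(big))
  repeat {
    egs <- vapply(big, function(g) eigengene(expr, g, log2_transform),
                  numeric(ncol(expr)))
    if (length(big) < 2L) break
    cm <- stats::cor(egs)
    cm[lower.tri(cm, diag = TRUE)] <- -Inf
    if (max(cm) <= params$merge_corr) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    big[[ij[1]]] <- c(big[[ij[1]]], big[[ij[2]]])
    big <- big[-ij[2]]
    names(big) <- sprintf("GEM%02d", seq_along(big))
  }
  module_set(big, egs, if (is.null(unassigned)) character(0) else unassigned)
}

#' Construct a module set
#'
#' @param modules named list of disjoint gene vectors.
#' @param eigengenes samples x modules matrix of eigengene profiles.
#' @param unassigned genes not in any module.
#' @return object of class `module_set`.
#' @export
module_set <- function(modules, eigengenes, unassigned = character(0)) {
  if (length(modules) > 0) {
    check_that(!anyDuplicated(unlist(modules)), "modules must be disjoint")
    colnames(eigengenes) <- names(modules)
  }
  structure(list(modules = modules, eigengenes = eigengenes,
                 unassigned = unassigned), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("Module set: %d modules (sizes %s), %d unassigned genes\n",
              length(x$modules),
              paste(lengths(x$modules), collapse = ", "),
              length(x$unassigned)))
  invisible(x)
}

#' Run the full coexpression stage
#'
#' Convenience wrapper: filter, adjacency, TOM, module detection.
#'
#' @inheritParams filter_genes
#' @inheritParams detect_modules
#' @return a `module_set` with the TOM kept as attribute `tom`.
#' @export
coexpression_modules <- function(expr, coding = rownames(expr), fpkm_min = 1,
                                 params = coexpression_params()) {
  kept <- filter_genes(expr, coding, fpkm_min)
  a <- wgcna_adjacency(kept, beta = params$beta)
  tom <- topological_overlap(a)
  ms <- detect_modules(1 - tom, kept, params)
  attr(ms, "tom") <- tom
  ms
}

#' Correlate module eigengenes with shape features
#'
#' Pearson correlation per (module, feature) with Student asymptotic
#' p-values, plus a rank-based permutation correction: the shape rows are
#' label-permuted `B` times, each time the full `|r|` matrix is recomputed
#' and its entries sorted; the observed entry of rank k is compared against
#' the null distribution of rank-k statistics, giving
#' `p_perm = (1 + #\{null_k >= obs_k\}) / (B + 1)` with a Clopper-Pearson
#' confidence interval. A pair is flagged significant when `|r| > r_min`
#' and the Student p is below `p_max`.
#'
#' @param eigengenes samples x modules matrix.
#' @param shape data.frame from [read_shape_tsv()] (or matrix) with one row
#'   per sample, aligned with the eigengene rows.
#' @param B number of permutations (>= 100; default 1000).
#' @param r_min,p_max significance thresholds (defaults 0.5 and 0.05).
#' @param seed RNG seed for the permutations.
#' @return list of class `module_shape_correlation` with matrices `pcc`,
#'   `p_student`, `p_perm`, `ci_lo`, `ci_hi`, `significant`.
#' @export
correlate_modules_shape <- function(eigengenes, shape, B = 1000,
                                    r_min = 0.5, p_max = 0.05, seed = NULL) {
  if (is.data.frame(shape)) {
    shape <- as.matrix(shape[, setdiff(colnames(shape), c("sample", "batch")),
                             drop = FALSE])
  }
  n <- nrow(eigengenes)
  check_that(nrow(shape) == n, "sample mismatch between eigengenes and shape")
  check_that(n >= 4, "need at least 4 samples")
  check_that(B >= 100, "B must be >= 100")
  r <- stats::cor(eigengenes, shape)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_student <- 2 * stats::pt(-abs(tt), df = n - 2)

  m <- length(r)
  obs_sorted <- sort(abs(as.vector(r)), decreasing = TRUE)
  ord <- order(abs(as.vector(r)), decreasing = TRUE)
  exceed <- integer(m)
  with_seed(seed, {
    for (b in seq_len(B)) {
      rb <- stats::cor(eigengenes, shape[sample.int(n), , drop = FALSE])
      null_sorted <- sort(abs(as.vector(rb)), decreasing = TRUE)
      exceed <- exceed + (null_sorted >= obs_sorted)
    }
  })
  p_rank <- (1 + exceed) / (B + 1)
  ci_lo_r <- stats::qbeta(0.025, exceed + 1, B - exceed)
  ci_hi_r <- stats::qbeta(0.975, exceed + 2, B - exceed)
  p_perm <- ci_lo <- ci_hi <- matrix(NA_real_, nrow(r), ncol(r),
                                     dimnames = dimnames(r))
  p_perm[ord] <- p_rank
  ci_lo[ord] <- ci_lo_r
  ci_hi[ord] <- ci_hi_r
  significant <- abs(r) > r_min & p_student < p_max
  structure(list(pcc = r, p_student = p_student, p_perm = p_perm,
                 ci_lo = ci_lo, ci_hi = ci_hi, significant = significant,
                 B = B, r_min = r_min, p_max = p_max),
            class = "module_shape_correlation")
}

#' @export
print.module_shape_correlation <- function(x, ...) {
  cat(sprintf("Module-shape correlation: %d modules x %d features, %d significant pair(s)\n",
              nrow(x$pcc), ncol(x$pcc), sum(x$significant)))
  invisible(x)
}

#' Jackknife stability of module detection
#'
#' Leave-one-sample-out re-detection; for each original module reports the
#' mean and minimum best-match Jaccard index across folds.
#'
#' @param expr filtered expression matrix, genes x samples.
#' @param params a [coexpression_params()].
#' @param reference optional `module_set` detected on the full data
#'   (recomputed if missing).
#' @return data.frame with one row per original module: `module`,
#'   `mean_jaccard`, `min_jaccard`.
#' @export
jackknife_modules <- function(expr, params = coexpression_params(),
                              reference = NULL) {
  check_that(ncol(expr) >= 3, "need at least 3 samples")
  if (is.null(reference)) {
    reference <- coexpression_modules(expr, params = params)
  }
  if (length(reference$modules) == 0L) {
    return(data.frame(module = character(0), mean_jaccard = numeric(0),
                      min_jaccard = numeric(0)))
  }
  folds <- lapply(seq_len(ncol(expr)), function(j) {
    ms <- coexpression_modules(expr[, -j, drop = FALSE], params = params)
    best_match_jaccard(ms$modules, reference$modules)$jaccard
  })
  jm <- do.call(cbind, folds)
  data.frame(module = names(reference$modules),
             mean_jaccard = rowMeans(jm),
             min_jaccard = apply(jm, 1, min),
             stringsAsFactors = FALSE)
}
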