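# Drug-perturbation validation: filtering of kinase-inhibitor target
# profiles, batch-relative morphology log fold changes, the
# PageRank-times-overlap influence score, and the in-vs-out-of-network
# group and correlation statistics.

#' Filter kinase-inhibitor target profiles
#'
#' Keeps drug-target pairs with binding class 1 (high-affinity binding)
#' and drops drugs retaining more than five targets, leaving
#' narrow-spectrum inhibitors; drugs with no class-1 target are dropped.
#'
#' @param tas data.frame with columns `drug`, `target`, `binding_class`.
#' @param max_targets maximum retained target-set size (default 5).
#' @return named list of `drug_profile` objects (elements `drug`,
#'   `targets`).
#' @export
filter_drug_targets <- function(tas, max_targets = 5) {
  check_that(all(c("drug", "target", "binding_class") %in% colnames(tas)),
             "need columns drug, target, binding_class")
  keep <- tas[tas$binding_class == 1, , drop = FALSE]
  profiles <- lapply(split(keep$target, keep$drug), unique)
  profiles <- profiles[lengths(profiles) >= 1 &
                         lengths(profiles) <= max_targets]
  lapply(stats::setNames(names(profiles), names(profiles)), function(d) {
    structure(list(drug = d, targets = profiles[[d]]),
              class = "drug_profile")
  })
}

#' Batch-relative morphology log fold changes
#'
#' Per cell and feature: `log10(value / batch control mean)`, where the
#' control pool is the rows whose `drug` equals `control_label`. Paired
#' dye-normalized readings (columns `<feature>_reading1` /
#' `<feature>_reading2`) are first averaged into `<feature>`. Features
#' whose control mean is zero in a batch are masked (`NA`) for that batch.
#'
#' @param response data.frame with `cell_id`, `drug`, `batch` and numeric
#'   feature columns.
#' @param control_label value of `drug` marking control cells (default
#'   `"control"`).
#' @return data.frame with the same id columns and per-feature log10 fold
#'   changes (control rows excluded).
#' @export
morphology_lfc <- function(response, control_label = "control") {
  id_cols <- c("cell_id", "drug", "batch")
  feat_cols <- setdiff(colnames(response), id_cols)
  # average paired dye-normalized readings into their base feature
  rd1 <- grep("_reading1$", feat_cols, value = TRUE)
  for (c1 in rd1) {
    base <- sub("_reading1$", "", c1)
    c2 <- paste0(base, "_reading2")
    if (c2 %in% feat_cols) {
      response[[base]] <- (response[[c1]] + response[[c2]]) / 2
      response[[c1]] <- NULL
      response[[c2]] <- NULL
    }
  }
  feat_cols <- setdiff(colnames(response), id_cols)
  out <- list()
  for (b in unique(response$batch)) {
    rb <- response[response$batch == b, , drop = FALSE]
    ctrl <- rb[rb$drug == control_label, feat_cols, drop = FALSE]
    check_that(nrow(ctrl) > 0, sprintf("batch %s has no control cells", b))
    cm <- colMeans(ctrl)
    treated <- rb[rb$drug != control_label, , drop = FALSE]
    lfc <- sweep(as.matrix(treated[, feat_cols, drop = FALSE]), 2, cm, `/`)
    lfc <- log10(lfc)
    lfc[, cm == 0] <- NA_real_
    out[[b]] <- cbind(treated[, id_cols], as.data.frame(lfc))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# PageRank on the undirected |weight| view, damping 0.85; memoized on the
# network object via an attribute so repeated influence calls are cheap.
network_pagerank <- function(net, damping = 0.85) {
  cached <- attr(net, "pagerank")
  if (!is.null(cached)) return(cached)
  g <- as_igraph(net, directed = FALSE)
  pr <- igraph::page_rank(g, damping = damping,
                          weights = pmax(abs(igraph::E(g)$weight), 1e-12))
  pr$vector
}

#' Attach a cached PageRank vector to a network
#'
#' @param net an `assembled_network`.
#' @param damping damping factor (default 0.85).
#' @return the network with a `pagerank` attribute.
#' @export
with_pagerank <- function(net, damping = 0.85) {
  attr(net, "pagerank") <- network_pagerank(net, damping)
  net
}

#' Network influence score of a drug
#'
#' `S = (sum of PageRank over in-network targets) * |K intersect N| /
#' min(|K|, |N|)` -- the summed centrality of the targeted nodes times the
#' Szymkiewicz-Simpson overlap of the target set `K` with the network node
#' set `N`. Zero iff no target lies in the network.
#'
#' @param profile a `drug_profile` (or character target vector).
#' @param net an `assembled_network` (PageRank with damping 0.85 on the
#'   undirected `|weight|` view is computed, or reused via
#'   [with_pagerank()]).
#' @return non-negative influence score.
#' @export
influence_score <- function(profile, net) {
  check_that(nrow(net$nodes) > 0, "empty network")
  targets <- if (inherits(profile, "drug_profile")) profile$targets
             else as.character(profile)
  pr <- network_pagerank(net)
  inside <- intersect(targets, names(pr))
  if (length(inside) == 0L) return(0)
  sum(pr[inside]) * length(inside) / min(length(targets), length(pr))
}

#' Compare morphology effects of in-network vs out-of-network drugs
#'
#' A drug is in-network when at least one filtered target is a network
#' node. Per feature, the absolute log fold changes of the two drug groups
#' are compared with a Welch two-sample t-test and a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param lfcs output of [morphology_lfc()].
#' @param profiles list from [filter_drug_targets()].
#' @param net an `assembled_network`.
#' @return data.frame `feature`, `n_in`, `n_out`, `welch_t`, `welch_p`,
#'   `ks_d`, `ks_p` (NA with a reason when a group has < 2 drugs).
#' @export
compare_in_vs_out <- function(lfcs, profiles, net) {
  nodes <- net$nodes$node
  in_net <- vapply(profiles, function(p) any(p$targets %in% nodes),
                   logical(1))
  lab <- stats::setNames(in_net[lfcs$drug], lfcs$drug)
  keep <- lfcs$drug %in% names(profiles)
  lfcs <- lfcs[keep, , drop = FALSE]
  grp <- in_net[lfcs$drug]
  feat_cols <- setdiff(colnames(lfcs), c("cell_id", "drug", "batch"))
  n_in <- length(unique(lfcs$drug[grp]))
  n_out <- length(unique(lfcs$drug[!grp]))
  rows <- lapply(feat_cols, function(f) {
    x <- abs(lfcs[[f]][grp]); y <- abs(lfcs[[f]][!grp])
    if (n_in < 2 || n_out < 2) {
      return(data.frame(feature = f, n_in = n_in, n_out = n_out,
                        welch_t = NA_real_, welch_p = NA_real_,
                        ks_d = NA_real_, ks_p = NA_real_,
                        reason = "fewer than 2 drugs in a group",
                        stringsAsFactors = FALSE))
    }
    wt <- stats::t.test(x, y)
    kt <- suppressWarnings(stats::ks.test(x, y))
    data.frame(feature = f, n_in = n_in, n_out = n_out,
               welch_t = unname(wt$statistic), welch_p = wt$p.value,
               ks_d = unname(kt$statistic), ks_p = kt$p.value,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate drug influence with morphological effect
#'
#' Per feature: Spearman rank correlation (with asymptotic p) between the
#' influence score and the per-drug mean absolute log10 fold change.
#'
#' @param lfcs output of [morphology_lfc()].
#' @param scores named influence scores per drug.
#' @param min_drugs minimum number of scored drugs (default 5).
#' @return data.frame `feature`, `rho`, `p` (NA when scores are constant).
#' @export
correlate_influence <- function(lfcs, scores, min_drugs = 5) {
  drugs <- intersect(unique(lfcs$drug), names(scores))
  check_that(length(drugs) >= min_drugs,
             sprintf("need >= %d drugs with scores", min_drugs))
  feat_cols <- setdiff(colnames(lfcs), c("cell_id", "drug", "batch"))
  s <- scores[drugs]
  rows <- lapply(feat_cols, function(f) {
    eff <- vapply(drugs, function(d) {
      mean(abs(lfcs[[f]][lfcs$drug == d]), na.rm = TRUE)
    }, numeric(1))
    if (stats::sd(s) == 0) {
      return(data.frame(feature = f, rho = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(s, eff, method = "spearman"))
    data.frame(feature = f, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
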