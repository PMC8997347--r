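# Maximum-flow subnetwork extraction between a module supernode and a
# signaling endpoint, with semantic-similarity edge capacities.

#' Maximum flow between two network nodes
#'
#' Computes the maximum source-to-sink flow on the directed view of the
#' network (or the undirected view with `undirected = TRUE`), with
#' per-edge capacities taken from the network's `capacity` column (the
#' unsigned semantic similarity set by [reweight_edges()]; `|weight|`
#' otherwise). The flow value equals the minimum-cut capacity.
#'
#' @param net an `assembled_network`.
#' @param source,sink node names (must be present and distinct).
#' @param undirected treat all edges as bidirectional (default FALSE).
#' @return list of class `flow_result`: `value`, `edges` (data.frame
#'   `source`, `target`, `capacity`, `flow`), `cut` (min-cut edge ids).
#' @export
max_flow <- function(net, source, sink, undirected = FALSE) {
  check_that(source != sink, "source and sink must differ")
  g <- as_igraph(net, directed = !undirected)
  vn <- igraph::V(g)$name
  check_that(source %in% vn, sprintf("source '%s' absent from network", source))
  check_that(sink %in% vn, sprintf("sink '%s' absent from network", sink))
  cap <- if ("capacity" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$capacity
  } else {
    abs(igraph::E(g)$weight)
  }
  check_that(all(cap >= 0), "capacities must be non-negative")
  mf <- igraph::max_flow(g, source = source, target = sink, capacity = cap)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2], capacity = cap,
                      flow = as.numeric(mf$flow), stringsAsFactors = FALSE)
  structure(list(value = mf$value, edges = edges,
                 cut = as.integer(mf$cut)), class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("Max flow %.6g over %d edges (%d carrying flow)\n",
              x$value, nrow(x$edges), sum(abs(x$edges$flow) > 0)))
  invisible(x)
}

#' Top flow-carrying subnetwork
#'
#' Keeps the edges whose flow is at least the given percentile of the
#' positive flows (percentile computed over flow-carrying edges only,
#' linear-interpolation quantile; ties at the threshold are included).
#'
#' @param flow a `flow_result`.
#' @param percentile percentile in `[0, 100]` (default 99).
#' @return data.frame of the retained edges (`source`, `target`,
#'   `capacity`, `flow`); empty with a warning when no edge carries flow.
#' @export
top_flow_subnetwork <- function(flow, percentile = 99) {
  stopifnot(inherits(flow, "flow_result"))
  fl <- abs(flow$edges$flow)
  pos <- fl > 0
  if (!any(pos)) {
    warning("no edge carries positive flow", call. = FALSE)
    return(flow$edges[0, ])
  }
  thr <- stats::quantile(fl[pos], probs = percentile / 100, type = 7,
                         names = FALSE)
  out <- flow$edges[pos & fl >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}
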