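#' Sigmoid node weights from clr abundances
#'
#' Maps each clr value through a logistic sigmoid,
#' `p_i(u) = 1 / (1 + exp(-(clr - offset) / scale))`, so that an OTU at its
#' geometric-mean abundance (clr = 0, with the defaults) gets weight 0.5 and
#' weights lie strictly in (0, 1). The default unit scale / zero offset is
#' the standard logistic; both are exposed for sensitivity analysis since
#' downstream indices respond to the sigmoid's steepness.
#'
#' @param clr Samples x OTUs clr matrix.
#' @param scale Positive sigmoid scale (default 1).
#' @param offset Sigmoid midpoint on the clr axis (default 0).
#' @return Samples x OTUs matrix of node weights in (0, 1).
#' @export
node_weights <- function(clr, scale = 1, offset = 0) {
  stopifnot(scale > 0)
  stats::plogis((clr - offset) / scale)
}

#' Edge-satisfaction index per sample and module
#'
#' Measures the completeness of each network module in each sample:
#' `ES_{M,i} = sum_{(u,v) in M} sigma(u,v) * min(p_i(u), p_i(v)) /
#' sum_{(u,v) in M} sigma(u,v)`, the weighted fraction of the module's
#' internal edges whose both endpoints are "present" (carry high node
#' weight) in sample i. Because node and edge weights lie in (0, 1], the
#' index lies in [0, 1]. Modules without any internal edge have no defined
#' index; their column is omitted with a warning. The ratio form makes the
#' index identical whether internal edges are counted once or as ordered
#' pairs.
#'
#' @param net A [co_network()].
#' @param partition A `module_partition` (or a named membership vector).
#' @param w Node-weight matrix from [node_weights()]; columns must cover all
#'   network nodes.
#' @return Samples x modules matrix of ES values in `[0, 1]`, columns named
#'   by module id in ascending order.
#' @export
edge_satisfaction <- function(net, partition, w) {
  memb <- if (inherits(partition, "module_partition")) {
    partition$membership
  } else {
    partition
  }
  if (!all(net$nodes %in% names(memb))) stop("partition must cover all nodes")
  if (!all(net$nodes %in% colnames(w))) {
    stop("node weights must cover all network nodes")
  }
  mods <- sort(unique(as.integer(memb[net$nodes])))
  eu <- net$edges$u; ev <- net$edges$v
  internal <- memb[eu] == memb[ev]
  es <- matrix(NA_real_, nrow(w), 0L, dimnames = list(rownames(w), NULL))
  kept <- integer(0)
  for (m in mods) {
    sel <- internal & memb[eu] == m
    if (!any(sel)) {
      warning("module ", m, " has no internal edge; column omitted")
      next
    }
    wt <- net$edges$weight[sel]
    pm <- pmin(w[, eu[sel], drop = FALSE], w[, ev[sel], drop = FALSE])
    es <- cbind(es, as.vector(pm %*% wt) / sum(wt))
    kept <- c(kept, m)
  }
  colnames(es) <- as.character(kept)
  es
}

#' Assign a community type to every sample
#'
#' The community type of a sample is the module with the highest
#' edge-satisfaction index in that sample. Ties (including all-zero rows)
#' are broken toward the lowest module id and flagged, so downstream counts
#' are reproducible.
#'
#' @param es Samples x modules ES matrix from [edge_satisfaction()].
#' @return `data.frame` with `sample_id`, `community_type` (integer module
#'   id) and `tie` (logical flag).
#' @export
assign_types <- function(es) {
  if (ncol(es) < 1L) stop("need at least one module column")
  mods <- as.integer(colnames(es))
  best <- apply(es, 1L, function(r) {
    top <- which(r == max(r))
    c(mods[top[1L]], length(top) > 1L)
  })
  data.frame(sample_id = rownames(es),
             community_type = as.integer(best[1L, ]),
             tie = as.logical(best[2L, ]),
             stringsAsFactors = FALSE)
}

#' Long-format export of an ES matrix
#'
#' Heatmap-ready tidy table; samples are ordered by latitude when metadata
#' is supplied, mirroring the latitude-sorted ES heatmap of the reference
#' analysis.
#'
#' @param es ES matrix.
#' @param meta Optional metadata with `sample_id` and `latitude`.
#' @return `data.frame` with columns `sample_id`, `module`, `es`.
#' @export
es_long <- function(es, meta = NULL) {
  ord <- rownames(es)
  if (!is.null(meta)) {
    lat <- meta$latitude[match(ord, meta$sample_id)]
    ord <- ord[order(lat)]
  }
  es <- es[ord, , drop = FALSE]
  data.frame(sample_id = rep(rownames(es), times = ncol(es)),
             module = rep(as.integer(colnames(es)), each = nrow(es)),
             es = as.vector(es),
             stringsAsFactors = FALSE)
}
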