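#' Construct a co-occurrence network object
#'
#' An undirected OTU graph with strictly positive edge weights in (0, 1].
#' Stored as a canonical edge list (`u < v` lexicographically) plus the node
#' inventory; weighted degrees and the total edge weight are derived on
#' demand.
#'
#' @param edges `data.frame` with columns `u`, `v` (node ids) and `weight`.
#' @param nodes Character vector of node ids (defaults to nodes appearing in
#'   `edges`).
#' @return Object of class `co_network`.
#' @export
co_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("u", "v", "weight") %in% names(edges)))
  edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
  if (any(edges$u == edges$v)) stop("self-loops are not allowed")
  if (any(edges$weight <= 0)) stop("edge weights must be strictly positive")
  if (any(edges$weight > 1)) stop("edge weights must be <= 1")
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  if (anyDuplicated(paste(edges$u, edges$v))) stop("duplicate edges")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$u, edges$v)))
  if (!all(c(edges$u, edges$v) %in% nodes)) stop("edge endpoint not in nodes")
  edges <- edges[order(edges$u, edges$v), c("u", "v", "weight")]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "co_network")
}

#' Print a co_network summary
#'
#' @param x Object.
#' @param ... Unused.
#' @return The object, invisibly.
#' @method print co_network
#' @export
print.co_network <- function(x, ...) {
  cat("co_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "positive edges, total weight", round(sum(x$edges$weight), 3), "\n")
  invisible(x)
}

# internal: weighted adjacency matrix of a co_network (dense; desk scale)
adjacency_of <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  iu <- match(net$edges$u, net$nodes)
  iv <- match(net$edges$v, net$nodes)
  a[cbind(iu, iv)] <- net$edges$weight
  a[cbind(iv, iu)] <- net$edges$weight
  a
}

#' Infer a network of direct positive associations between OTUs
#'
#' A conditional-independence screen in the spirit of local-to-global
#' causal-structure learning: starting from all pairs whose Pearson
#' correlation of clr abundances is significant (Fisher z-test at `alpha`),
#' each surviving pair is re-tested given every conditioning subset of the
#' pair's current candidate neighbors up to size `max_conditioning`
#' (neighborhoods are frozen within each conditioning stage, so the result
#' does not depend on column order). A pair is kept only if no test accepts
#' conditional independence. The edge weight is the minimal-magnitude
#' surviving partial correlation; pairs whose minimal association is
#' negative are discarded, so all weights lie in (0, 1].
#'
#' @param clr Samples x OTUs matrix of clr-transformed abundances
#'   ([clr_transform()]); needs >= 10 samples and >= 3 OTUs.
#' @param alpha Significance level of the Fisher z-test (default 0.05).
#' @param max_conditioning Largest conditioning-set size (default 3).
#' @param max_neighbors Cap on the candidate-neighbor pool per pair (largest
#'   absolute marginal correlations kept) to bound the subset enumeration.
#' @return A [co_network()] over the non-constant OTU columns.
#' @export
infer_network <- function(clr, alpha = 0.05, max_conditioning = 3L,
                          max_neighbors = 20L) {
  stopifnot(is.matrix(clr))
  n <- nrow(clr)
  if (n < 10L) stop("need >= 10 samples")
  sds <- apply(clr, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant OTU column(s) excluded from testing")
    clr <- clr[, sds > 0, drop = FALSE]
  }
  p <- ncol(clr)
  if (p < 3L) stop("need >= 3 non-constant OTUs")
  ids <- colnames(clr)
  C <- stats::cor(clr)

  fisher_p <- function(r, n_eff) {
    r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
    z <- atanh(r) * sqrt(n_eff)
    2 * stats::pnorm(-abs(z))
  }

  ## stage 0: marginal screen
  alive <- matrix(FALSE, p, p)
  weight <- matrix(NA_real_, p, p)
  p0 <- matrix(fisher_p(C, n - 3), p, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (p0[i, j] < alpha) {
      alive[i, j] <- TRUE
      weight[i, j] <- C[i, j]
    }
  }

  partial_cor <- function(i, j, s) {
    sub <- C[c(i, j, s), c(i, j, s), drop = FALSE]
    om <- tryCatch(solve(sub), error = function(e) NULL)
    if (is.null(om)) return(NA_real_)
    -om[1L, 2L] / sqrt(om[1L, 1L] * om[2L, 2L])
  }

  if (max_conditioning >= 1L) for (size in seq_len(max_conditioning)) {
    nb <- lapply(seq_len(p), function(i)
      which(alive[i, ] | alive[, i]))                # frozen this stage
    pairs <- which(alive, arr.ind = TRUE)
    if (nrow(pairs) == 0L) break
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1L]; j <- pairs[e, 2L]
      cand <- setdiff(union(nb[[i]], nb[[j]]), c(i, j))
      if (length(cand) > max_neighbors) {
        strength <- abs(C[cand, i]) + abs(C[cand, j])
        cand <- cand[order(-strength, cand)][seq_len(max_neighbors)]
      }
      if (length(cand) < size) next
      subs <- utils::combn(sort(cand), size)
      for (k in seq_len(ncol(subs))) {
        r <- partial_cor(i, j, subs[, k])
        if (is.na(r)) next
        if (fisher_p(r, n - size - 3) >= alpha) {    # independence accepted
          alive[i, j] <- FALSE
          break
        }
        if (abs(r) < abs(weight[i, j])) weight[i, j] <- r
      }
    }
  }

  keep <- which(alive & weight > 0, arr.ind = TRUE)
  edges <- data.frame(u = ids[keep[, 1L]], v = ids[keep[, 2L]],
                      weight = pmin(1, weight[keep]),
                      stringsAsFactors = FALSE)
  co_network(edges, nodes = ids)
}

#' Weighted modularity Q of a partition
#'
#' Evaluates, over ordered node pairs (diagonal included),
#' `Q = (1 / 2S) * sum_{u,v} (sigma(u,v) - k_u k_v / 2S) * delta(M_u, M_v)`
#' where `sigma(u,v)` is the edge weight, `S` the sum of all edge weights,
#' `k_u` the weighted degree and `delta` the same-module indicator. This is
#' the quantity maximized by the module-detection algorithms and reported
#' alongside every partition.
#'
#' @param net A [co_network()].
#' @param membership Named integer vector mapping every node to a module id.
#' @return Modularity Q (scalar in `[-0.5, 1]`).
#' @export
modularity_q <- function(net, membership) {
  a <- adjacency_of(net)
  if (!all(net$nodes %in% names(membership))) {
    stop("membership must cover all nodes")
  }
  m <- membership[net$nodes]
  s <- sum(a) / 2
  if (s == 0) stop("empty network: S = 0")
  k <- rowSums(a)
  same <- outer(m, m, "==")
  sum((a - outer(k, k) / (2 * s)) * same) / (2 * s)
}

#' Detect network modules
#'
#' Partitions the network into modules with a chosen community-detection
#' algorithm, heuristically maximizing modularity. Disconnected components
#' are handled natively by the algorithms. Module ids are renumbered 1..K by
#' descending module size (ties by first node) for stable downstream naming,
#' and the partition carries its Q as computed by [modularity_q()].
#'
#' @param net A [co_network()].
#' @param algorithm One of `"louvain"`, `"leiden"`, `"label_prop"`,
#'   `"fast_greedy"`, `"walktrap"`.
#' @param seed Integer seed (several algorithms are stochastic).
#' @return Object of class `module_partition`: list with `membership` (named
#'   integer vector), `Q`, `algorithm`, `sizes`.
#' @export
detect_modules <- function(net, algorithm = "louvain", seed = 1L) {
  algs <- c("louvain", "leiden", "label_prop", "fast_greedy", "walktrap")
  if (!algorithm %in% algs) {
    stop("unknown algorithm '", algorithm, "'; choose one of: ",
         paste(algs, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  set.seed(as.integer(seed))
  comm <- switch(algorithm,
    louvain = igraph::cluster_louvain(g, weights = igraph::E(g)$weight),
    leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                    weights = igraph::E(g)$weight,
                                    n_iterations = 5L),
    label_prop = igraph::cluster_label_prop(g, weights = igraph::E(g)$weight),
    fast_greedy = igraph::cluster_fast_greedy(g,
                                              weights = igraph::E(g)$weight),
    walktrap = igraph::cluster_walktrap(g, weights = igraph::E(g)$weight))
  memb <- igraph::membership(comm)
  memb <- stats::setNames(as.integer(memb), names(memb))[net$nodes]
  memb <- renumber_modules(memb)
  structure(list(membership = memb,
                 Q = modularity_q(net, memb),
                 algorithm = algorithm,
                 sizes = as.integer(table(memb))),
            class = "module_partition")
}

# internal: relabel modules 1..K by descending size, ties by first appearance
renumber_modules <- function(memb) {
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- names(sizes)[order(-sizes, first)]
  stats::setNames(match(as.character(memb), ord), names(memb))
}

#' Print a module_partition summary
#'
#' @param x Object.
#' @param ... Unused.
#' @return The object, invisibly.
#' @method print module_partition
#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition (", x$algorithm, "): ", length(x$sizes),
      " modules, sizes ", paste(x$sizes, collapse = "/"),
      ", Q = ", round(x$Q, 4), "\n", sep = "")
  invisible(x)
}

#' Select the working partition among candidates
#'
#' Among candidate partitions whose smallest module has at least
#' `min_module_size` nodes, returns the one with the highest modularity Q —
#' the rule used to pick the working module set in the reference analysis
#' (highest Q among algorithms, with small-module partitions rejected as
#' failing to capture the macrostructure). If no candidate passes the size
#' check, the highest-Q partition is returned with a warning.
#'
#' @param candidates List of `module_partition` objects.
#' @param min_module_size Minimum size of the smallest allowed module
#'   (default 3).
#' @return The selected `module_partition`.
#' @export
select_partition <- function(candidates, min_module_size = 3L) {
  if (length(candidates) == 0L) stop("no candidate partitions")
  qs <- vapply(candidates, function(p) p$Q, numeric(1L))
  ok <- vapply(candidates, function(p) min(p$sizes) >= min_module_size,
               logical(1L))
  if (any(ok)) {
    candidates[ok][[which.max(qs[ok])]]
  } else {
    warning("no candidate passes the module-size check; ",
            "returning highest-Q partition")
    candidates[[which.max(qs)]]
  }
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical up to relabeling, ~0 = random.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
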