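# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own computational paths.

# all set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# brute-force evaluation of the ordered-pair modularity formula, working
# directly off the edge list (no adjacency matrix, no matrix algebra)
brute_modularity <- function(net, membership) {
  nodes <- net$nodes
  lut <- c(stats::setNames(net$edges$weight,
                           paste(net$edges$u, net$edges$v)),
           stats::setNames(net$edges$weight,
                           paste(net$edges$v, net$edges$u)))
  sigma <- function(a, b) {
    w <- lut[paste(a, b)]
    if (is.na(w)) 0 else w
  }
  k <- vapply(nodes, function(a)
    sum(net$edges$weight[net$edges$u == a | net$edges$v == a]), numeric(1))
  s <- sum(net$edges$weight)
  total <- 0
  for (a in nodes) for (b in nodes) {
    if (membership[a] == membership[b]) {
      total <- total + sigma(a, b) - k[a] * k[b] / (2 * s)
    }
  }
  unname(total / (2 * s))
}

# random connected-ish weighted graph on n nodes
random_weighted_net <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    e <- expand.grid(u = seq_len(n), v = seq_len(n))
    e <- e[e$u < e$v & stats::runif(nrow(e)) < p_edge, ]
    if (nrow(e) >= 1L) break
  }
  e$weight <- stats::runif(nrow(e), 0.05, 1)
  e$u <- sprintf("n%02d", e$u)
  e$v <- sprintf("n%02d", e$v)
  co_network(e, nodes = sprintf("n%02d", seq_len(n)))
}

# planted-partition graph: `blocks` blocks of `size` nodes, strong within
# weights, sparse weak between weights
planted_partition_net <- function(blocks, size, w_in = c(0.6, 1),
                                  w_out = 0.05, p_out = 0.1, seed = 1) {
  set.seed(seed)
  n <- blocks * size
  lab <- rep(seq_len(blocks), each = size)
  e <- expand.grid(u = seq_len(n), v = seq_len(n))
  e <- e[e$u < e$v, ]
  same <- lab[e$u] == lab[e$v]
  keep <- same | stats::runif(nrow(e)) < p_out
  e <- e[keep, ]
  same <- same[keep]
  e$weight <- ifelse(same, stats::runif(nrow(e), w_in[1], w_in[2]), w_out)
  ids <- sprintf("n%02d", seq_len(n))
  e$u <- ids[e$u]; e$v <- ids[e$v]
  list(net = co_network(e, nodes = ids),
       planting = stats::setNames(lab, ids))
}

# classification accuracy after the best one-to-one relabeling (exhaustive
# over permutations; fine for K <= 6)
best_match_accuracy <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  pl <- unique(pred); tl <- unique(truth)
  if (length(pl) > 7L) stop("too many predicted labels for exhaustive match")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  labels <- union(pl, tl)
  best <- 0
  for (p in perms(labels)) {
    map <- stats::setNames(p, labels)
    best <- max(best, mean(map[pred] == truth))
  }
  best
}

# permutation-calibrated chi-square independence p-value of composition vs
# type (the naive chi-square null is invalid under Dirichlet-multinomial
# overdispersion)
perm_chisq_p <- function(otu, type, B = 99, seed = 1) {
  set.seed(seed)
  stat <- function(ty) {
    tab <- rowsum(otu, ty)
    suppressWarnings(stats::chisq.test(tab)$statistic)
  }
  obs <- stat(type)
  null <- replicate(B, stat(sample(type)))
  (1 + sum(null >= obs)) / (B + 1)
}

# quick metadata builder with valid defaults
make_meta <- function(lat, lon, date = "2019-06", seafloor = 4000,
                      ids = sprintf("s%02d", seq_along(lat))) {
  data.frame(sample_id = ids, latitude = lat, longitude = lon,
             date = date, sampling_depth_m = 5,
             seafloor_depth_m = seafloor, size_fraction = ">0.8",
             stringsAsFactors = FALSE)
}

# a small strong-signal world reused by several tests
strong_world <- function(seed, n = 150, K = 3) {
  generate_world(world_config(
    n_samples = n, n_otus_per_module = 8, n_modules = K,
    n_noise_otus = 10, read_depth = 3000, gradient_strength = 15,
    seed = seed))
}

# full chain world -> clr -> network -> modules -> ES -> types
type_chain <- function(world, max_conditioning = 2) {
  clr <- clr_transform(world$otu)
  net <- infer_network(clr, alpha = 0.05, max_conditioning = max_conditioning)
  part <- suppressWarnings(detect_modules(net, "louvain", seed = 1))
  es <- suppressWarnings(edge_satisfaction(net, part, node_weights(clr)))
  list(clr = clr, net = net, part = part, es = es,
       labels = assign_types(es))
}
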