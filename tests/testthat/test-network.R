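test_that("co_network enforces its invariants", {
  e <- data.frame(u = "a", v = "a", weight = 0.5)
  expect_error(co_network(e), "self-loops")
  expect_error(co_network(data.frame(u = "a", v = "b", weight = -0.1)),
               "strictly positive")
  expect_error(co_network(data.frame(u = "a", v = "b", weight = 1.2)),
               "<= 1")
  net <- co_network(data.frame(u = c("b", "a"), v = c("a", "c"),
                               weight = c(0.3, 0.7)))
  expect_identical(net$edges$u, c("a", "a"))       # canonicalized u < v
})

test_that("modularity matches frozen brute-force values", {
  # two disjoint unit-weight edges
  net <- co_network(data.frame(u = c("a", "c"), v = c("b", "d"),
                               weight = c(1, 1)))
  one <- setNames(rep(1L, 4), c("a", "b", "c", "d"))
  expect_equal(modularity_q(net, one), 0)
  per_edge <- setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  expect_equal(modularity_q(net, per_edge), 0.5)
  # pairing nodes ACROSS the two edges: brute-force oracle gives -0.5
  across <- setNames(c(1L, 2L, 1L, 2L), c("a", "b", "c", "d"))
  expect_equal(brute_modularity(net, across), -0.5)
  expect_equal(modularity_q(net, across), -0.5)
  # empty network errors
  expect_error(modularity_q(co_network(data.frame(u = "a", v = "b",
                                                  weight = 1)[0, ],
                                       nodes = c("a", "b")), one),
               "S = 0")
})

test_that("ordered-pair and per-module aggregate forms of Q agree", {
  for (s in 1:10) {
    net <- random_weighted_net(7, 0.5, seed = s)
    set.seed(s)
    memb <- setNames(sample(1:3, 7, replace = TRUE), net$nodes)
    # per-module aggregate: sum_M [ w_in/S - (K_M / 2S)^2 ]
    s_tot <- sum(net$edges$weight)
    k <- vapply(net$nodes, function(a)
      sum(net$edges$weight[net$edges$u == a | net$edges$v == a]), numeric(1))
    q2 <- sum(vapply(unique(memb), function(m) {
      inside <- memb[net$edges$u] == m & memb[net$edges$v] == m
      sum(net$edges$weight[inside]) / s_tot -
        (sum(k[memb == m]) / (2 * s_tot))^2
    }, numeric(1)))
    expect_equal(modularity_q(net, memb), q2, tolerance = 1e-9)
  }
})

test_that("network inference screens off indirect associations", {
  set.seed(42)
  n <- 300
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.3)
  z <- y + rnorm(n, sd = 0.3)
  clr <- cbind(X = x, Y = y, Z = z)
  net <- infer_network(clr, alpha = 0.05, max_conditioning = 1)
  key <- paste(net$edges$u, net$edges$v)
  expect_true("X Y" %in% key)
  expect_true("Y Z" %in% key)
  expect_false("X Z" %in% key)                    # screened off by Y
})

test_that("edge weights are clipped into (0, 1] and negatives discarded", {
  set.seed(1)
  a <- rnorm(100)
  clr <- cbind(A = a, B = a, C = rnorm(100))      # duplicated column
  net <- infer_network(clr, 0.05, 0)
  expect_true(all(net$edges$weight > 0 & net$edges$weight <= 1))
  expect_true("A B" %in% paste(net$edges$u, net$edges$v))
  # anti-correlated pair yields no edge
  clr2 <- cbind(A = a, B = -a + rnorm(100, sd = 0.1), C = rnorm(100))
  net2 <- infer_network(clr2, 0.05, 0)
  expect_false("A B" %in% paste(net2$edges$u, net2$edges$v))
})

test_that("inference is invariant to OTU column order", {
  w <- strong_world(4, n = 100)
  clr <- clr_transform(w$otu)
  set.seed(7)
  perm <- sample(ncol(clr))
  n1 <- infer_network(clr, 0.05, 2)
  n2 <- infer_network(clr[, perm], 0.05, 2)
  key <- function(net) paste(net$edges$u, net$edges$v)
  expect_setequal(key(n1), key(n2))
  m <- match(key(n2), key(n1))
  expect_equal(n1$edges$weight[m], n2$edges$weight, tolerance = 1e-12)
})

test_that("constant columns are excluded with a warning", {
  set.seed(2)
  clr <- cbind(A = rnorm(50), B = rnorm(50), C = rnorm(50), D = rep(1, 50))
  expect_warning(net <- infer_network(clr, 0.05, 1), "constant")
  expect_false("D" %in% net$nodes)
})

test_that("module detection separates ideal and planted structure", {
  # two disjoint 4-cliques
  cl <- function(ids) {
    e <- t(combn(ids, 2))
    data.frame(u = e[, 1], v = e[, 2], weight = 1)
  }
  net <- co_network(rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4))))
  part <- detect_modules(net, "louvain", seed = 1)
  expect_equal(length(part$sizes), 2L)
  expect_equal(length(unique(part$membership[paste0("a", 1:4)])), 1L)
  expect_equal(length(unique(part$membership[paste0("b", 1:4)])), 1L)

  # planted partition, 6 blocks
  pp <- planted_partition_net(6, 6, seed = 3)
  det <- detect_modules(pp$net, "louvain", seed = 1)
  expect_gte(adjusted_rand_index(det$membership[names(pp$planting)],
                                 pp$planting), 0.9)

  # determinism and algorithm validation
  expect_identical(detect_modules(pp$net, "louvain", seed = 5)$membership,
                   detect_modules(pp$net, "louvain", seed = 5)$membership)
  expect_error(detect_modules(pp$net, "nope"), "unknown algorithm")

  # a second algorithm is available and returns a valid partition
  lp <- detect_modules(pp$net, "label_prop", seed = 1)
  expect_true(all(names(pp$planting) %in% names(lp$membership)))
})

test_that("detected partitions attain the enumerated optimum on toys", {
  for (s in 1:4) {
    set.seed(s)
    # two 3-cliques joined by a weak bridge: clear optimum at 6 nodes
    e <- rbind(t(combn(paste0("x", 1:3), 2)), t(combn(paste0("y", 1:3), 2)))
    e <- data.frame(u = e[, 1], v = e[, 2],
                    weight = runif(6, 0.6, 1))
    e <- rbind(e, data.frame(u = "x3", v = "y1", weight = 0.1))
    net <- co_network(e)
    det <- detect_modules(net, "louvain", seed = 1)
    best <- max(vapply(all_partitions(6), function(p)
      modularity_q(net, setNames(p, net$nodes)), numeric(1)))
    expect_equal(det$Q, best, tolerance = 1e-9)
  }
})

test_that("partition selection prefers high Q subject to the size floor", {
  fake <- function(q, sizes) {
    structure(list(membership = NULL, Q = q, algorithm = "fake",
                   sizes = sizes), class = "module_partition")
  }
  a <- fake(0.40, c(5, 5)); b <- fake(0.55, c(6, 4))
  expect_equal(select_partition(list(a, b), 3)$Q, 0.55)
  expect_equal(select_partition(list(a), 3)$Q, 0.40)
  c1 <- fake(0.60, c(8, 1))                        # vetoed by size floor
  expect_equal(select_partition(list(a, c1), 3)$Q, 0.40)
  expect_warning(sel <- select_partition(list(c1), 3), "size check")
  expect_equal(sel$Q, 0.60)
  expect_error(select_partition(list()), "no candidate")
})

test_that("module ids are renumbered by descending size", {
  pp <- planted_partition_net(3, c(4), seed = 2)
  det <- detect_modules(pp$net, "louvain", seed = 1)
  expect_true(all(diff(det$sizes) <= 0))
  expect_identical(sort(unique(det$membership)),
                   seq_along(det$sizes))
})
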