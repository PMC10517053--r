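test_that("position encoding respects longitude circularity", {
  expect_equal(unname(encode_position(10, 0)), cbind(10, 0, 1))
  expect_equal(unname(encode_position(0, 90)), cbind(0, 1, 0))
  expect_equal(encode_position(5, 180), encode_position(5, -180))
  expect_equal(unname(encode_position(0, 180))[2], 0, tolerance = 1e-12)
  expect_equal(unname(encode_position(0, 180))[3], -1)
})

test_that("standardization is learned on fit rows only", {
  x <- matrix(c(1, 2, 3, 10), 4, 1, dimnames = list(NULL, "f"))
  std <- standardize_features(x, fit_rows = 1:3)
  expect_equal(mean(std$x[1:3, ]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(std$x[1:3, ]^2)), 1, tolerance = 1e-9)  # pop. sd
  expect_equal(std$means[["f"]], 2)
  # held-out value equal to the fit mean maps to 0
  x2 <- rbind(x[1:3, , drop = FALSE], f = 2)
  expect_equal(unname(standardize_features(x2, 1:3)$x[4, 1]), 0)
  # constant column
  xc <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(stdc <- standardize_features(xc), "constant feature")
  expect_equal(unname(stdc$x[, "b"]), rep(0, 3))
})

test_that("training handles grids, degenerate classes and probabilities", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 20)
  m <- train_classifier(x, y, "linear", hyper_grid = data.frame(C = 1))
  expect_identical(m$hyper$C, 1)                   # one-setting grid chosen
  expect_equal(mean(predict(m, x, type = "class") == y), 1)   # separable
  pr <- predict(m, x)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  expect_error(train_classifier(x[c(1, 21:25), ], y[c(1, 21:25)], "linear"),
               "class 'a' has fewer than 2")
  # full grid search runs and records per-setting accuracy
  mg <- train_classifier(x, y, "linear", inner_folds = 3, seed = 2)
  expect_length(mg$grid_accuracy, 5L)
  expect_false(anyNA(mg$grid_accuracy))
  # all three algorithms fit and predict
  for (alg in c("knn", "nbayes")) {
    ma <- train_classifier(x, y, alg)
    expect_true(all(abs(rowSums(predict(ma, x)) - 1) < 1e-9))
  }
  expect_error(train_classifier(x, y, "svm9000"), "unknown algorithm")
})

test_that("noise features give chance-level LOO accuracy", {
  accs <- vapply(1:8, function(s) {
    set.seed(s)
    x <- matrix(rnorm(36 * 2), 36, 2, dimnames = list(NULL, c("f1", "f2")))
    y <- rep(1:3, each = 12)
    loo_cv(x, y, "nbayes")$accuracy
  }, numeric(1))
  # binomial null: mean 1/3, sd of the mean over 8 x 36 trials
  se <- sqrt((1 / 3) * (2 / 3) / (8 * 36))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 0.02)
})

test_that("LOO returns complete, perfectly-scored predictions when separable", {
  set.seed(3)
  x <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 8, 0.3), 15, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("lo", "hi"), each = 15)
  cv <- loo_cv(x, y, "linear", hyper_grid = data.frame(C = 1))
  expect_equal(nrow(cv$per_sample), 30L)
  expect_false(anyNA(cv$prob))
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$micro_auc, 1)
  expect_equal(sum(cv$confusion), 30)
  expect_equal(sum(diag(cv$confusion)), 30)
})

test_that("LOO folds reproduce standalone training on the remaining rows", {
  # nested-CV discipline: fold i's model must equal a model trained on all
  # rows but i (standardization and fit both refit without row i)
  set.seed(4)
  x <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("p", "q"), 10)
  cv <- loo_cv(x, y, "nbayes")
  for (i in c(1, 7, 20)) {
    m <- train_classifier(x[-i, ], y[-i], "nbayes")
    expect_equal(unname(cv$prob[i, ]),
                 unname(predict(m, x[i, , drop = FALSE])[1, ]),
                 tolerance = 1e-9)
  }
})

test_that("buffered CV excludes training samples inside the radius", {
  # test point at (0,0); neighbors at ~1113 km and ~3337 km
  lat <- c(0, 0, 0, 0); lon <- c(0, 10, 30, 60)
  # closed-form arc lengths: ~1112 km and ~3336 km on the 6371 km sphere
  expect_equal(haversine_km(0, 0, 0, 10), 6371 * pi / 18, tolerance = 1e-9)
  expect_equal(haversine_km(0, 0, 0, 30), 6371 * pi / 6, tolerance = 1e-9)
  x <- cbind(f1 = c(0, 1, 10, 11), f2 = c(0, 1, 10, 11))
  y <- c("a", "a", "b", "b")
  # with a 2000 km buffer, sample 2 is excluded from fold 1: training for
  # fold 1 = {3, 4}, a single-class set -> predicted "b" with prob 1
  expect_warning(
    b <- buffered_cv(x, y, cbind(lat, lon), 2000, "knn",
                     hyper_grid = data.frame(k = 1)),
    "single training class")
  expect_equal(unname(b$prob[1, ]), c(0, 1))
  # without the buffer sample 1 is classed correctly from its 1-NN (row 2)
  l <- loo_cv(x, y, "knn", hyper_grid = data.frame(k = 1))
  expect_equal(unname(which.max(l$prob[1, ])), 1L)
  # radius 0 reproduces LOO exactly
  b0 <- buffered_cv(x, y, cbind(lat, lon), 0, "knn",
                    hyper_grid = data.frame(k = 1))
  expect_identical(b0$prob, l$prob)
})

test_that("empty buffered training sets are skipped and reported", {
  lat <- c(0, 0.5, -0.5); lon <- c(0, 0.5, -0.5)    # all within ~80 km
  x <- cbind(f1 = rnorm(3), f2 = rnorm(3))
  y <- c("a", "b", "a")
  expect_warning(b <- buffered_cv(x, y, cbind(lat, lon), 2000, "nbayes"),
                 "skipped")
  expect_equal(b$n_skipped, 3L)
  expect_true(is.na(b$accuracy))
  expect_true(all(b$per_sample$skipped))
})

test_that("micro ROC-AUC agrees with a brute-force ranking oracle", {
  prob <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7))
  colnames(prob) <- c("a", "b")
  labels <- c("a", "b", "b")
  # oracle: all (positive, negative) pairs in the pooled one-vs-rest setting
  y <- as.vector(outer(labels, colnames(prob), "=="))
  s <- as.vector(prob)
  pairs <- expand.grid(p = which(y), n = which(!y))
  oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                        ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(micro_roc_auc(prob, labels), oracle)
  # perfect and uniform probabilities
  perf <- rbind(c(1, 0), c(0, 1)); colnames(perf) <- c("a", "b")
  expect_equal(micro_roc_auc(perf, c("a", "b")), 1)
  unif <- matrix(0.5, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(micro_roc_auc(unif, c("a", "b", "a", "b")), 0.5)
  expect_error(micro_roc_auc(perf, c("a", "a")), "single observed class")
})

test_that("threshold selection maximizes micro F1 with smallest-tie rule", {
  prob <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.3, 0.7))
  colnames(prob) <- c("a", "b")
  labels <- c("a", "a", "b", "b")
  # any threshold in (0.3, 0.7] is perfect; smallest grid point wins
  expect_equal(select_threshold(prob, labels, grid = seq(0.05, 0.95, 0.05)),
               0.35)
  expect_equal(select_threshold(prob, labels, grid = 0.5), 0.5)
  # matches an exhaustive F1 sweep on a calibrated 3-class case
  set.seed(5)
  p3 <- matrix(runif(60), 20, 3)
  p3 <- p3 / rowSums(p3)
  colnames(p3) <- c("1", "2", "3")
  l3 <- colnames(p3)[max.col(p3)]
  grid <- seq(0.01, 0.99, by = 0.01)
  f1 <- vapply(grid, function(t) {
    pred <- p3 >= t
    truth <- outer(l3, colnames(p3), "==")
    tp <- sum(pred & truth)
    2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
  }, numeric(1))
  expect_equal(select_threshold(p3, l3, grid), grid[which.max(f1)])
})

test_that("permutation importance isolates the informative feature", {
  set.seed(6)
  n <- 80
  sig <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  x <- cbind(signal = sig, noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c("a", "b"), each = n / 2)
  m <- train_classifier(x, y, "nbayes")
  imp <- permutation_importance(m, x, y, n_repeats = 10, seed = 1)
  expect_identical(names(which.max(imp)), "signal")
  expect_lt(abs(imp[["noise1"]]), 0.1)
  expect_gt(imp[["signal"]], 5 * max(abs(imp[c("noise1", "noise2")])))
})

test_that("feature subsets run from configuration alone", {
  w <- generate_world(world_config(n_samples = 60, n_modules = 3,
                                   gradient_strength = 10, seed = 8))
  y <- factor(w$truth$sample_type)
  for (fs in c("all17", "sst", "chl_a", "sst_chl", "env7", "position")) {
    x <- planktotype:::feature_subset(w$features, w$meta, fs)
    m <- train_classifier(x, y, "nbayes")
    expect_equal(nrow(predict(m, x)), 60L)
  }
  expect_error(planktotype:::feature_subset(w$features, w$meta, "bogus"),
               "unknown feature_set")
})
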