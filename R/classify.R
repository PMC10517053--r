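#' Encode a position as (latitude, sin longitude, cos longitude)
#'
#' Longitude is circular (-180 and 180 degrees coincide), so it enters the
#' feature set through its sine and cosine.
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @return Matrix with columns `lat`, `sin_lon`, `cos_lon`.
#' @export
encode_position <- function(lat, lon) {
  rad <- lon * pi / 180
  cbind(lat = lat, sin_lon = sin(rad), cos_lon = cos(rad))
}

#' Standardize features to zero mean and unit variance
#'
#' Means and (population) standard deviations are learned on `fit_rows` only
#' and applied to all rows, so held-out rows never influence their own
#' transform. Constant columns are centered, get sd 1, and raise a warning.
#'
#' @param x Numeric feature matrix.
#' @param fit_rows Row indices on which to learn the transform (default all).
#' @return List with `x` (transformed matrix), `means`, `sds`.
#' @export
standardize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  x <- as.matrix(x)
  xf <- x[fit_rows, , drop = FALSE]
  means <- colMeans(xf)
  sds <- sqrt(colMeans(sweep(xf, 2L, means)^2))
  if (any(sds == 0)) {
    warning("constant feature column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; left centered with sd set to 1")
    sds[sds == 0] <- 1
  }
  list(x = sweep(sweep(x, 2L, means), 2L, sds, `/`), means = means, sds = sds)
}

# internal: stratified fold assignment, round-robin within each class after a
# seeded shuffle; classes smaller than k simply occupy fewer folds
stratified_folds <- function(labels, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# internal fitters ----------------------------------------------------------

# linear decision rule with an L2 penalty C: multinomial (or binomial)
# ridge-penalized logistic regression, lambda = 1/(n*C). Native class
# probabilities; data are standardized upstream.
fit_linear <- function(x, y, C) {
  n <- nrow(x)
  lam <- 1 / (n * C)
  pad <- ncol(x) < 2L
  if (pad) x <- cbind(x, `.pad` = 0)
  y <- droplevels(y)
  singles <- names(which(table(y) == 1L))     # glmnet needs >= 2 per class
  if (length(singles)) {
    dup <- which(as.character(y) %in% singles)
    x <- rbind(x, x[dup, , drop = FALSE])
    y <- factor(c(as.character(y), as.character(y)[dup]), levels = levels(y))
  }
  classes <- levels(droplevels(y))
  fam <- if (length(classes) == 2L) "binomial" else "multinomial"
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = fam, alpha = 0,
                   lambda = sort(unique(lam * c(100, 10, 1)),
                                 decreasing = TRUE),
                   standardize = FALSE),
    warning = function(w) {
      # small multinomial classes are routine inside LOO folds
      if (grepl("dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(kind = "linear", fit = fit, lambda = lam, classes = classes, pad = pad)
}

predict_fit_linear <- function(model, x) {
  if (model$pad) x <- cbind(x, `.pad` = 0)
  pr <- stats::predict(model$fit, newx = x, s = model$lambda,
                       type = "response")
  if (length(model$classes) == 2L) {
    p2 <- as.vector(pr)
    out <- cbind(1 - p2, p2)
  } else {
    out <- pr[, , 1L]
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  }
  colnames(out) <- model$classes
  out
}

fit_knn <- function(x, y, k) {
  list(kind = "knn", x = x, y = droplevels(y), k = k,
       classes = levels(droplevels(y)))
}

predict_fit_knn <- function(model, x) {
  k <- min(model$k, nrow(model$x))
  out <- matrix(0, nrow(x), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (i in seq_len(nrow(x))) {
    d2 <- colSums((t(model$x) - x[i, ])^2)
    nb <- order(d2)[seq_len(k)]
    tab <- table(factor(model$y[nb], levels = model$classes))
    out[i, ] <- as.numeric(tab) / k
  }
  out
}

# Gaussian naive Bayes with variance smoothing
fit_nbayes <- function(x, y, eps = 1e-9) {
  y <- droplevels(y)
  classes <- levels(y)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  va <- do.call(rbind, lapply(classes, function(cl)
    apply(x[y == cl, , drop = FALSE], 2L, stats::var)))
  va[is.na(va)] <- 0
  va <- va + eps * max(va, 1e-12)
  prior <- as.numeric(table(y)) / length(y)
  list(kind = "nbayes", mu = mu, va = va, prior = prior, classes = classes)
}

predict_fit_nbayes <- function(model, x) {
  ll <- vapply(seq_along(model$classes), function(j) {
    rowSums(sweep(-0.5 * sweep(x, 2L, model$mu[j, ])^2, 2L,
                  model$va[j, ], `/`) -
              0.5 * matrix(log(2 * pi * model$va[j, ]), nrow(x),
                           ncol(x), byrow = TRUE)) + log(model$prior[j])
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  ll <- ll - apply(ll, 1L, max)
  pr <- exp(ll)
  pr <- pr / rowSums(pr)
  colnames(pr) <- model$classes
  pr
}

fit_by_algorithm <- function(algorithm, x, y, hyper) {
  switch(algorithm,
         linear = fit_linear(x, y, C = hyper$C),
         knn = fit_knn(x, y, k = hyper$k),
         nbayes = fit_nbayes(x, y, eps = hyper$eps),
         stop("unknown algorithm '", algorithm, "'"))
}

predict_fit <- function(model, x) {
  switch(model$kind,
         linear = predict_fit_linear(model, x),
         knn = predict_fit_knn(model, x),
         nbayes = predict_fit_nbayes(model, x))
}

#' Default hyperparameter grid per algorithm
#'
#' The linear grid spans C in {0.01, 0.1, 1, 10, 100} so the reference
#' study's selected C = 1.0 is reachable by the exhaustive search.
#'
#' @param algorithm `"linear"`, `"knn"` or `"nbayes"`.
#' @return `data.frame`, one row per hyperparameter setting.
#' @export
default_hyper_grid <- function(algorithm) {
  switch(algorithm,
         linear = data.frame(C = c(0.01, 0.1, 1, 10, 100)),
         knn = data.frame(k = c(1L, 3L, 5L, 7L, 9L)),
         nbayes = data.frame(eps = 1e-9),
         stop("unknown algorithm '", algorithm, "'"))
}

#' Train a community-type classifier with exhaustive grid search
#'
#' Standardizes the features, runs an exhaustive search over `hyper_grid`
#' with stratified `inner_folds`-fold cross-validation (selection metric:
#' accuracy; ties resolved toward the first grid row), then refits the
#' winning setting on all rows. Supported algorithms: `"linear"` (L2-penalized
#' linear decision rule with penalty parameter C), `"knn"` (k-nearest
#' neighbors, probabilities = neighbor vote shares) and `"nbayes"` (Gaussian
#' naive Bayes).
#'
#' @param features Numeric matrix / data.frame, samples x features.
#' @param labels Class labels (factor or coercible); every class needs at
#'   least 2 members.
#' @param algorithm Algorithm name.
#' @param hyper_grid `data.frame` grid (default [default_hyper_grid()]);
#'   a single-row grid skips the inner CV.
#' @param inner_folds Folds of the inner grid-search CV (default 5).
#' @param seed Integer seed (fold assignment).
#' @return Object of class `trained_classifier` carrying the standardization
#'   constants, fitted rule, class ids, chosen hyperparameters and a
#'   probability threshold (default 0.5 until [select_threshold()] is
#'   applied).
#' @export
train_classifier <- function(features, labels, algorithm = "linear",
                             hyper_grid = default_hyper_grid(algorithm),
                             inner_folds = 5L, seed = 1L) {
  x <- as.matrix(features)
  y <- factor(labels)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("class '", names(counts)[which(counts < 2L)[1L]],
         "' has fewer than 2 members")
  }
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  std <- standardize_features(x)

  best <- 1L
  cv_acc <- rep(NA_real_, nrow(hyper_grid))
  if (nrow(hyper_grid) > 1L) {
    k <- max(2L, min(inner_folds, min(counts)))
    fold <- stratified_folds(y, k, seed)
    for (h in seq_len(nrow(hyper_grid))) {
      hit <- 0L; tot <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f; te <- !tr
        if (!any(te) || nlevels(droplevels(y[tr])) < 2L) next
        fit <- fit_by_algorithm(algorithm, std$x[tr, , drop = FALSE],
                                y[tr], as.list(hyper_grid[h, , drop = FALSE]))
        pr <- predict_fit(fit, std$x[te, , drop = FALSE])
        pred <- colnames(pr)[max.col(pr, ties.method = "first")]
        hit <- hit + sum(pred == as.character(y[te]))
        tot <- tot + sum(te)
      }
      cv_acc[h] <- hit / tot
    }
    best <- which.max(cv_acc)
  }
  hyper <- as.list(hyper_grid[best, , drop = FALSE])
  fit <- fit_by_algorithm(algorithm, std$x, y, hyper)
  structure(list(algorithm = algorithm,
                 means = std$means, sds = std$sds,
                 fit = fit, classes = levels(y),
                 hyper = hyper, grid_accuracy = cv_acc,
                 feature_names = colnames(x),
                 probability_threshold = 0.5),
            class = "trained_classifier")
}

#' Predict community types or probabilities
#'
#' @param object A `trained_classifier`.
#' @param newdata Feature matrix / data.frame with the training columns.
#' @param type `"prob"` (default) for the class-probability matrix (rows sum
#'   to 1) or `"class"` for argmax labels.
#' @param ... Unused.
#' @export
predict.trained_classifier <- function(object, newdata,
                                       type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(x))
    if (length(missing)) {
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  x <- sweep(sweep(x, 2L, object$means), 2L, object$sds, `/`)
  pr <- predict_fit(object$fit, x)
  full <- matrix(0, nrow(pr), length(object$classes),
                 dimnames = list(rownames(newdata), object$classes))
  full[, colnames(pr)] <- pr
  if (type == "prob") full else
    object$classes[max.col(full, ties.method = "first")]
}

#' Print a trained_classifier summary
#'
#' @param x Object.
#' @param ... Unused.
#' @return The object, invisibly.
#' @method print trained_classifier
#' @export
print.trained_classifier <- function(x, ...) {
  cat("trained_classifier:", x$algorithm, "|",
      length(x$classes), "classes |",
      paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
      "| threshold", x$probability_threshold, "\n")
  invisible(x)
}

#' Micro-averaged one-vs-rest ROC-AUC
#'
#' Pools the one-vs-rest (class, sample) indicator/probability pairs across
#' all classes and computes the area under the pooled ROC curve
#' (rank/Mann-Whitney form, equivalent to the trapezoidal area with tied
#' scores grouped).
#'
#' @param prob Samples x classes probability matrix (rows sum to 1), columns
#'   named by class.
#' @param labels True labels.
#' @return AUC in `[0, 1]`.
#' @export
micro_roc_auc <- function(prob, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("micro ROC-AUC undefined with a single observed class")
  }
  ind <- outer(labels, colnames(prob), "==")
  y <- as.vector(ind)
  s <- as.vector(prob)
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(s)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal CV engine shared by loo_cv and buffered_cv
spatial_cv <- function(features, labels, coords = NULL, radius_km = 0,
                       algorithm = "linear",
                       hyper_grid = default_hyper_grid(algorithm),
                       inner_folds = 5L, seed = 1L) {
  x <- as.matrix(features)
  y <- factor(labels)
  n <- nrow(x)
  if (n < 3L) stop("need >= 3 samples")
  if (radius_km > 0 && is.null(coords)) {
    stop("coordinates required for a positive buffer radius")
  }
  classes <- levels(y)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(x), classes))
  skipped <- logical(n)
  single_class_folds <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (radius_km > 0) {
      d <- haversine_km(coords[i, 1L], coords[i, 2L],
                        coords[tr, 1L], coords[tr, 2L])
      tr <- tr[d >= radius_km]
    }
    if (length(tr) == 0L) {
      skipped[i] <- TRUE
      next
    }
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L) {
      single_class_folds <- single_class_folds + 1L
      prob[i, as.character(levels(ytr))] <- 1
      prob[i, is.na(prob[i, ])] <- 0
      next
    }
    std <- suppressWarnings(standardize_features(x, fit_rows = tr))
    best <- 1L
    if (nrow(hyper_grid) > 1L) {
      k <- max(2L, min(inner_folds, min(table(ytr))))
      fold <- stratified_folds(as.character(y[tr]), k, seed_stream(seed, i))
      acc <- numeric(nrow(hyper_grid))
      for (h in seq_len(nrow(hyper_grid))) {
        hit <- 0L; tot <- 0L
        for (f in seq_len(k)) {
          itr <- tr[fold != f]; ite <- tr[fold == f]
          if (!length(ite) || nlevels(droplevels(y[itr])) < 2L) next
          fit <- fit_by_algorithm(algorithm, std$x[itr, , drop = FALSE],
                                  y[itr],
                                  as.list(hyper_grid[h, , drop = FALSE]))
          pr <- predict_fit(fit, std$x[ite, , drop = FALSE])
          pred <- colnames(pr)[max.col(pr, ties.method = "first")]
          hit <- hit + sum(pred == as.character(y[ite]))
          tot <- tot + length(ite)
        }
        acc[h] <- if (tot > 0L) hit / tot else 0
      }
      best <- which.max(acc)
    }
    fit <- fit_by_algorithm(algorithm, std$x[tr, , drop = FALSE], y[tr],
                            as.list(hyper_grid[best, , drop = FALSE]))
    pr <- predict_fit(fit, std$x[i, , drop = FALSE])
    prob[i, colnames(pr)] <- pr
    prob[i, is.na(prob[i, ])] <- 0
  }
  if (any(skipped)) {
    warning(sum(skipped), " sample(s) skipped: empty buffered training set")
  }
  if (single_class_folds > 0L) {
    warning(single_class_folds,
            " fold(s) had a single training class; predicted as that class")
  }
  eval_idx <- which(!skipped)
  pred <- rep(NA_character_, n)
  pred[eval_idx] <- classes[max.col(prob[eval_idx, , drop = FALSE],
                                    ties.method = "first")]
  truth <- as.character(y)
  confusion <- table(factor(truth[eval_idx], levels = classes),
                     factor(pred[eval_idx], levels = classes))
  auc <- if (length(unique(truth[eval_idx])) >= 2L) {
    micro_roc_auc(prob[eval_idx, , drop = FALSE], truth[eval_idx])
  } else {
    NA_real_                       # undefined when < 2 classes evaluated
  }
  structure(list(
    per_sample = data.frame(sample_id = rownames(x) %||%
                              as.character(seq_len(n)),
                            truth = truth, predicted = pred,
                            skipped = skipped, stringsAsFactors = FALSE),
    prob = prob,
    accuracy = if (length(eval_idx)) mean(pred[eval_idx] == truth[eval_idx])
               else NA_real_,
    micro_auc = auc,
    confusion = confusion,
    n_skipped = sum(skipped)),
    class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a classifier trained — with nested
#' standardization and grid search — on all other samples.
#'
#' @inheritParams train_classifier
#' @return Object of class `cv_result`: per-sample predictions, probability
#'   matrix, accuracy, micro-average ROC-AUC ([micro_roc_auc()]) and the
#'   K x K confusion matrix.
#' @export
loo_cv <- function(features, labels, algorithm = "linear",
                   hyper_grid = default_hyper_grid(algorithm),
                   inner_folds = 5L, seed = 1L) {
  spatial_cv(features, labels, coords = NULL, radius_km = 0,
             algorithm = algorithm, hyper_grid = hyper_grid,
             inner_folds = inner_folds, seed = seed)
}

#' Spatially buffered cross-validation
#'
#' Leave-one-out in which, for each test sample, all training samples lying
#' within `radius_km` great-circle kilometres of it are additionally
#' excluded, controlling leakage through spatial autocorrelation. The
#' reference buffer is 2000 km. Folds whose training set becomes empty are
#' skipped, counted and excluded from the accuracy denominator; a radius of
#' 0 reproduces [loo_cv()] exactly.
#'
#' @inheritParams train_classifier
#' @param coords Two-column matrix of (latitude, longitude) degrees.
#' @param radius_km Buffer radius in km.
#' @return A `cv_result` (see [loo_cv()]) with `n_skipped` filled in.
#' @export
buffered_cv <- function(features, labels, coords, radius_km = 2000,
                        algorithm = "linear",
                        hyper_grid = default_hyper_grid(algorithm),
                        inner_folds = 5L, seed = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(as.matrix(features))) {
    stop("coords must have one row per sample")
  }
  spatial_cv(features, labels, coords = coords, radius_km = radius_km,
             algorithm = algorithm, hyper_grid = hyper_grid,
             inner_folds = inner_folds, seed = seed)
}

#' Print a cv_result summary
#'
#' @param x Object.
#' @param ... Unused.
#' @return The object, invisibly.
#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: accuracy", round(x$accuracy, 3),
      "| micro ROC-AUC", round(x$micro_auc, 3),
      "|", x$n_skipped, "skipped\n")
  invisible(x)
}

#' Choose the probability threshold maximizing micro-averaged F1
#'
#' Sweeps a threshold grid over the rule "predict every class whose
#' probability is at least the threshold" and returns the grid value with
#' the highest micro-averaged one-vs-rest F1 (pooled TP/FP/FN); ties go to
#' the smallest threshold. Applied to cross-validated probabilities this is
#' the rule that selected 0.28 in the reference study.
#'
#' @param prob Samples x classes probability matrix.
#' @param labels True labels.
#' @param grid Candidate thresholds in (0, 1); default 0.01..0.99 by 0.01.
#' @return The selected threshold.
#' @export
select_threshold <- function(prob, labels,
                             grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(grid) >= 1L, all(grid > 0 & grid < 1))
  grid <- sort(grid)
  truth <- outer(as.character(labels), colnames(prob), "==")
  f1 <- vapply(grid, function(t) {
    pred <- prob >= t
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  grid[which.max(f1)]
}

#' Permutation importance of each feature
#'
#' For every feature, the column is randomly permuted `n_repeats` times and
#' the mean decrease of micro-average ROC-AUC relative to the unpermuted
#' baseline is reported. A feature carrying no information scores ~0; the
#' most informative features score highest.
#'
#' @param model A `trained_classifier`.
#' @param features Feature matrix on the model's columns.
#' @param labels True labels.
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return Named numeric vector, one AUC decrease per feature.
#' @export
permutation_importance <- function(model, features, labels, n_repeats = 10L,
                                   seed = 1L) {
  x <- as.matrix(features)
  baseline <- micro_roc_auc(predict(model, x), labels)
  out <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    set.seed(seed_stream(seed, j))
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      baseline - micro_roc_auc(predict(model, xp), labels)
    }, numeric(1L))
    out[j] <- mean(drops)
  }
  out
}
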