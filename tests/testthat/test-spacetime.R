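test_that("block-center downsampling selects, never interpolates", {
  g <- generate_grid_series(1, c(24, 24), seed = 1)
  d <- downsample_grid(g, 12)
  expect_length(d$lat, 2L)
  expect_length(d$lon, 2L)
  # kept cells sit at zero-based block-local index (6, 6)
  expect_equal(d$lat, g$lat[c(7, 19)])
  expect_equal(d$data$sst[1, , ], g$data$sst[1, c(7, 19), c(7, 19)])
  # factor 1 is the identity
  id <- downsample_grid(g, 1)
  expect_identical(id$data$sst, g$data$sst)
  expect_error(downsample_grid(downsample_grid(g, 12), 12), "smaller")
})

test_that("map prediction applies threshold-set and argmax semantics", {
  w <- generate_world(world_config(n_samples = 100, n_modules = 3,
                                   gradient_strength = 10, seed = 6))
  x <- as.matrix(w$features[, satellite_feature_names()])
  m <- train_classifier(x, factor(w$truth$sample_type), "linear",
                        hyper_grid = data.frame(C = 1))
  m$probability_threshold <- 0.28
  g <- generate_grid_series(1, c(12, 12), missing_rate = 0.15, seed = 2)
  pred <- predict_map(m, g)
  expect_equal(nrow(pred), 12 * 12 * 12)

  pcols <- as.matrix(pred[, paste0("prob_", m$classes)])
  ok <- !pred$missing
  # predicted set = classes at or above the threshold
  sets <- strsplit(pred$types, ";", fixed = TRUE)
  for (i in which(ok)[1:200]) {
    expect_setequal(sets[[i]], m$classes[pcols[i, ] >= 0.28])
  }
  # argmax type is in the set whenever the set is nonempty; none-flag else
  nonempty <- ok & !pred$none
  expect_true(all(mapply(function(s, a) as.character(a) %in% s,
                         sets[nonempty], pred$argmax_type[nonempty])))
  expect_true(all(pred$types[pred$none] == ""))
  # masked cells carry the missing flag and no probabilities
  expect_true(all(is.na(pcols[pred$missing, ])))
  expect_gt(sum(pred$missing), 0)
  # feature-name mismatch is reported by name
  g2 <- g; g2$data$nflh <- NULL
  expect_error(predict_map(m, g2), "nflh")
})

test_that("cell areas follow the cosine-latitude rule", {
  # hand-built one-month prediction on a 2-cell grid at 0 and 60 degrees
  pred <- data.frame(time_index = 1L, year = 2003L, month = 1L,
                     lat = c(0, 60), lon = 0,
                     missing = FALSE, none = FALSE,
                     argmax_type = 1L, max_prob = 0.9,
                     types = c("1;2", "1"), stringsAsFactors = FALSE)
  attr(pred, "dlat") <- 1; attr(pred, "dlon") <- 1
  class(pred) <- c("grid_prediction", "data.frame")
  a <- area_series(pred)
  eq_area <- (pi * 6371 / 180)^2                    # 1x1 deg at the equator
  expect_equal(eq_area, 12364, tolerance = 1e-4)
  a1 <- a$area_km2[a$type == "1"]
  expect_equal(a1, eq_area * (1 + cos(pi / 3)), tolerance = 1e-9)
  # the multi-label cell contributes its full area to type 2 as well
  expect_equal(a$area_km2[a$type == "2"], eq_area, tolerance = 1e-9)
  # argmax mode counts each cell once
  a_arg <- area_series(pred, mode = "argmax")
  expect_true(!"2" %in% a_arg$type)
  expect_equal(sum(a_arg$area_km2), eq_area * 1.5, tolerance = 1e-9)
})

test_that("monthly area is conserved across types, none and missing", {
  w <- generate_world(world_config(n_samples = 80, n_modules = 3,
                                   gradient_strength = 10, seed = 3))
  x <- as.matrix(w$features[, satellite_feature_names()])
  m <- train_classifier(x, factor(w$truth$sample_type), "linear",
                        hyper_grid = data.frame(C = 1))
  m$probability_threshold <- 0.9           # force some none-flagged cells
  g <- generate_grid_series(1, c(10, 10), missing_rate = 0.2, seed = 9)
  pred <- predict_map(m, g)
  ar <- area_series(pred, mode = "argmax")
  total <- tapply(ar$area_km2, ar$time_index, sum)
  cell_area <- (pi * 6371 / 180)^2 *
    abs(diff(g$lat[1:2])) * abs(diff(g$lon[1:2])) * cos(g$lat * pi / 180)
  expect_equal(as.numeric(total),
               rep(sum(cell_area) * length(g$lon), 12),
               tolerance = 1e-9)
})

test_that("seasonal Mann-Kendall matches closed forms", {
  # strictly increasing 5-year monthly series: S = 12 * C(5,2) = 120,
  # Var = 12 * 5*4*15/18 (no ties)
  x <- seq_len(60)
  mk <- seasonal_mann_kendall(x, 12)
  expect_equal(mk$s, 120)
  expect_equal(mk$var_s, 12 * 5 * 4 * 15 / 18)
  expect_lt(mk$p_value, 0.05)
  expect_identical(mk$direction, "increasing")
  # reversal negates S exactly
  expect_equal(seasonal_mann_kendall(rev(x), 12)$s, -120)
  # constant series: p = 1, no direction
  mc <- seasonal_mann_kendall(rep(2, 48), 12)
  expect_equal(mc$p_value, 1)
  expect_identical(mc$direction, "none")
})

test_that("seasonal Sen slope is exact on linear + seasonal signals", {
  yrs <- rep(0:4, each = 12)
  cyc <- sin(2 * pi * (0:59) / 12)
  expect_equal(seasonal_sen_slope(0.5 * yrs, 12), 0.5)
  expect_equal(seasonal_sen_slope(0.5 * yrs + 3 * cyc, 12), 0.5)
  expect_equal(seasonal_sen_slope(rep(7, 36), 12), 0)
  expect_error(seasonal_sen_slope(1:11, 12), "fewer than 2")
  # pooled pairwise-slope enumeration oracle on a noisy series
  set.seed(2)
  x <- 0.3 * yrs + cyc + rnorm(60, sd = 0.2)
  slopes <- c()
  for (m in 1:12) {
    idx <- seq(m, 60, by = 12)
    pr <- t(combn(seq_along(idx), 2))
    slopes <- c(slopes, (x[idx[pr[, 2]]] - x[idx[pr[, 1]]]) /
                  (pr[, 2] - pr[, 1]))
  }
  expect_equal(seasonal_sen_slope(x, 12), median(slopes))
})

test_that("area trends table runs per region and type", {
  pred <- expand.grid(time_index = 1:24, lat = c(0, 30), lon = c(0, 10))
  pred$year <- 2003 + (pred$time_index - 1) %/% 12
  pred$month <- (pred$time_index - 1) %% 12 + 1
  pred$missing <- FALSE
  pred$none <- FALSE
  pred$argmax_type <- ifelse(pred$lat == 0, 1L, 2L)
  pred$max_prob <- 1
  pred$types <- as.character(pred$argmax_type)
  attr(pred, "dlat") <- 1; attr(pred, "dlon") <- 1
  class(pred) <- c("grid_prediction", "data.frame")
  mask <- data.frame(lat = c(0, 30, 0, 30), lon = c(0, 0, 10, 10),
                     region = c("trades", "westerlies", "trades",
                                "westerlies"))
  ar <- area_series(pred, region_mask = mask)
  tr <- area_trends(ar)
  expect_setequal(tr$region, c("trades", "westerlies"))
  expect_true(all(tr$sen_slope_km2_per_year == 0))   # static map: no trend
  expect_true(all(tr$p_value == 1))
})
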