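#' Downsample a gridded series by block-center selection
#'
#' Keeps exactly one cell per `factor` x `factor` block — the cell at
#' zero-based block-local index `(floor(factor/2), floor(factor/2))`, i.e.
#' the lower-right of the four central cells for an even factor — and drops
#' partial edge blocks. Selection, not aggregation: kept values equal the
#' corresponding input cells. With factor 12 this reduces a 5-arcminute grid
#' to one cell per 1-degree square, the cost-reduction step of the reference
#' workflow.
#'
#' @param field A `grid_field_series`.
#' @param factor Integer block size (>= 1); 1 is the identity.
#' @return A downsampled `grid_field_series`.
#' @export
downsample_grid <- function(field, factor = 12L) {
  stopifnot(inherits(field, "grid_field_series"), factor >= 1L)
  nr <- length(field$lat); nc <- length(field$lon)
  if (nr < factor || nc < factor) stop("grid smaller than the block factor")
  off <- floor(factor / 2) + 1L            # 1-based block-local index
  ri <- seq(off, by = factor, length.out = nr %/% factor)
  ci <- seq(off, by = factor, length.out = nc %/% factor)
  out <- field
  out$lat <- field$lat[ri]
  out$lon <- field$lon[ci]
  out$data <- lapply(field$data, function(a) a[, ri, ci, drop = FALSE])
  out$mask <- field$mask[, ri, ci, drop = FALSE]
  if (!is.null(field$latent)) out$latent <- field$latent[, ri, ci, drop = FALSE]
  out
}

#' Predict community types over a gridded series
#'
#' Applies a trained classifier to every (month, cell) with complete
#' features. Each cell receives the set of types whose probability reaches
#' the model's probability threshold, plus the argmax type and its
#' probability (the value displayed when several types co-occur). Cells
#' with any missing parameter, or below-threshold everywhere, carry the
#' none flag (the "gray" cells of the reference maps).
#'
#' @param model A `trained_classifier` whose features are the grid's
#'   parameter names (e.g. the 17 satellite parameters).
#' @param field A `grid_field_series`.
#' @return Object of class `grid_prediction`: tidy `data.frame` with
#'   `time_index`, `year`, `month`, `lat`, `lon`, `missing` (masked/incomplete
#'   input), `none` (no type reached the threshold), `argmax_type`,
#'   `max_prob`, `types` (";"-separated predicted set) and one `prob_<class>`
#'   column per class. Cell sizes are carried as the `dlat`/`dlon` attributes.
#' @export
predict_map <- function(model, field) {
  stopifnot(inherits(field, "grid_field_series"))
  need <- model$feature_names
  missing_par <- setdiff(need, names(field$data))
  if (length(missing_par)) {
    stop("grid is missing parameter(s): ", paste(missing_par, collapse = ", "))
  }
  dims <- dim(field$mask)
  nt <- dims[1L]; nr <- dims[2L]; nc <- dims[3L]
  cells <- expand.grid(time_index = seq_len(nt), ilat = seq_len(nr),
                       ilon = seq_len(nc))
  x <- vapply(need, function(p) as.vector(field$data[[p]]),
              numeric(nt * nr * nc))
  incomplete <- as.vector(field$mask) | !stats::complete.cases(x)

  classes <- model$classes
  prob <- matrix(NA_real_, nrow(cells), length(classes),
                 dimnames = list(NULL, classes))
  if (any(!incomplete)) {
    prob[!incomplete, ] <- predict(model, x[!incomplete, , drop = FALSE])
  }
  thr <- model$probability_threshold
  pass <- !is.na(prob) & prob >= thr
  none <- !incomplete & rowSums(pass) == 0L
  arg <- max.col(ifelse(is.na(prob), -Inf, prob), ties.method = "first")
  arg_type <- ifelse(incomplete | none, NA_integer_, as.integer(classes[arg]))
  max_prob <- ifelse(incomplete, NA_real_, prob[cbind(seq_len(nrow(prob)), arg)])
  sets <- vapply(seq_len(nrow(prob)), function(i) {
    if (incomplete[i] || none[i]) "" else
      paste(classes[pass[i, ]], collapse = ";")
  }, character(1L))

  out <- data.frame(time_index = cells$time_index,
                    year = field$time$year[cells$time_index],
                    month = field$time$month[cells$time_index],
                    lat = field$lat[cells$ilat],
                    lon = field$lon[cells$ilon],
                    missing = incomplete,
                    none = none,
                    argmax_type = arg_type,
                    max_prob = max_prob,
                    types = sets,
                    stringsAsFactors = FALSE)
  pcols <- as.data.frame(prob)
  names(pcols) <- paste0("prob_", classes)
  out <- cbind(out, pcols)
  attr(out, "dlat") <- if (nr > 1L) abs(diff(field$lat[1:2])) else NA_real_
  attr(out, "dlon") <- if (nc > 1L) abs(diff(field$lon[1:2])) else NA_real_
  attr(out, "classes") <- classes
  class(out) <- c("grid_prediction", "data.frame")
  out
}

#' Monthly area occupied by each community type per region
#'
#' Sums cell areas per (month, region, type). The area of a cell centered
#' at latitude phi spanning `dlat` x `dlon` degrees is
#' `(pi * R / 180)^2 * dlat * dlon * cos(phi)` with R = 6371 km. In the
#' default `"multi"` mode every type in a cell's predicted set receives the
#' full cell area (multi-label cells count toward each of their types);
#' `"argmax"` counts each cell once, toward its top type. None-flagged and
#' missing cells contribute to the `"none"` / `"missing"` rows so monthly
#' totals are conserved.
#'
#' @param pred A `grid_prediction`.
#' @param region_mask Optional `data.frame` with `lat`, `lon`, `region`
#'   assigning cells to regions (e.g. Longhurst biomes); unmatched cells are
#'   reported as region `"unmasked"`. Default: one global region.
#' @param mode `"multi"` (default) or `"argmax"`.
#' @return `data.frame` with `time_index`, `year`, `month`, `region`, `type`
#'   (class id as character, or `"none"`/`"missing"`), `area_km2`.
#' @export
area_series <- function(pred, region_mask = NULL,
                        mode = c("multi", "argmax")) {
  mode <- match.arg(mode)
  dlat <- attr(pred, "dlat"); dlon <- attr(pred, "dlon")
  if (is.na(dlat) || is.na(dlon)) stop("cell size undefined for 1-cell grids")
  r <- 6371
  area <- (pi * r / 180)^2 * dlat * dlon * cos(pred$lat * pi / 180)

  region <- rep("global", nrow(pred))
  if (!is.null(region_mask)) {
    key <- paste(signif(pred$lat, 10), signif(pred$lon, 10))
    mkey <- paste(signif(region_mask$lat, 10), signif(region_mask$lon, 10))
    hit <- match(key, mkey)
    region <- ifelse(is.na(hit), "unmasked",
                     as.character(region_mask$region[hit]))
    if (any(is.na(hit))) {
      message(sum(is.na(hit)), " cell-month(s) not covered by the region mask")
    }
  }

  type_of <- function(i) {
    if (pred$missing[i]) return("missing")
    if (pred$none[i]) return("none")
    if (mode == "argmax") as.character(pred$argmax_type[i]) else
      strsplit(pred$types[i], ";", fixed = TRUE)[[1L]]
  }
  types <- lapply(seq_len(nrow(pred)), type_of)
  nrep <- lengths(types)
  long <- data.frame(time_index = rep(pred$time_index, nrep),
                     year = rep(pred$year, nrep),
                     month = rep(pred$month, nrep),
                     region = rep(region, nrep),
                     type = unlist(types),
                     area_km2 = rep(area, nrep),
                     stringsAsFactors = FALSE)
  out <- stats::aggregate(area_km2 ~ time_index + year + month + region + type,
                          data = long, FUN = sum)
  out[order(out$time_index, out$region, out$type), , drop = FALSE]
}

# internal: Kendall S statistic and tie-corrected variance of one season
kendall_s <- function(v) {
  n <- length(v)
  s <- 0
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      s <- s + sum(sign(v[(i + 1L):n] - v[i]))
    }
  }
  ties <- table(v)
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  c(s = s, var = var_s)
}

#' Seasonal Mann-Kendall trend test
#'
#' Computes the Kendall S statistic within each season (calendar month for
#' `period = 12`) across years, sums S and the tie-corrected variances over
#' seasons (no cross-season covariance correction), and evaluates the
#' two-sided p-value by normal approximation with continuity correction.
#' Robust to an arbitrary fixed seasonal cycle.
#'
#' @param series Numeric vector of period-spaced values (e.g. a monthly area
#'   series), season index cycling as position modulo `period`; `NA`s are
#'   dropped within seasons.
#' @param period Number of seasons per cycle (default 12).
#' @return List with `p_value`, `direction` (`"increasing"`, `"decreasing"`
#'   or `"none"`), `s` and `var_s`.
#' @export
seasonal_mann_kendall <- function(series, period = 12L) {
  seas <- ((seq_along(series) - 1L) %% period) + 1L
  s_tot <- 0; v_tot <- 0
  for (m in seq_len(period)) {
    v <- series[seas == m]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    ks <- kendall_s(v)
    s_tot <- s_tot + ks["s"]; v_tot <- v_tot + ks["var"]
  }
  if (v_tot == 0) {
    return(list(p_value = 1, direction = "none", s = 0, var_s = 0))
  }
  z <- if (s_tot > 0) (s_tot - 1) / sqrt(v_tot) else
    if (s_tot < 0) (s_tot + 1) / sqrt(v_tot) else 0
  p <- 2 * stats::pnorm(-abs(z))
  dir <- if (s_tot > 0) "increasing" else if (s_tot < 0) "decreasing" else
    "none"
  list(p_value = unname(p), direction = dir,
       s = unname(s_tot), var_s = unname(v_tot))
}

#' Seasonal Theil-Sen slope
#'
#' Median of all within-season pairwise slopes
#' `(x_j - x_i) / (year_j - year_i)`, pooled across seasons; a seasonal
#' cycle added to a linear trend leaves the estimate unchanged because only
#' same-season pairs are compared. Units: series units per year.
#'
#' @inheritParams seasonal_mann_kendall
#' @return Slope (per year).
#' @export
seasonal_sen_slope <- function(series, period = 12L) {
  seas <- ((seq_along(series) - 1L) %% period) + 1L
  yr <- (seq_along(series) - 1L) %/% period
  slopes <- numeric(0)
  for (m in seq_len(period)) {
    idx <- which(seas == m & !is.na(series))
    if (length(idx) < 2L) next
    v <- series[idx]; t <- yr[idx]
    pair <- utils::combn(length(idx), 2L)
    slopes <- c(slopes, (v[pair[2L, ]] - v[pair[1L, ]]) /
                  (t[pair[2L, ]] - t[pair[1L, ]]))
  }
  if (length(slopes) == 0L) stop("fewer than 2 points in every season")
  stats::median(slopes)
}

#' Long-term trends of community-type areas per region
#'
#' Runs the seasonal Mann-Kendall test and seasonal Theil-Sen slope on the
#' monthly area series of every (region, type) combination.
#'
#' @param areas Output of [area_series()].
#' @param period Seasons per year (default 12).
#' @return `data.frame` with `region`, `type`, `p_value`, `direction`,
#'   `sen_slope_km2_per_year`.
#' @export
area_trends <- function(areas, period = 12L) {
  nt <- max(areas$time_index)
  combos <- unique(areas[, c("region", "type")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- areas$region == combos$region[i] & areas$type == combos$type[i]
    series <- numeric(nt)                       # absent months = area 0
    series[areas$time_index[sel]] <- areas$area_km2[sel]
    mk <- seasonal_mann_kendall(series, period)
    data.frame(region = combos$region[i], type = combos$type[i],
               p_value = mk$p_value, direction = mk$direction,
               sen_slope_km2_per_year = seasonal_sen_slope(series, period),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
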