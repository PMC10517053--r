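#' The 17 satellite-derived parameter names
#'
#' Remote-sensing reflectance at 10 wavelengths (sr^-1), chlorophyll-a
#' (mg m^-3), diffuse attenuation at 490 nm (m^-1), particulate organic and
#' inorganic carbon (mg m^-3, mol m^-3), photosynthetically available
#' radiation (einstein m^-2 d^-1), normalized fluorescence line height
#' (mW cm^-2 um^-1 sr^-1) and sea-surface temperature (degrees C).
#'
#' @return Character vector of length 17.
#' @export
satellite_feature_names <- function() {
  c(paste0("rrs_", c(412, 443, 469, 488, 531, 547, 555, 645, 667, 678)),
    "chl_a", "kd_490", "poc", "pic", "par", "nflh", "sst")
}

# internal: deterministic smooth response of each of the 17 parameters to the
# latent environmental gradient g in [0, 1]. Shapes are chosen to be smooth,
# mutually distinct and on realistic scales; no radiative-transfer realism is
# attempted. Returns a length(g) x 17 matrix.
satellite_feature_surface <- function(g) {
  wl <- c(412, 443, 469, 488, 531, 547, 555, 645, 667, 678)
  out <- matrix(0, length(g), 17L,
                dimnames = list(NULL, satellite_feature_names()))
  for (j in seq_along(wl)) {
    phase <- (wl[j] - 412) / (678 - 412)         # wavelength-specific shape
    out[, j] <- 0.005 + 0.004 * cos(2 * pi * (0.75 * g - 0.4 * phase))
  }
  out[, "chl_a"] <- exp(1.2 - 4.0 * g)                       # 0.07 .. 3.3
  out[, "kd_490"] <- 0.02 + 0.20 * exp(-3 * g)
  out[, "poc"] <- 30 + 260 * exp(-2.5 * g)
  out[, "pic"] <- 2e-4 + 2e-3 * exp(-(g - 0.35)^2 / 0.02)
  out[, "par"] <- 18 + 42 * exp(-(g - 0.5)^2 / 0.08)         # peaks mid-grad
  out[, "nflh"] <- 0.01 + 0.30 * exp(-4 * g)
  out[, "sst"] <- -2 + 32 * g
  out
}

# internal: derive a sub-stream seed from the master seed; kept < 2^31 so it
# is a valid R integer
seed_stream <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + 101 * k) %% 2147483647L)
}

#' Configuration of a synthetic plankton world
#'
#' Bundles and validates the knobs of [generate_world()]. Defaults describe
#' a world at the scale of the reference study's training set: ~180 open-ocean
#' samples, six planted OTU modules, 10,000-read sampling depth, a strong
#' latitude-driven gradient and mildly noisy satellite features.
#'
#' @param n_samples Number of samples.
#' @param n_otus_per_module OTUs planted in each module.
#' @param n_modules Number of planted modules K.
#' @param n_noise_otus Additional OTUs belonging to no module.
#' @param read_depth Reads per sample (>= 100).
#' @param gradient_strength Effect size linking the latent gradient to module
#'   expression; 0 removes all community signal.
#' @param feature_noise_sd Feature noise as a fraction of each feature's
#'   dynamic range.
#' @param spatial_cluster_km Radius of the spatial sampling clusters (km).
#' @param shallow_frac Fraction of samples placed over a seafloor shallower
#'   than 200 m, exercising the open-ocean filter.
#' @param samples_per_cluster Mean cluster size used to pick the number of
#'   spatial clusters.
#' @param cluster_labels If `TRUE`, community types are drawn per spatial
#'   cluster independently of latitude (spatially clustered but positionally
#'   unpredictable labels, for leakage experiments); default `FALSE` ties the
#'   type to the latent gradient.
#' @param seed Master seed; every generated object draws from its own stream
#'   derived from it.
#' @return Object of class `world_config`.
#' @export
world_config <- function(n_samples = 180L, n_otus_per_module = 12L,
                         n_modules = 6L, n_noise_otus = 30L,
                         read_depth = 10000L, gradient_strength = 6,
                         feature_noise_sd = 0.03, spatial_cluster_km = 400,
                         shallow_frac = 0, samples_per_cluster = 6L,
                         cluster_labels = FALSE, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_otus_per_module = as.integer(n_otus_per_module),
              n_modules = as.integer(n_modules),
              n_noise_otus = as.integer(n_noise_otus),
              read_depth = as.integer(read_depth),
              gradient_strength = gradient_strength,
              feature_noise_sd = feature_noise_sd,
              spatial_cluster_km = spatial_cluster_km,
              shallow_frac = shallow_frac,
              samples_per_cluster = as.integer(samples_per_cluster),
              cluster_labels = isTRUE(cluster_labels),
              seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 1L || n_otus_per_module < 1L || n_modules < 1L)
      stop("configuration error: counts must be >= 1")
    if (n_noise_otus < 0L) stop("configuration error: n_noise_otus < 0")
    if (read_depth < 100L) stop("configuration error: read_depth < 100")
    if (gradient_strength < 0) stop("configuration error: negative gradient")
  })
  structure(cfg, class = "world_config")
}

#' Generate a synthetic metabarcoding world with ground truth
#'
#' Places samples in spatial clusters on the sphere, derives a latent
#' environmental gradient that is monotone in latitude (a temperature
#' surrogate), lets the gradient pick one dominant planted OTU module per
#' sample, draws read counts from a Dirichlet-multinomial (module members get
#' a concentration boost proportional to their module's activation, giving
#' the overdispersion and positive within-module covariation typical of
#' metabarcoding data), and evaluates the 17 satellite parameters as smooth
#' functions of the gradient plus independent noise.
#'
#' @param config A [world_config()].
#' @return List with `otu` (samples x OTUs integer matrix; rows sum to
#'   `read_depth`), `meta` (metadata `data.frame`), `features`
#'   (`data.frame` with `sample_id` plus the 17 parameters), and `truth`
#'   (list: `otu_module` named integer vector with 0 = noise, `sample_type`
#'   named integer vector in 1..K, `latent_gradient`, `cluster` id per
#'   sample).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  K <- config$n_modules
  n <- config$n_samples
  sample_ids <- sprintf("s%03d", seq_len(n))

  ## spatial clusters on the sphere
  set.seed(seed_stream(config$seed, 1L))
  n_clust <- max(2L, ceiling(n / config$samples_per_cluster))
  c_lat <- stats::runif(n_clust, -70, 70)
  c_lon <- stats::runif(n_clust, -180, 180)
  cl <- sort(rep_len(seq_len(n_clust), n))
  bearing <- stats::runif(n, 0, 2 * pi)
  dist_km <- stats::runif(n, 0, config$spatial_cluster_km)
  pos <- destination_point(c_lat[cl], c_lon[cl], bearing, dist_km)

  ## latent gradient, monotone in latitude
  g <- pmin(1, pmax(0, (pos$lat + 70) / 140))

  ## community type and module activations
  centers <- (seq_len(K) - 0.5) / K
  act <- exp(-outer(g, centers, "-")^2 / (2 * (0.6 / K)^2))   # n x K
  if (config$cluster_labels) {
    set.seed(seed_stream(config$seed, 7L))
    lab_of_cluster <- sample(rep_len(seq_len(K), n_clust))
    type <- lab_of_cluster[cl]
    act <- matrix(0, n, K)
    act[cbind(seq_len(n), type)] <- 1
  } else {
    type <- max.col(act, ties.method = "first")
  }

  ## OTU inventory
  n_otus <- K * config$n_otus_per_module + config$n_noise_otus
  otu_ids <- sprintf("otu_%04d", seq_len(n_otus))
  otu_module <- c(rep(seq_len(K), each = config$n_otus_per_module),
                  rep(0L, config$n_noise_otus))
  names(otu_module) <- otu_ids

  ## Dirichlet-multinomial counts
  set.seed(seed_stream(config$seed, 3L))
  counts <- matrix(0L, n, n_otus, dimnames = list(sample_ids, otu_ids))
  for (i in seq_len(n)) {
    alpha <- rep(1, n_otus)
    boosted <- otu_module > 0L
    alpha[boosted] <- 1 + config$gradient_strength * act[i, otu_module[boosted]]
    p <- stats::rgamma(n_otus, shape = alpha)
    counts[i, ] <- as.integer(
      stats::rmultinom(1L, config$read_depth, p / sum(p)))
  }

  ## satellite features: smooth response + scaled independent noise
  set.seed(seed_stream(config$seed, 4L))
  surf <- satellite_feature_surface(g)
  ranges <- apply(satellite_feature_surface(seq(0, 1, length.out = 201L)),
                  2L, function(x) diff(range(x)))
  noise <- matrix(stats::rnorm(n * 17L), n, 17L)
  feat <- surf + sweep(noise, 2L, config$feature_noise_sd * ranges, `*`)
  features <- data.frame(sample_id = sample_ids, feat,
                         stringsAsFactors = FALSE)

  ## metadata, with a configurable fraction of shallow-seafloor samples
  set.seed(seed_stream(config$seed, 5L))
  n_shallow <- round(config$shallow_frac * n)
  shallow <- seq_len(n) %in% sample.int(n, n_shallow)
  seafloor <- ifelse(shallow, stats::runif(n, 20, 199),
                     stats::runif(n, 1000, 6000))
  meta <- data.frame(
    sample_id = sample_ids,
    latitude = pos$lat,
    longitude = pos$lon,
    date = sprintf("2019-%02d", sample.int(12L, n, replace = TRUE)),
    sampling_depth_m = stats::runif(n, 0, 9.5),
    seafloor_depth_m = seafloor,
    size_fraction = ">0.8",
    stringsAsFactors = FALSE
  )

  list(otu = counts, meta = meta, features = features,
       truth = list(otu_module = otu_module,
                    sample_type = stats::setNames(type, sample_ids),
                    latent_gradient = stats::setNames(g, sample_ids),
                    cluster = stats::setNames(cl, sample_ids)),
       config = config)
}

# internal: destination point on the sphere given start, bearing (rad) and
# great-circle distance (km); Earth radius 6371 km
destination_point <- function(lat, lon, bearing, dist_km) {
  r <- 6371
  to_rad <- pi / 180
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  delta <- dist_km / r
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(bearing))
  lam2 <- lam1 + atan2(sin(bearing) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  lon2 <- ((lam2 / to_rad + 180) %% 360) - 180
  list(lat = phi2 / to_rad, lon = lon2)
}

#' Generate a gridded monthly feature series
#'
#' Builds `n_years` of monthly grids of the 17 satellite parameters. The
#' latent gradient field is monotone in latitude, carries an
#' opposite-hemisphere seasonal cycle and an optional linear trend of known
#' slope (the analogue of long-term surface warming shifting community-type
#' boundaries), plus cell-level noise. A missing-data mask can be injected
#' at a configurable rate.
#'
#' @param n_years Number of years (>= 1); months run January..December.
#' @param grid_shape Integer `(rows, cols)` = (latitude, longitude) cells.
#' @param gradient_trend_per_year Linear trend added to the latent gradient
#'   per year (gradient units / year).
#' @param missing_rate Bernoulli rate of masked (missing) cell-months.
#' @param seasonal_amplitude Amplitude of the seasonal gradient cycle.
#' @param feature_noise_sd Cell noise as a fraction of feature dynamic range.
#' @param start_year First calendar year (default 2003).
#' @param seed Integer seed.
#' @return Object of class `grid_field_series`: list with `time`
#'   (`data.frame` of year, month), `lat`, `lon` (cell-center degrees),
#'   `data` (named list of 17 arrays, dim time x lat x lon), `mask` (logical
#'   array, `TRUE` = missing) and `latent` (the underlying gradient array).
#' @export
generate_grid_series <- function(n_years, grid_shape = c(24L, 24L),
                                 gradient_trend_per_year = 0,
                                 missing_rate = 0, seasonal_amplitude = 0.04,
                                 feature_noise_sd = 0.01,
                                 start_year = 2003L, seed = 1L) {
  stopifnot(n_years >= 1)
  if (any(grid_shape < 1L)) stop("empty grid")
  nr <- grid_shape[1L]; nc <- grid_shape[2L]
  lat <- seq(-65, 65, length.out = nr)
  lon <- seq(-180, 180 - 360 / nc, length.out = nc)
  nt <- 12L * n_years
  time <- data.frame(year = start_year + rep(seq_len(n_years) - 1L, each = 12L),
                     month = rep(1:12, n_years))
  tyears <- (seq_len(nt) - 1L) / 12

  set.seed(seed_stream(seed, 6L))
  g0 <- (lat + 70) / 140
  season <- sin(2 * pi * (time$month - 1) / 12)
  hemis <- ifelse(lat >= 0, 1, -1)
  latent <- array(0, dim = c(nt, nr, nc))
  for (t in seq_len(nt)) {
    base <- g0 + seasonal_amplitude * season[t] * hemis +
      gradient_trend_per_year * tyears[t]
    latent[t, , ] <- matrix(base, nr, nc) +
      matrix(stats::rnorm(nr * nc, sd = 0.01), nr, nc)
  }
  latent[] <- pmin(1.2, pmax(-0.2, latent))      # clamp, keeping dims

  ranges <- apply(satellite_feature_surface(seq(0, 1, length.out = 201L)),
                  2L, function(x) diff(range(x)))
  flat <- satellite_feature_surface(as.vector(latent))
  data <- vector("list", 17L)
  names(data) <- satellite_feature_names()
  for (j in seq_len(17L)) {
    v <- flat[, j] + stats::rnorm(length(latent),
                                  sd = feature_noise_sd * ranges[j])
    data[[j]] <- array(v, dim = dim(latent))
  }
  mask <- array(stats::runif(length(latent)) < missing_rate,
                dim = dim(latent))
  structure(list(time = time, lat = lat, lon = lon, data = data,
                 mask = mask, latent = latent),
            class = "grid_field_series")
}

#' Print a grid_field_series summary
#'
#' @param x Object.
#' @param ... Unused.
#' @return The object, invisibly.
#' @method print grid_field_series
#' @export
print.grid_field_series <- function(x, ...) {
  cat("grid_field_series:", nrow(x$time), "months,",
      length(x$lat), "x", length(x$lon), "cells,",
      length(x$data), "parameters,",
      round(100 * mean(x$mask), 1), "% masked\n")
  invisible(x)
}
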