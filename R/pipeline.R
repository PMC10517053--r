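#' Default pipeline configuration
#'
#' Every tunable of the end-to-end pipeline with its reference default:
#' rarefaction to 10,000 reads, 5-arcminute monthly binning, the 200 m
#' open-ocean seafloor rule, 200 km spatial thinning, the 0.2%-in-10%
#' OTU occurrence filter, clr pseudocount 1, partial-correlation network
#' inference at alpha 0.05 with conditioning up to size 3, module size
#' floor 3, unit logistic sigmoid, linear classifier with C grid
#' {0.01..100}, 2000 km buffered CV, threshold grid 0.01..0.99 and 12x12
#' grid downsampling. `world` holds the synthetic-generator settings used
#' when no input files are given.
#'
#' @return Nested named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    inputs = list(otu = NULL, meta = NULL, features = NULL),
    world = list(n_samples = 150L, n_otus_per_module = 10L, n_modules = 3L,
                 n_noise_otus = 20L, read_depth = 3000L,
                 gradient_strength = 12, feature_noise_sd = 0.03,
                 spatial_cluster_km = 1200, samples_per_cluster = 5L,
                 shallow_frac = 0.05),
    rarefaction_depth = 10000L,
    bin_arcmin = 5,
    min_seafloor_m = 200,
    thin_min_km = 200,
    otu_min_frac = 0.002,
    otu_min_prevalence = 0.10,
    clr_pseudocount = 1,
    network_alpha = 0.05,
    max_conditioning = 3L,
    module_algorithms = c("louvain", "label_prop"),
    min_module_size = 3L,
    sigmoid_scale = 1,
    sigmoid_offset = 0,
    algorithm = "linear",
    hyper_C = c(0.01, 0.1, 1, 10, 100),
    inner_folds = 5L,
    buffer_km = 2000,
    threshold_grid = seq(0.01, 0.99, by = 0.01),
    feature_set = "all17",
    n_years = 5L,
    grid_shape = c(24L, 24L),
    gradient_trend_per_year = 0,
    grid_missing_rate = 0,
    downsample_factor = 1L
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override the defaults of
#' [default_pipeline_config()]; unknown keys (at top level or inside
#' `world`/`inputs`) are rejected by name.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_checked <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown)) {
      stop("unknown configuration key", if (length(unknown) > 1L) "s" else "",
           " in ", where, ": ", paste(unknown, collapse = ", "))
    }
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_checked(base[[k]], upd[[k]], k)
      } else {
        upd[[k]]
      }
    }
    base
  }
  structure(merge_checked(unclass(cfg), user, "config"),
            class = "pipeline_config")
}

# internal: feature-subset selection mirroring the reference comparison table
feature_subset <- function(features, meta, feature_set) {
  env7 <- c("sst", "chl_a", "kd_490", "poc", "pic", "par", "nflh")
  cols <- switch(feature_set,
                 all17 = satellite_feature_names(),
                 sst = "sst",
                 chl_a = "chl_a",
                 sst_chl = c("sst", "chl_a"),
                 env7 = env7,
                 position = NULL,
                 stop("unknown feature_set '", feature_set, "'"))
  if (identical(feature_set, "position")) {
    encode_position(meta$latitude, meta$longitude)
  } else {
    as.matrix(features[, cols, drop = FALSE])
  }
}

#' Run the full pipeline
#'
#' Executes the stages in fixed order — simulate (or load), rarefy, bin,
#' open-ocean filter, missing-feature drop, spatial thinning, OTU filter,
#' clr, network inference, module detection, edge-satisfaction typing,
#' classifier training with threshold selection, LOO and buffered CV,
#' gridded prediction and area-trend estimation — writing every product
#' plus the resolved configuration and a provenance manifest (input hashes,
#' seeds, package version) into `out_dir`. Per-stage drop counts go to the
#' log via `message()`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory products.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("planktotype_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) message("[planktotype] ", ...)

  ## inputs: files if configured, otherwise the synthetic world
  if (!is.null(config$inputs$otu)) {
    stage("loading inputs")
    otu <- read_otu_table(config$inputs$otu)
    meta <- read_sample_meta(config$inputs$meta)
    features <- read_features(config$inputs$features)
    depth <- config$rarefaction_depth
  } else {
    stage("simulating world (seed ", config$seed, ")")
    wc <- do.call(world_config, c(config$world, list(seed = config$seed)))
    world <- generate_world(wc)
    otu <- world$otu; meta <- world$meta; features <- world$features
    depth <- min(config$rarefaction_depth, wc$read_depth)
  }
  write_otu_table(otu, file.path(out_dir, "otu_raw.tsv"))

  ## preprocess
  stage("rarefying to ", depth, " reads")
  otu <- rarefy(otu, depth, seed = seed_stream(config$seed, 11L))
  meta <- meta[meta$sample_id %in% rownames(otu), , drop = FALSE]
  binned <- bin_samples(otu, meta, cell_arcmin = config$bin_arcmin)
  stage("binned ", nrow(otu), " samples into ", nrow(binned$table), " bins")
  otu <- binned$table; meta <- binned$meta
  features <- features_for_bins(features, binned$groups)

  meta <- filter_open_ocean(meta, config$min_seafloor_m)
  dropped <- drop_missing_features(meta, features)
  meta <- dropped$meta; features <- dropped$features
  meta <- thin_spatial(meta, config$thin_min_km,
                       seed = seed_stream(config$seed, 12L))
  stage(nrow(meta), " samples after open-ocean filter + thinning")
  otu <- otu[meta$sample_id, , drop = FALSE]
  features <- features[meta$sample_id, , drop = FALSE]
  otu <- filter_otus(otu, config$otu_min_frac, config$otu_min_prevalence,
                     depth = depth)
  stage(ncol(otu), " OTUs pass the occurrence filter")
  clr <- clr_transform(otu, config$clr_pseudocount)
  write_otu_table(otu, file.path(out_dir, "otu_filtered.tsv"))
  write_sample_meta(meta, file.path(out_dir, "samples.csv"))

  ## network and modules
  stage("inferring network (alpha ", config$network_alpha, ")")
  net <- infer_network(clr, alpha = config$network_alpha,
                       max_conditioning = config$max_conditioning)
  stage(nrow(net$edges), " positive edges among ", length(net$nodes), " OTUs")
  cands <- lapply(config$module_algorithms, function(a)
    detect_modules(net, a, seed = seed_stream(config$seed, 13L)))
  part <- select_partition(cands, config$min_module_size)
  stage("selected ", part$algorithm, " partition, Q = ", round(part$Q, 3))
  write_network(net, file.path(out_dir, "network_edges.tsv"),
                file.path(out_dir, "network.graphml"))
  utils::write.csv(data.frame(otu_id = names(part$membership),
                              module = part$membership),
                   file.path(out_dir, "modules.csv"), row.names = FALSE)

  ## community typing
  w <- node_weights(clr, config$sigmoid_scale, config$sigmoid_offset)
  es <- edge_satisfaction(net, part, w)
  labels <- assign_types(es)
  utils::write.csv(data.frame(sample_id = rownames(es), es,
                              check.names = FALSE),
                   file.path(out_dir, "edge_satisfaction.csv"),
                   row.names = FALSE)
  utils::write.csv(labels, file.path(out_dir, "community_types.csv"),
                   row.names = FALSE)

  ## classifier + cross-validation
  x <- feature_subset(features, meta, config$feature_set)
  y <- factor(labels$community_type)
  rare <- names(which(table(y) < 2L))
  if (length(rare)) {
    stage("dropping ", sum(y %in% rare),
          " sample(s) of community type(s) with < 2 members: ",
          paste(rare, collapse = ", "))
    keep <- !(y %in% rare)
    x <- x[keep, , drop = FALSE]; y <- droplevels(y[keep])
    meta <- meta[keep, , drop = FALSE]
  }
  grid <- if (config$algorithm == "linear") {
    data.frame(C = config$hyper_C)
  } else {
    default_hyper_grid(config$algorithm)
  }
  stage("training ", config$algorithm, " classifier on ",
        config$feature_set, " features")
  model <- train_classifier(x, y, config$algorithm, grid,
                            config$inner_folds,
                            seed = seed_stream(config$seed, 14L))
  loo <- loo_cv(x, y, config$algorithm, grid, config$inner_folds,
                seed = seed_stream(config$seed, 15L))
  buf <- buffered_cv(x, y, cbind(meta$latitude, meta$longitude),
                     config$buffer_km, config$algorithm, grid,
                     config$inner_folds, seed = seed_stream(config$seed, 15L))
  model$probability_threshold <-
    select_threshold(loo$prob[!loo$per_sample$skipped, , drop = FALSE],
                     y[!loo$per_sample$skipped], config$threshold_grid)
  stage("LOO acc ", round(loo$accuracy, 3), " / AUC ",
        round(loo$micro_auc, 3), "; buffered acc ", round(buf$accuracy, 3),
        " / AUC ", round(buf$micro_auc, 3), "; threshold ",
        model$probability_threshold)
  cv_summary <- list(
    loo = list(accuracy = loo$accuracy, micro_auc = loo$micro_auc),
    buffered = list(accuracy = buf$accuracy, micro_auc = buf$micro_auc,
                    n_skipped = buf$n_skipped),
    threshold = model$probability_threshold,
    hyper = model$hyper)
  jsonlite::write_json(cv_summary, file.path(out_dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(loo$per_sample, file.path(out_dir, "cv_loo.csv"),
                   row.names = FALSE)
  utils::write.csv(buf$per_sample, file.path(out_dir, "cv_buffered.csv"),
                   row.names = FALSE)

  ## gridded prediction and trends
  stage("predicting ", config$n_years, "-year gridded series")
  grid_series <- generate_grid_series(
    config$n_years, config$grid_shape,
    gradient_trend_per_year = config$gradient_trend_per_year,
    missing_rate = config$grid_missing_rate,
    seed = seed_stream(config$seed, 16L))
  if (config$downsample_factor > 1L) {
    grid_series <- downsample_grid(grid_series, config$downsample_factor)
  }
  pred <- predict_map(model, grid_series)
  areas <- area_series(pred)
  trends <- area_trends(areas)
  utils::write.csv(as.data.frame(pred), file.path(out_dir, "grid_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(areas, file.path(out_dir, "area_series.csv"),
                   row.names = FALSE)
  utils::write.csv(trends, file.path(out_dir, "area_trends.csv"),
                   row.names = FALSE)

  ## provenance
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("planktotype")),
    r_version = R.version.string,
    seed = config$seed,
    output_md5 = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  stage("done: ", out_dir)

  invisible(list(out_dir = out_dir, otu = otu, meta = meta,
                 features = features, network = net, partition = part,
                 es = es, labels = labels, model = model, loo = loo,
                 buffered = buf, predictions = pred, areas = areas,
                 trends = trends))
}

# internal: bins carry the mean feature vector of their member samples
features_for_bins <- function(features, groups) {
  missing <- setdiff(satellite_feature_names(), names(features))
  if (length(missing)) {
    stop("features missing parameter(s): ", paste(missing, collapse = ", "))
  }
  feat <- features
  rownames(feat) <- feat$sample_id
  feat <- feat[, satellite_feature_names(), drop = FALSE]
  out <- t(vapply(groups, function(ids)
    colMeans(feat[ids, , drop = FALSE]), numeric(ncol(feat))))
  data.frame(sample_id = names(groups), out, stringsAsFactors = FALSE,
             row.names = names(groups))
}
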