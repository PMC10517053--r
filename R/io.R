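#' Write / read an OTU table as TSV
#'
#' On-disk dialect: OTUs as rows, samples as columns, first column `otu_id`,
#' integer or real cells. In memory the package keeps samples as rows, so
#' the writer transposes.
#'
#' @param table Samples x OTUs matrix.
#' @param path File path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu_id = colnames(table), t(table), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_otu_table
#' @return `read_otu_table` returns a samples x OTUs numeric matrix.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- NULL
  out <- t(m)
  colnames(out) <- df[[1L]]
  if (any(out < 0, na.rm = TRUE)) stop("negative counts in OTU table")
  out
}

#' Write / read sample metadata as CSV
#'
#' Columns: `sample_id`, `latitude`, `longitude`, `date`,
#' `sampling_depth_m`, `seafloor_depth_m`, `size_fraction` (units in names).
#'
#' @param meta Metadata `data.frame`.
#' @param path File path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.csv(check_meta(meta), path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  check_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read per-sample satellite features as CSV
#'
#' @param features `data.frame` with `sample_id` plus the 17 parameters.
#' @param path File path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a co-occurrence network
#'
#' Edge list as TSV (`u`, `v`, `weight`) and, optionally, GraphML.
#'
#' @param net A [co_network()].
#' @param path TSV path.
#' @param graphml_path Optional GraphML path.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @param nodes Optional node inventory for isolated nodes.
#' @export
read_network <- function(path, nodes = NULL) {
  co_network(utils::read.delim(path, stringsAsFactors = FALSE), nodes = nodes)
}

#' Write a gridded feature series as tidy CSV
#'
#' Long format with columns `year`, `month`, `lat`, `lon`, `missing` and one
#' column per parameter (a text-only stand-in for the NetCDF exchange format;
#' see the methods vignette).
#'
#' @param field A `grid_field_series`.
#' @param path File path.
#' @export
write_grid_series <- function(field, path) {
  dims <- dim(field$mask)
  idx <- expand.grid(t = seq_len(dims[1L]), r = seq_len(dims[2L]),
                     c = seq_len(dims[3L]))
  df <- data.frame(year = field$time$year[idx$t],
                   month = field$time$month[idx$t],
                   lat = field$lat[idx$r], lon = field$lon[idx$c],
                   missing = as.vector(field$mask))
  for (p in names(field$data)) df[[p]] <- as.vector(field$data[[p]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_grid_series
#' @export
read_grid_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  tim <- unique(df[, c("year", "month")])
  tim <- tim[order(tim$year, tim$month), , drop = FALSE]
  rownames(tim) <- NULL
  nt <- nrow(tim); nr <- length(lat); nc <- length(lon)
  ti <- match(paste(df$year, df$month), paste(tim$year, tim$month))
  ri <- match(df$lat, lat); ci <- match(df$lon, lon)
  ord <- cbind(ti, ri, ci)
  pars <- setdiff(names(df), c("year", "month", "lat", "lon", "missing"))
  data <- lapply(pars, function(p) {
    a <- array(NA_real_, dim = c(nt, nr, nc)); a[ord] <- df[[p]]; a
  })
  names(data) <- pars
  mask <- array(TRUE, dim = c(nt, nr, nc))
  mask[ord] <- df$missing
  structure(list(time = tim, lat = lat, lon = lon, data = data, mask = mask),
            class = "grid_field_series")
}

#' Validate pipeline input files
#'
#' Schema checks on the three input tables: metadata coordinate ranges and
#' parseable dates, presence of the 17 satellite parameter names, and
#' integrality/non-negativity of pre-binning OTU counts. Returns a
#' machine-readable error list; an empty `data.frame` means the inputs pass.
#'
#' @param otu_path,meta_path,features_path File paths (TSV / CSV / CSV).
#' @return `data.frame` with columns `file`, `error`.
#' @export
validate_inputs <- function(otu_path, meta_path, features_path) {
  errs <- list()
  add <- function(file, msg) errs[[length(errs) + 1L]] <<-
    data.frame(file = file, error = msg, stringsAsFactors = FALSE)

  otu <- tryCatch(read_otu_table(otu_path), error = function(e) {
    add(otu_path, conditionMessage(e)); NULL
  })
  if (!is.null(otu)) {
    if (any(otu != round(otu))) add(otu_path, "non-integer counts")
    if (any(otu < 0)) add(otu_path, "negative counts")
  }

  meta <- tryCatch(utils::read.csv(meta_path, stringsAsFactors = FALSE),
                   error = function(e) {
                     add(meta_path, conditionMessage(e)); NULL
                   })
  if (!is.null(meta)) {
    chk <- tryCatch({check_meta(meta); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(chk)) add(meta_path, chk)
    if (!is.null(otu) && !setequal(rownames(otu), meta$sample_id)) {
      add(meta_path, "sample ids do not match the OTU table")
    }
  }

  feat <- tryCatch(utils::read.csv(features_path, stringsAsFactors = FALSE),
                   error = function(e) {
                     add(features_path, conditionMessage(e)); NULL
                   })
  if (!is.null(feat)) {
    missing <- setdiff(satellite_feature_names(), names(feat))
    for (p in missing) add(features_path, paste("missing parameter:", p))
  }

  if (length(errs)) do.call(rbind, errs) else
    data.frame(file = character(0), error = character(0))
}
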