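#' Rarefy an OTU table to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total read count is below `depth` are dropped (a
#' message reports how many). This is the standard normalization applied to
#' metabarcoding occurrence tables before compositional analysis; the
#' reference workflow uses a depth of 10,000 reads per sample.
#'
#' @param table Numeric matrix of non-negative integer read counts, samples
#'   in rows, OTUs in columns, with dimnames.
#' @param depth Target read depth per sample (reads), `>= 1`.
#' @param seed Integer seed controlling the subsampling stream.
#' @return A samples x OTUs integer matrix in which every row sums to
#'   exactly `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(is.matrix(table), depth >= 1)
  if (any(table < 0)) stop("read counts must be non-negative")
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep)) {
    warning("no sample reaches the rarefaction depth; returning empty table")
  }
  if (any(!keep)) {
    message(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(table)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  }
  out <- matrix(0L, nrow = sum(keep), ncol = ncol(table),
                dimnames = list(rownames(table)[keep], colnames(table)))
  set.seed(as.integer(seed))
  rows <- which(keep)
  for (i in seq_along(rows)) {
    x <- table[rows[i], ]
    if (sum(x) == depth) {            # nothing to subsample
      out[i, ] <- as.integer(x)
      next
    }
    pool <- rep.int(seq_along(x), x)
    drawn <- sample(pool, size = depth, replace = FALSE)
    out[i, ] <- tabulate(drawn, nbins = length(x))
  }
  out
}

#' Bin samples into spatial-cell x month pseudo-samples
#'
#' Samples falling in the same `cell_arcmin` square grid cell (and, when
#' `by_month` is `TRUE`, the same calendar month) are averaged cell-wise into
#' a single pseudo-sample, matching the binning of sequencing samples onto
#' the 5-arcminute monthly satellite grid. Binned counts can be non-integer;
#' downstream transforms operate on reals.
#'
#' @param table Samples x OTUs count matrix (typically rarefied).
#' @param meta Sample metadata `data.frame` with columns `sample_id`,
#'   `latitude`, `longitude`, `date` (parseable as year-month, e.g.
#'   `"2019-07"`), `sampling_depth_m`, `seafloor_depth_m`, `size_fraction`.
#' @param cell_arcmin Grid cell size in arc minutes (default 5).
#' @param by_month Merge only samples sharing a calendar month (default TRUE).
#' @return List with elements `table` (binned matrix, one row per bin),
#'   `meta` (bin metadata with cell-center coordinates; numeric metadata
#'   columns are averaged within the bin) and `groups` (named list mapping
#'   each bin id to its member sample ids).
#' @export
bin_samples <- function(table, meta, cell_arcmin = 5, by_month = TRUE) {
  check_meta(meta)
  if (!setequal(rownames(table), meta$sample_id) ||
      nrow(table) != nrow(meta)) {
    stop("table rows and meta$sample_id do not match")
  }
  meta <- meta[match(rownames(table), meta$sample_id), , drop = FALSE]
  step <- cell_arcmin / 60
  ilat <- floor((meta$latitude + 90) / step)
  ilon <- floor((meta$longitude + 180) / step)
  mon <- format_year_month(meta$date)
  key <- if (by_month) paste(ilat, ilon, mon, sep = "|") else
    paste(ilat, ilon, sep = "|")
  groups <- split(seq_len(nrow(table)), key)
  binned <- t(vapply(groups, function(idx)
    colMeans(table[idx, , drop = FALSE]), numeric(ncol(table))))
  bin_meta <- do.call(rbind, lapply(names(groups), function(k) {
    idx <- groups[[k]]
    data.frame(
      sample_id = paste0("bin_", gsub("\\|", "_", k)),
      latitude = (ilat[idx[1L]] + 0.5) * step - 90,
      longitude = (ilon[idx[1L]] + 0.5) * step - 180,
      date = mon[idx[1L]],
      sampling_depth_m = mean(meta$sampling_depth_m[idx]),
      seafloor_depth_m = mean(meta$seafloor_depth_m[idx]),
      size_fraction = meta$size_fraction[idx[1L]],
      n_merged = length(idx),
      stringsAsFactors = FALSE
    )
  }))
  rownames(binned) <- bin_meta$sample_id
  rownames(bin_meta) <- NULL
  members <- lapply(groups, function(idx) rownames(table)[idx])
  names(members) <- bin_meta$sample_id
  list(table = binned, meta = bin_meta, groups = members)
}

#' Keep open-ocean samples only
#'
#' Removes samples taken where the seafloor is shallower than
#' `min_seafloor_m` (strictly `<`; a seafloor exactly at the threshold is
#' retained). Samples with a missing seafloor depth are removed with a
#' warning.
#'
#' @param meta Sample metadata (see [bin_samples()]).
#' @param min_seafloor_m Depth threshold in metres, positive down
#'   (default 200).
#' @return Filtered metadata.
#' @export
filter_open_ocean <- function(meta, min_seafloor_m = 200) {
  check_meta(meta)
  miss <- is.na(meta$seafloor_depth_m)
  if (any(miss)) {
    warning(sum(miss), " sample(s) with missing seafloor depth removed")
  }
  keep <- !miss & meta$seafloor_depth_m >= min_seafloor_m
  meta[keep, , drop = FALSE]
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, used consistently for
#' spatial thinning and the buffered cross-validation exclusion zone.
#' Vectorized over coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' All-pairs haversine distance matrix
#'
#' @param lat,lon Coordinate vectors in decimal degrees.
#' @return Symmetric n x n matrix of distances in km.
#' @export
haversine_matrix <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  (d + t(d)) / 2
}

#' Spatially thin samples to a minimum pairwise separation
#'
#' Greedy thinning in the style of occurrence-record thinning tools: while
#' any pair of samples lies closer than `min_km`, the sample with the most
#' neighbors inside `min_km` is removed (ties broken by a seeded random
#' draw). The retained set has every pairwise great-circle distance
#' `>= min_km`; the greedy rule aims to keep many samples but does not
#' guarantee the maximum.
#'
#' @param meta Sample metadata with `latitude`/`longitude`.
#' @param min_km Minimum separation in km (default 200).
#' @param seed Integer seed for tie-breaking.
#' @return Thinned metadata (subset of rows of `meta`).
#' @export
thin_spatial <- function(meta, min_km = 200, seed = 1L) {
  check_meta(meta)
  if (nrow(meta) == 0L) stop("no samples to thin")
  d <- haversine_matrix(meta$latitude, meta$longitude)
  viol <- d < min_km
  diag(viol) <- FALSE
  alive <- rep(TRUE, nrow(meta))
  set.seed(as.integer(seed))
  repeat {
    deg <- rowSums(viol[, alive, drop = FALSE]) * alive
    if (max(deg) == 0) break
    worst <- which(deg == max(deg))
    drop <- if (length(worst) > 1L) sample(worst, 1L) else worst
    alive[drop] <- FALSE
  }
  meta[alive, , drop = FALSE]
}

#' Filter OTUs by minimum occurrence and prevalence
#'
#' Retains OTUs whose per-sample count reaches `min_frac * depth` reads in at
#' least `ceiling(min_prevalence * n_samples)` samples. With the reference
#' settings (depth 10,000, `min_frac = 0.002`, `min_prevalence = 0.10`) the
#' per-sample threshold is 20 reads; a count equal to the threshold passes.
#'
#' @param table Samples x OTUs matrix (rarefied, possibly bin-averaged, so
#'   rows share a common nominal depth).
#' @param min_frac Occurrence threshold as a fraction of the read depth.
#' @param min_prevalence Minimum fraction of samples in which the occurrence
#'   threshold must be met.
#' @param depth Nominal read depth; defaults to the median row sum.
#' @return The table restricted to retained OTU columns.
#' @export
filter_otus <- function(table, min_frac = 0.002, min_prevalence = 0.10,
                        depth = stats::median(rowSums(table))) {
  stopifnot(is.matrix(table), nrow(table) > 0L)
  thr_reads <- min_frac * depth
  thr_samples <- ceiling(min_prevalence * nrow(table))
  prev <- colSums(table >= thr_reads)
  keep <- prev >= thr_samples
  table[, keep, drop = FALSE]
}

#' Centered log-ratio transform
#'
#' Per sample (row), `clr(x) = log(x + pseudocount) - mean(log(x +
#' pseudocount))`. The standard transform for compositional count data;
#' every output row sums to zero.
#'
#' @param table Samples x OTUs matrix of (possibly averaged) counts.
#' @param pseudocount Positive offset added before taking logs (default 1).
#' @return Samples x OTUs matrix of clr values.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lg <- log(table + pseudocount)
  sweep(lg, 1L, rowMeans(lg))
}

#' Drop samples with any missing satellite feature
#'
#' A sample is removed when any of its feature values is `NA`; the reference
#' workflow drops samples with missing satellite data before thinning.
#'
#' @param meta Sample metadata.
#' @param features Feature `data.frame`/matrix with `sample_id` rownames or a
#'   `sample_id` column; one row per sample in `meta`.
#' @return List with filtered `meta` and `features`.
#' @export
drop_missing_features <- function(meta, features) {
  feat <- features
  if (!is.null(feat$sample_id)) {
    rownames(feat) <- feat$sample_id
    feat$sample_id <- NULL
  }
  feat <- feat[match(meta$sample_id, rownames(feat)), , drop = FALSE]
  ok <- stats::complete.cases(feat)
  if (any(!ok)) {
    message(sum(!ok), " sample(s) with missing feature values dropped")
  }
  list(meta = meta[ok, , drop = FALSE], features = feat[ok, , drop = FALSE])
}

# internal: metadata schema check shared by the preprocess stages
check_meta <- function(meta) {
  need <- c("sample_id", "latitude", "longitude", "date",
            "sampling_depth_m", "seafloor_depth_m", "size_fraction")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(abs(meta$latitude) > 90, na.rm = TRUE)) stop("latitude out of range")
  if (any(meta$longitude <= -180 | meta$longitude > 180, na.rm = TRUE)) {
    stop("longitude out of range (-180, 180]")
  }
  invisible(meta)
}

# internal: normalize dates to "YYYY-MM"
format_year_month <- function(x) {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}", x)
  if (!all(ok)) stop("dates must be parseable as YYYY-MM")
  substr(x, 1L, 7L)
}
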