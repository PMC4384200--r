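#' @keywords internal
"_PACKAGE"

SITE_TYPES <- c("aqs", "fixed", "home", "snapshot", "reference", "distributed")

# long-series tiers used for trend estimation and PLS outcomes
LONG_SERIES_TYPES <- c("aqs", "fixed", "reference")

#' Site table constructor
#'
#' Validates and normalises a table of monitoring or prediction sites.
#' Coordinates may be supplied either as planar km (`x_km`, `y_km`) or as
#' `lon`/`lat`, in which case they are projected to a planar km grid by an
#' equirectangular projection about the table centroid (adequate at the
#' ~75 km metropolitan scale this model targets; all distances downstream are
#' Euclidean km).
#'
#' @param df data.frame with columns `site_id`, `site_type`, and either
#'   `x_km`/`y_km` or `lon`/`lat`; optional `cluster_id` (snapshot sites only).
#' @return data.frame of class `st_sites` with columns `site_id`, `site_type`,
#'   `x_km`, `y_km`, `cluster_id`.
#' @export
st_sites <- function(df) {
  stopifnot(is.data.frame(df), all(c("site_id", "site_type") %in% names(df)))
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) {
    stop("duplicate site_id: ", paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  }
  df$site_type <- as.character(df$site_type)
  bad <- setdiff(unique(df$site_type), SITE_TYPES)
  if (length(bad)) stop("unknown site_type: ", paste(bad, collapse = ", "))
  if (!all(c("x_km", "y_km") %in% names(df))) {
    if (!all(c("lon", "lat") %in% names(df))) {
      stop("sites need x_km/y_km or lon/lat columns")
    }
    xy <- project_lonlat(df$lon, df$lat)
    df$x_km <- xy$x_km
    df$y_km <- xy$y_km
  }
  if (!all(is.finite(df$x_km)) || !all(is.finite(df$y_km))) {
    stop("non-finite site coordinates")
  }
  if (is.null(df$cluster_id)) df$cluster_id <- NA_character_
  df$cluster_id <- as.character(df$cluster_id)
  df$cluster_id[!is.na(df$cluster_id) & df$cluster_id == ""] <- NA_character_
  is_snap <- df$site_type == "snapshot"
  if (any(is_snap & is.na(df$cluster_id))) {
    stop("snapshot sites must carry a cluster_id")
  }
  if (any(!is_snap & !is.na(df$cluster_id))) {
    stop("cluster_id is only meaningful for snapshot sites")
  }
  keep <- c("site_id", "site_type", "x_km", "y_km", "cluster_id",
            intersect(c("lon", "lat"), names(df)))
  out <- df[, keep, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("st_sites", "data.frame")
  out
}

#' Equirectangular projection to planar km about the centroid
#'
#' @param lon,lat numeric degree vectors.
#' @param origin optional `c(lon0, lat0)`; defaults to the centroid.
#' @return list with `x_km`, `y_km`, `origin`.
#' @export
project_lonlat <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(origin[2] * pi / 180)
  list(
    x_km = (lon - origin[1]) * km_per_deg_lon,
    y_km = (lat - origin[2]) * km_per_deg_lat,
    origin = origin
  )
}

#' Spatiotemporal monitoring dataset
#'
#' The central observable: a sparse site-by-period collection of two-week
#' average concentrations (log scale once [log_transform()] has been applied),
#' with site metadata, the two-week [build_time_axis()] grid, and the
#' site-by-covariate table used for mean modeling.
#'
#' @param obs data.frame with columns `site_id`, `t` (period index into
#'   `axis`), `value`; at most one value per (site, period).
#' @param sites an [st_sites()] table covering every `site_id` in `obs`.
#' @param axis an [build_time_axis()] object.
#' @param covariates optional data.frame: `site_id` plus one numeric column per
#'   geographic covariate.
#' @param log_scale logical; `TRUE` once values are natural-log concentrations.
#' @param units free-text original measurement units (e.g. `"ug/m3"`, `"ppb"`).
#' @return object of class `st_dataset`.
#' @export
st_dataset <- function(obs, sites, axis, covariates = NULL,
                       log_scale = FALSE, units = "ug/m3") {
  if (!inherits(sites, "st_sites")) sites <- st_sites(sites)
  stopifnot(inherits(axis, "st_time_axis"))
  stopifnot(is.data.frame(obs), all(c("site_id", "t", "value") %in% names(obs)))
  obs <- data.frame(
    site_id = as.character(obs$site_id),
    t = as.integer(obs$t),
    value = as.numeric(obs$value),
    stringsAsFactors = FALSE
  )
  if (nrow(obs)) {
    if (any(obs$t < 1L | obs$t > length(axis))) stop("period index outside axis")
    if (!all(is.finite(obs$value))) stop("non-finite observation values")
    key <- paste(obs$site_id, obs$t)
    if (anyDuplicated(key)) {
      stop("duplicate (site, period) observations: ",
           paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
    }
    missing_sites <- setdiff(obs$site_id, sites$site_id)
    if (length(missing_sites)) {
      stop("observations at unknown sites: ", paste(utils::head(missing_sites, 5), collapse = ", "))
    }
    obs <- obs[order(obs$t, match(obs$site_id, sites$site_id)), , drop = FALSE]
    rownames(obs) <- NULL
  }
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), "site_id" %in% names(covariates))
    covariates$site_id <- as.character(covariates$site_id)
    if (anyDuplicated(covariates$site_id)) stop("duplicate site_id in covariates")
  }
  structure(
    list(obs = obs, sites = sites, axis = axis, covariates = covariates,
         log_scale = isTRUE(log_scale), units = units),
    class = "st_dataset"
  )
}

#' @export
print.st_dataset <- function(x, ...) {
  tab <- table(x$sites$site_type)
  cat("<st_dataset> ", nrow(x$obs), " observations at ", nrow(x$sites),
      " sites over ", length(x$axis), " two-week periods\n", sep = "")
  cat("  site types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  scale:", if (x$log_scale) "log" else "original", paste0("(", x$units, ")"), "\n")
  invisible(x)
}

#' Subset a dataset to selected sites
#'
#' @param data an [st_dataset()].
#' @param site_ids character vector of sites to keep.
#' @return an [st_dataset()] restricted to those sites.
#' @export
subset_sites <- function(data, site_ids) {
  stopifnot(inherits(data, "st_dataset"))
  sites <- data$sites[data$sites$site_id %in% site_ids, , drop = FALSE]
  class(sites) <- c("st_sites", "data.frame")
  obs <- data$obs[data$obs$site_id %in% site_ids, , drop = FALSE]
  cov <- data$covariates
  if (!is.null(cov)) cov <- cov[cov$site_id %in% site_ids, , drop = FALSE]
  st_dataset(obs, sites, data$axis, cov, data$log_scale, data$units)
}

#' Read a dataset from the package's CSV dialects
#'
#' `observations.csv` columns: `site_id, site_type, date, resolution, value`
#' and optional `lod`; `sites.csv` columns: `site_id, site_type, lon, lat,
#' cluster_id` (or `x_km`/`y_km`); `covariates.csv`: `site_id` plus one column
#' per covariate. Two-week resolution observations are assigned to axis
#' periods (with one-week realignment where needed); finer resolutions must be
#' aggregated with [aggregate_to_periods()] first.
#'
#' @param obs_csv,sites_csv path to CSV files; `covariates_csv` optional.
#' @param axis an [build_time_axis()] grid; if `NULL` one is built spanning
#'   the observed dates.
#' @param units unit label recorded on the dataset.
#' @return an [st_dataset()] on the original (pre-log) scale. Below-LOD values
#'   are substituted with LOD/2 when an `lod` column is present.
#' @export
read_st_dataset <- function(obs_csv, sites_csv, covariates_csv = NULL,
                            axis = NULL, units = "ug/m3") {
  sites <- st_sites(utils::read.csv(sites_csv, stringsAsFactors = FALSE))
  raw <- utils::read.csv(obs_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "date", "value") %in% names(raw)))
  raw$date <- as.Date(raw$date)
  if (is.null(raw$resolution)) raw$resolution <- "2week"
  if (!all(raw$resolution %in% "2week")) {
    stop("read_st_dataset() ingests 2-week observations; aggregate finer resolutions with aggregate_to_periods()")
  }
  if (is.null(axis)) {
    axis <- build_time_axis(min(raw$date), max(raw$date) + 14L)
  }
  if (!is.null(raw$lod)) {
    has_lod <- !is.na(raw$lod)
    raw$value[has_lod] <- substitute_lod(raw$value[has_lod], raw$lod[has_lod])
  }
  t_idx <- realign_offgrid_sample(raw$date, axis)
  obs <- data.frame(site_id = raw$site_id, t = t_idx, value = raw$value)
  covariates <- if (!is.null(covariates_csv)) {
    utils::read.csv(covariates_csv, stringsAsFactors = FALSE)
  }
  st_dataset(obs, sites, axis, covariates, log_scale = FALSE, units = units)
}

#' Write a dataset to the package's CSV dialects
#'
#' Writes `observations.csv`, `sites.csv` and (when present)
#' `covariates.csv` under `dir`. Reading them back with [read_st_dataset()]
#' using the same axis reproduces the dataset.
#'
#' @param data an [st_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_st_dataset <- function(data, dir) {
  stopifnot(inherits(data, "st_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs_out <- data.frame(
    site_id = data$obs$site_id,
    site_type = data$sites$site_type[match(data$obs$site_id, data$sites$site_id)],
    date = format(data$axis[data$obs$t]),
    resolution = "2week",
    value = data$obs$value
  )
  utils::write.csv(obs_out, file.path(dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(data$sites), file.path(dir, "sites.csv"), row.names = FALSE)
  if (!is.null(data$covariates)) {
    utils::write.csv(data$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  invisible(dir)
}

# covariate matrix (sites x covariates) aligned to given site ids
covariate_matrix <- function(covariates, site_ids) {
  stopifnot(is.data.frame(covariates))
  idx <- match(site_ids, covariates$site_id)
  if (anyNA(idx)) {
    stop("covariates missing for sites: ",
         paste(utils::head(site_ids[is.na(idx)], 5), collapse = ", "))
  }
  num <- covariates[idx, setdiff(names(covariates), "site_id"), drop = FALSE]
  m <- as.matrix(num)
  storage.mode(m) <- "double"
  rownames(m) <- site_ids
  m
}
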