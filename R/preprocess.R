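#' Substitute values below the limit of detection
#'
#' Concentrations below the instrument limit of detection (LOD) are replaced
#' with LOD/2, the conventional substitution for left-censored monitoring
#' data; values at or above the LOD pass through unchanged.
#'
#' @param value numeric concentrations (original scale).
#' @param lod positive limit(s) of detection, recycled against `value`.
#' @return numeric vector with below-LOD entries replaced by `lod / 2`.
#' @export
substitute_lod <- function(value, lod) {
  if (any(!is.finite(lod) | lod <= 0)) stop("lod must be positive")
  ifelse(value < lod, lod / 2, value)
}

#' Aggregate raw observations to the two-week grid
#'
#' Hourly data are first averaged to daily means, then daily means to
#' two-week period means on the axis grid. A daily mean is formed only when at
#' least `completeness_min` of the 24 hours are present; a period mean only
#' when at least `completeness_min` of the 14 days are present. Incomplete
#' periods are absent from the result, never zero. Native two-week samples are
#' assigned directly (with one-week realignment for off-grid starts).
#'
#' @param raw data.frame with columns `site_id`, `date` (`Date` for
#'   daily/2-week rows; POSIXct or `date` + `hour` for hourly rows),
#'   `resolution` in `{"hourly","daily","2week"}`, `value`, optional `lod`.
#' @param axis a [build_time_axis()] grid.
#' @param completeness_min required fraction of sub-intervals present at each
#'   aggregation step, in `[0, 1]`; defaults to the conventional 75%
#'   regulatory completeness criterion.
#' @return data.frame `site_id, t, value` of period means on the original
#'   scale, suitable for [st_dataset()]. LOD substitution, when an `lod`
#'   column is present, is applied at the native resolution before averaging.
#' @export
aggregate_to_periods <- function(raw, axis, completeness_min = 0.75) {
  stopifnot(is.data.frame(raw), all(c("site_id", "date", "resolution", "value") %in% names(raw)))
  stopifnot(completeness_min >= 0, completeness_min <= 1)
  bad_res <- setdiff(unique(raw$resolution), c("hourly", "daily", "2week"))
  if (length(bad_res)) stop("unknown resolution: ", paste(bad_res, collapse = ", "))
  if (!is.null(raw$lod)) {
    has <- !is.na(raw$lod)
    raw$value[has] <- substitute_lod(raw$value[has], raw$lod[has])
  }

  pieces <- list()

  hourly <- raw[raw$resolution == "hourly", , drop = FALSE]
  daily <- raw[raw$resolution == "daily", , drop = FALSE]
  if (nrow(hourly)) {
    day <- as.Date(hourly$date)
    key <- paste(hourly$site_id, day, sep = "\r")
    n_h <- tapply(hourly$value, key, length)
    mu_h <- tapply(hourly$value, key, mean)
    ok <- n_h >= completeness_min * 24
    if (any(ok)) {
      parts <- do.call(rbind, strsplit(names(mu_h)[ok], "\r", fixed = TRUE))
      daily <- rbind(
        daily[, c("site_id", "date", "resolution", "value")],
        data.frame(
          site_id = parts[, 1], date = as.Date(parts[, 2]),
          resolution = "daily", value = as.numeric(mu_h[ok])
        )
      )
    }
  }
  if (nrow(daily)) {
    t_idx <- assign_period(as.Date(daily$date), axis)
    keep <- !is.na(t_idx)
    key <- paste(daily$site_id[keep], t_idx[keep], sep = "\r")
    n_d <- tapply(daily$value[keep], key, length)
    mu_d <- tapply(daily$value[keep], key, mean)
    ok <- n_d >= completeness_min * 14
    if (any(ok)) {
      parts <- do.call(rbind, strsplit(names(mu_d)[ok], "\r", fixed = TRUE))
      pieces$daily <- data.frame(
        site_id = parts[, 1], t = as.integer(parts[, 2]),
        value = as.numeric(mu_d[ok])
      )
    }
  }
  twoweek <- raw[raw$resolution == "2week", , drop = FALSE]
  if (nrow(twoweek)) {
    pieces$twoweek <- data.frame(
      site_id = twoweek$site_id,
      t = realign_offgrid_sample(as.Date(twoweek$date), axis),
      value = twoweek$value
    )
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(site_id = character(), t = integer(), value = numeric())
  rownames(out) <- NULL
  out[order(out$t, out$site_id), , drop = FALSE]
}

#' Exclude regulatory monitors with short or irregular records
#'
#' Removes `aqs`-type sites whose observed span is shorter than `min_years`
#' or whose temporal coverage is irregular: a site is irregular when any
#' calendar quarter holds less than `quarter_min_frac` of its observations
#' (which catches e.g. summer-only monitors). Study-specific home and snapshot
#' sites, designed to be temporally sparse, are never removed.
#'
#' @param data an [st_dataset()].
#' @param min_years minimum observed span in years for `aqs` sites.
#' @param quarter_min_frac minimum fraction of a site's observations that each
#'   calendar quarter must hold; set to 0 to disable the regularity rule.
#' @return list with `data` (filtered [st_dataset()]) and `report` (a
#'   `filter_report` carrying `excluded_sites`).
#' @export
filter_monitors <- function(data, min_years = 2, quarter_min_frac = 0.10) {
  stopifnot(inherits(data, "st_dataset"), nrow(data$obs) > 0)
  excluded <- data.frame(site_id = character(), reason = character())
  aqs_ids <- data$sites$site_id[data$sites$site_type == "aqs"]
  for (sid in aqs_ids) {
    tt <- data$obs$t[data$obs$site_id == sid]
    if (!length(tt)) {
      excluded <- rbind(excluded, data.frame(site_id = sid, reason = "no_observations"))
      next
    }
    dates <- data$axis[tt]
    span_years <- as.numeric(max(dates) - min(dates) + 14) / 365.25
    if (span_years < min_years) {
      excluded <- rbind(excluded, data.frame(site_id = sid, reason = "short_record"))
      next
    }
    q <- quarters(dates)
    frac <- table(factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))) / length(q)
    if (any(frac < quarter_min_frac)) {
      excluded <- rbind(excluded, data.frame(site_id = sid, reason = "irregular_coverage"))
    }
  }
  keep <- setdiff(data$sites$site_id, excluded$site_id)
  report <- structure(
    list(excluded_sites = excluded, excluded_covariates = NULL, n_below_lod = NULL),
    class = "filter_report"
  )
  list(data = subset_sites(data, keep), report = report)
}

#' Exclude geographic covariates with minimal variation or influential values
#'
#' Applies four exclusion rules to each covariate, computed over the
#' monitoring sites (and participant locations for rule c):
#' \describe{
#'   \item{a_constant}{the modal value occurs at more than `modal_max` (80%)
#'     of monitoring sites;}
#'   \item{b_outlier}{more than `outlier_max` (2%) of monitoring-site values
#'     lie more than `outlier_sd` (5) SDs from the monitoring-site mean;}
#'   \item{c_extrapolation}{the SD over participant locations exceeds
#'     `sd_ratio_max` (5) times the SD over monitoring locations;}
#'   \item{d_landuse_max}{for land-use fraction variables only, the maximum
#'     over all monitoring sites is at most `landuse_max` (10%).}
#' }
#' A covariate violating several rules is attributed to the first in a--d
#' order; all violations are also logged.
#'
#' @param covariates data.frame: `site_id` plus numeric covariate columns.
#' @param monitor_ids,participant_ids character vectors of site ids indexing
#'   rows of `covariates`.
#' @param landuse_names covariate names subject to rule d.
#' @param modal_max,outlier_max,outlier_sd,sd_ratio_max,landuse_max rule
#'   thresholds (see above).
#' @return a `filter_report` with `excluded_covariates` (name, rule),
#'   `violations` (all rule hits) and `kept` (retained covariate names).
#' @export
filter_covariates <- function(covariates, monitor_ids, participant_ids = character(),
                              landuse_names = character(),
                              modal_max = 0.80, outlier_max = 0.02, outlier_sd = 5,
                              sd_ratio_max = 5, landuse_max = 0.10) {
  stopifnot(is.data.frame(covariates), "site_id" %in% names(covariates))
  if (!length(monitor_ids)) stop("empty monitoring-site set")
  M <- covariate_matrix(covariates, monitor_ids)
  P <- if (length(participant_ids)) covariate_matrix(covariates, participant_ids)
  vio <- list()
  for (nm in colnames(M)) {
    v <- M[, nm]
    hits <- character()
    if (max(table(v)) > modal_max * length(v)) hits <- c(hits, "a_constant")
    s <- stats::sd(v)
    if (s > 0 && mean(abs(v - mean(v)) > outlier_sd * s) > outlier_max) {
      hits <- c(hits, "b_outlier")
    }
    if (!is.null(P)) {
      sp <- stats::sd(P[, nm])
      if (s > 0 && sp > sd_ratio_max * s) hits <- c(hits, "c_extrapolation")
    }
    if (nm %in% landuse_names && max(v) <= landuse_max) hits <- c(hits, "d_landuse_max")
    if (length(hits)) vio[[nm]] <- hits
  }
  violations <- if (length(vio)) {
    data.frame(
      name = rep(names(vio), lengths(vio)),
      rule = unlist(vio, use.names = FALSE)
    )
  } else data.frame(name = character(), rule = character())
  excluded <- if (length(vio)) {
    data.frame(name = names(vio), rule = vapply(vio, `[`, "", 1L))
  } else data.frame(name = character(), rule = character())
  rownames(excluded) <- NULL
  structure(
    list(
      excluded_covariates = excluded,
      violations = violations,
      kept = setdiff(colnames(M), excluded$name),
      excluded_sites = NULL, n_below_lod = NULL
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  if (!is.null(x$excluded_covariates) && nrow(x$excluded_covariates)) {
    cat("  excluded covariates:\n")
    print(x$excluded_covariates, row.names = FALSE)
  }
  if (!is.null(x$excluded_sites) && nrow(x$excluded_sites)) {
    cat("  excluded sites:\n")
    print(x$excluded_sites, row.names = FALSE)
  }
  invisible(x)
}

#' Natural-log transform a dataset
#'
#' @param data an [st_dataset()] on the original concentration scale with
#'   strictly positive values (guaranteed after LOD substitution).
#' @return the dataset with `value = log(value)` and `log_scale = TRUE`.
#' @export
log_transform <- function(data) {
  stopifnot(inherits(data, "st_dataset"))
  if (data$log_scale) stop("dataset already on the log scale")
  bad <- data$obs$value <= 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(
      "nonpositive concentration at site ", data$obs$site_id[i],
      ", period ", data$obs$t[i], "; apply LOD substitution first"
    )
  }
  data$obs$value <- log(data$obs$value)
  data$log_scale <- TRUE
  data
}
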