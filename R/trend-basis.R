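#' EM-style imputation of missing entries by low-rank SVD reconstruction
#'
#' Iteratively fills missing entries of a time-by-site matrix with the current
#' rank-`k` SVD reconstruction (initialised from column means), recomputing
#' the SVD each pass, until the root-mean-square change of the imputed entries
#' falls below `tol` or `max_iter` is reached. Observed entries are never
#' altered. This is the standard EM treatment of missing data for empirical
#' orthogonal function extraction from gappy series.
#'
#' @param series_matrix numeric T-by-n matrix with `NA` for missing entries;
#'   every column needs at least 2 observed entries.
#' @param k reconstruction rank (>= 1).
#' @param tol convergence tolerance on the RMS change of imputed entries.
#' @param max_iter iteration cap.
#' @return the completed matrix (observed entries untouched), with attribute
#'   `iterations`.
#' @export
em_impute <- function(series_matrix, k, tol = 1e-8, max_iter = 200) {
  X <- as.matrix(series_matrix)
  stopifnot(k >= 1)
  miss <- is.na(X)
  n_obs_col <- colSums(!miss)
  if (any(n_obs_col < 2)) {
    stop("column(s) with fewer than 2 observed entries: ",
         paste(utils::head(which(n_obs_col < 2), 5), collapse = ", "))
  }
  if (!any(miss)) {
    attr(X, "iterations") <- 0L
    return(X)
  }
  k <- min(k, nrow(X), ncol(X))
  # init: column means
  cm <- colMeans(X, na.rm = TRUE)
  X[miss] <- cm[col(X)[miss]]
  it <- 0L
  repeat {
    it <- it + 1L
    sv <- svd(X, nu = k, nv = k)
    recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    delta <- sqrt(mean((X[miss] - recon[miss])^2))
    X[miss] <- recon[miss]
    if (delta < tol || it >= max_iter) break
  }
  attr(X, "iterations") <- it
  X
}

#' Extract raw temporal trends by singular value decomposition
#'
#' Column-centres the completed time-by-site matrix (removing each site's
#' mean, which belongs to the long-term average, not the trends) and returns
#' the left singular vectors of the top `m` singular values as raw trends,
#' ordered by decreasing singular value. Each trend's sign is fixed so that
#' its loading on the first site is positive, making the decomposition
#' deterministic.
#'
#' @param completed numeric T-by-n matrix with no missing entries.
#' @param m number of trends, `m < min(T, n)`.
#' @return T-by-m matrix of raw trends with attribute `singular_values` (all
#'   of them, for scree diagnostics).
#' @export
derive_raw_trends <- function(completed, m) {
  X <- as.matrix(completed)
  stopifnot(!anyNA(X))
  if (m >= min(dim(X))) stop("m must be < min(T, n)")
  Xc <- sweep(X, 2L, colMeans(X))
  if (all(abs(Xc) < .Machine$double.eps * 100)) {
    stop("degenerate (zero-variance) series matrix")
  }
  sv <- svd(Xc)
  trends <- sv$u[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    s <- sign(sv$v[1L, j])
    if (s == 0) s <- 1
    trends[, j] <- trends[, j] * s
  }
  attr(trends, "singular_values") <- sv$d
  trends
}

#' Smooth raw trends with natural cubic splines
#'
#' Each raw trend is replaced by its least-squares projection onto a natural
#' cubic spline basis in time with total degrees of freedom
#' `round(df_per_year * span_in_years)` (knots at time quantiles, equally
#' spaced on the regular two-week grid). Smoothed trends are re-normalised to
#' zero mean and unit root-mean-square over the grid.
#'
#' @param raw T-by-m matrix of raw trends.
#' @param axis the [build_time_axis()] grid (length T).
#' @param df_per_year smoothing degrees of freedom per year (4 or 8 in the
#'   model-selection grid, but any positive value is accepted).
#' @return a `trend_basis` object (see [estimate_trend_basis()]).
#' @export
smooth_trends <- function(raw, axis, df_per_year) {
  raw <- as.matrix(raw)
  T_ <- nrow(raw)
  stopifnot(inherits(axis, "st_time_axis"), length(axis) == T_)
  span_years <- (T_ * 14) / 365.25
  df_total <- max(2L, round(df_per_year * span_years))
  if (df_total >= T_) stop("total spline df (", df_total, ") must be < T (", T_, ")")
  tt <- seq_len(T_)
  B <- cbind(1, splines::ns(tt, df = df_total))
  fit <- stats::lm.fit(B, raw)
  sm <- as.matrix(fit$fitted.values)
  sm <- normalize_trends(sm)
  trend_basis(sm, axis, df_per_year = df_per_year)
}

# zero-mean, unit-RMS columns (scale is absorbed by the beta coefficients;
# fixing it makes the parameterisation identifiable)
normalize_trends <- function(f) {
  f <- sweep(f, 2L, colMeans(f))
  rms <- sqrt(colMeans(f^2))
  if (any(rms == 0)) stop("degenerate trend with zero variance after centering")
  sweep(f, 2L, rms, "/")
}

#' Trend basis constructor
#'
#' Holds the `m` smoothed non-constant temporal basis functions `f_1..f_m`
#' on the two-week grid. The constant trend `f_0 = 1` is implicit: it
#' multiplies the long-term mean field and is not stored.
#'
#' @param values T-by-m numeric matrix, columns zero-mean and unit-RMS.
#' @param axis the [build_time_axis()] grid.
#' @param df_per_year smoothing df per year used (NA if not smoothed).
#' @param source_sites ids of the long-series sites the basis was derived from.
#' @param singular_values singular values from the underlying SVD.
#' @return object of class `trend_basis` with fields `m`, `values`, `axis`,
#'   `df_per_year`, `source_sites`, `singular_values`.
#' @export
trend_basis <- function(values, axis, df_per_year = NA_real_,
                        source_sites = character(), singular_values = numeric()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(axis))
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(
    list(
      m = ncol(values), values = values, axis = axis,
      df_per_year = df_per_year, source_sites = source_sites,
      singular_values = singular_values
    ),
    class = "trend_basis"
  )
}

#' @export
print.trend_basis <- function(x, ...) {
  cat("<trend_basis> m =", x$m, "smooth trend(s) over", nrow(x$values),
      "periods; df/year =", x$df_per_year, "\n")
  invisible(x)
}

#' Evaluate the full trend design (including the implicit constant trend)
#'
#' @param basis a [trend_basis()].
#' @param t integer period indices.
#' @return length(t) x (m+1) matrix with first column 1 (`f0`).
#' @export
trend_design <- function(basis, t) {
  cbind(f0 = 1, basis$values[t, , drop = FALSE])
}

#' Estimate the smooth temporal basis from long-series sites
#'
#' Composition of [em_impute()], [derive_raw_trends()] and [smooth_trends()]:
#' the time series of the long-series site tiers (regulatory, fixed and
#' reference sites, which have multi-year records) are assembled into a
#' time-by-site matrix, missing stretches are EM-imputed at rank `m + 1`
#' (capped at n-1), raw trends extracted by SVD of the column-centred matrix,
#' and smoothed by spline projection. The basis is estimated once and held
#' fixed through model fitting and cross-validation.
#'
#' @param data an [st_dataset()] on the log scale.
#' @param m number of non-constant trends (1 or 2 in the selection grid).
#' @param df_per_year spline smoothness, df per year (4 or 8 in the grid).
#' @param site_types site tiers supplying the series.
#' @param min_obs minimum observations for a site's series to be used.
#' @return a [trend_basis()] with `source_sites` recorded.
#' @export
estimate_trend_basis <- function(data, m, df_per_year,
                                 site_types = LONG_SERIES_TYPES, min_obs = 2L) {
  stopifnot(inherits(data, "st_dataset"))
  ids <- data$sites$site_id[data$sites$site_type %in% site_types]
  n_by_site <- table(data$obs$site_id)
  ids <- ids[ids %in% names(n_by_site)[n_by_site >= min_obs]]
  if (length(ids) < 2) stop("need >= 2 long-series sites to estimate trends")
  T_ <- length(data$axis)
  M <- matrix(NA_real_, T_, length(ids), dimnames = list(NULL, ids))
  sel <- data$obs$site_id %in% ids
  M[cbind(data$obs$t[sel], match(data$obs$site_id[sel], ids))] <- data$obs$value[sel]
  k <- min(m + 1L, length(ids) - 1L)
  completed <- em_impute(M, k = k)
  raw <- derive_raw_trends(completed, m)
  basis <- smooth_trends(raw, data$axis, df_per_year)
  basis$source_sites <- ids
  basis$singular_values <- attr(raw, "singular_values")
  basis
}

#' Lag-1 autocorrelation diagnostic for post-fit residuals
#'
#' The model assumes the smooth trends absorb enough temporal structure that
#' residuals are independent in time. This diagnostic fits each source site's
#' series on the trend design by OLS and reports the per-site lag-1
#' autocorrelation of the residuals and their mean; values far from zero
#' suggest more trends or more df are needed.
#'
#' @param data an [st_dataset()] on the log scale.
#' @param basis a [trend_basis()].
#' @param site_ids sites to assess (default: the basis source sites).
#' @return list with `per_site` (named vector) and `mean_lag1`.
#' @export
residual_autocorrelation <- function(data, basis, site_ids = basis$source_sites) {
  out <- numeric(0)
  for (sid in site_ids) {
    rows <- data$obs$site_id == sid
    t <- data$obs$t[rows]
    if (length(t) < basis$m + 3L) next
    y <- data$obs$value[rows][order(t)]
    t <- sort(t)
    F <- trend_design(basis, t)
    r <- stats::lm.fit(F, y)$residuals
    # lag-1 in period index: only adjacent-period pairs count
    adj <- which(diff(t) == 1L)
    if (length(adj) < 3L) next
    out[sid] <- stats::cor(r[adj], r[adj + 1L])
  }
  list(per_site = out, mean_lag1 = mean(out))
}
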