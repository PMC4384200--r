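#' Cross-validation fold assignment
#'
#' Three schemes mirror the monitoring tiers: leave-one-out (`"loo"`) for the
#' small set of long-series sites, 10-fold (`"kfold10"`) for home-type sites,
#' and clustered 10-fold (`"kfold10_clustered"`) for snapshot sites, where
#' all monitors sharing a `cluster_id` are left out together.
#'
#' @param sites an [st_sites()] table (or data.frame with `site_id`, and
#'   `cluster_id` for the clustered scheme) of the sites to cross-validate.
#' @param scheme `"loo"`, `"kfold10"` or `"kfold10_clustered"`.
#' @param seed integer seed for the random fold assignment.
#' @param k number of folds for the k-fold schemes (default 10; capped at the
#'   number of sites or clusters).
#' @return data.frame of class `fold_plan` with `site_id`, `fold`; attributes
#'   `scheme` and `seed`. Fold sizes differ by at most one site (one cluster
#'   for the clustered scheme) and clusters are never split.
#' @export
make_folds <- function(sites, scheme = c("loo", "kfold10", "kfold10_clustered"),
                       seed = 1L, k = 10L) {
  scheme <- match.arg(scheme)
  ids <- as.character(sites$site_id)
  if (length(ids) < 2L) stop("need at least 2 sites to cross-validate")
  set.seed(seed)
  if (scheme == "loo") {
    fold <- seq_along(ids)
  } else if (scheme == "kfold10") {
    k <- min(k, length(ids))
    fold <- sample(rep_len(seq_len(k), length(ids)))
  } else {
    cl <- if (is.null(sites$cluster_id)) rep(NA_character_, length(ids))
          else as.character(sites$cluster_id)
    if (any(is.na(cl) | cl == "")) stop("clustered scheme requires cluster_id on every site")
    clusters <- unique(cl)
    if (length(clusters) < 2L) stop("need at least 2 clusters")
    k <- min(k, length(clusters))
    cl_fold <- sample(rep_len(seq_len(k), length(clusters)))
    names(cl_fold) <- sample(clusters)
    fold <- cl_fold[cl]
  }
  out <- data.frame(site_id = ids, fold = as.integer(fold))
  attr(out, "scheme") <- scheme
  attr(out, "seed") <- seed
  class(out) <- c("fold_plan", "data.frame")
  out
}

#' Cross-validation metrics for site means
#'
#' `rmse` is the root mean squared difference between observed and predicted
#' site means on the original concentration scale. `r2_cv` is the MSE-based
#' R-squared `max(0, 1 - RMSE^2 / MSE_obs)` with
#' `MSE_obs = mean((y_j - ybar)^2)`; it measures fit to the 1-1 line and is 0
#' whenever predictions do no better than the observed grand mean.
#' `r2_cvreg` is the squared correlation between predictions and
#' observations, which measures fit to the regression line and is reported
#' for comparability only.
#'
#' @param y observed site means (original scale).
#' @param yhat predicted site means (original scale).
#' @return list `rmse`, `r2_cv`, `r2_cvreg`, `mse_obs`, `n`.
#' @export
cv_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  rmse <- sqrt(mean((y - yhat)^2))
  mse_obs <- mean((y - mean(y))^2)
  r2_cv <- max(0, 1 - rmse^2 / mse_obs)
  r2_cvreg <- if (stats::sd(yhat) == 0 || stats::sd(y) == 0) 0 else stats::cor(y, yhat)^2
  list(rmse = rmse, r2_cv = r2_cv, r2_cvreg = r2_cvreg, mse_obs = mse_obs,
       n = length(y))
}

#' Site-type-stratified cross-validation of the fitted model
#'
#' For each fold: the covariance parameters (and, as their GLS by-products,
#' the mean coefficients) are re-estimated by maximum likelihood on the
#' retained sites; the time trends and PLS score definitions are *not*
#' re-estimated — they stay as computed on the full data. Concentrations at
#' the left-out sites are then predicted at their observed periods,
#' back-transformed, and averaged into predicted site means.
#'
#' @param data an [st_dataset()] on the log scale (all site types; the model
#'   conditions on every retained observation).
#' @param basis a [trend_basis()] estimated on the full data.
#' @param features a [build_feature_set()] computed on the full data.
#' @param structure an [st_structure()].
#' @param plan a [make_folds()] plan over the evaluation sites.
#' @param n_starts,seed,control passed to [fit_ml()].
#' @return object of class `cv_report`: `per_site` (data.frame `site_id`,
#'   `fold`, `n_obs`, `y`, `yhat`), the [cv_metrics()] fields, and the plan
#'   attributes.
#' @export
cross_validate <- function(data, basis, features, structure, plan,
                           n_starts = 1L, seed = 1L, control = list()) {
  stopifnot(inherits(plan, "fold_plan"))
  eval_ids <- plan$site_id
  missing <- setdiff(eval_ids, data$sites$site_id)
  if (length(missing)) stop("fold plan names unknown sites: ", paste(missing, collapse = ", "))
  rows <- list()
  for (f in sort(unique(plan$fold))) {
    out_ids <- plan$site_id[plan$fold == f]
    keep_ids <- setdiff(data$sites$site_id, out_ids)
    # retained sites must still support a fit
    n_kept_obs <- sum(data$obs$site_id %in% keep_ids)
    if (length(unique(data$obs$site_id[data$obs$site_id %in% keep_ids])) < 2L) {
      stop("fold ", f, " leaves fewer than 2 observed sites")
    }
    train <- subset_sites(data, keep_ids)
    fit <- fit_ml(train, basis, features, structure,
                  n_starts = n_starts, seed = seed, control = control)
    out_obs <- data$obs[data$obs$site_id %in% out_ids, , drop = FALSE]
    if (!nrow(out_obs)) next
    targets <- as.data.frame(data$sites[data$sites$site_id %in% out_ids, , drop = FALSE])
    pr <- predict(fit, targets = targets, covariates = data$covariates,
                  periods = sort(unique(out_obs$t)))
    for (sid in unique(out_obs$site_id)) {
      tt <- out_obs$t[out_obs$site_id == sid]
      yobs <- exp(out_obs$value[out_obs$site_id == sid])
      ypred <- pr$pred[sid, match(format(data$axis[tt]), colnames(pr$pred))]
      rows[[sid]] <- data.frame(
        site_id = sid, fold = f, n_obs = length(tt),
        y = mean(yobs), yhat = mean(ypred)
      )
    }
  }
  per_site <- do.call(rbind, rows)
  rownames(per_site) <- NULL
  met <- cv_metrics(per_site$y, per_site$yhat)
  structure(
    c(list(per_site = per_site), met,
      list(scheme = attr(plan, "scheme"), seed = attr(plan, "seed"))),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d sites (%s): RMSE %.3f, R2_CV %.3f, R2_CVreg %.3f\n",
              x$n, x$scheme, x$rmse, x$r2_cv, x$r2_cvreg))
  invisible(x)
}

#' Temporally adjusted cross-validation R-squared
#'
#' Replaces the observed-mean reference in the MSE-based R-squared with a
#' reference predictor built from the long-series (regulatory and fixed)
#' sites, isolating spatial prediction accuracy for temporally sparse sites:
#' \describe{
#'   \item{avg}{the cross-site mean of reference observations at the
#'     evaluated site's observed periods;}
#'   \item{close}{the nearest (Euclidean km) reference site's observations at
#'     those periods;}
#'   \item{smooth}{the nearest reference site's OLS-fitted smooth trend curve
#'     evaluated at those periods.}
#' }
#' The metric is `max(0, 1 - RMSE^2 / MSE_ref)` with
#' `MSE_ref = mean((y_j - ref_j)^2)` over evaluated site means, both on the
#' original concentration scale. Site-periods with no reference observation
#' available are dropped and counted.
#'
#' @param report a [cross_validate()] report.
#' @param data the full [st_dataset()] (log scale) the report came from.
#' @param basis the [trend_basis()] (needed for `"smooth"`).
#' @param reference `"avg"`, `"close"` or `"smooth"`.
#' @param ref_types site types providing the reference data.
#' @return list `r2`, `mse_ref`, `rmse`, `reference`, `n_dropped`.
#' @export
r2_temporally_adjusted <- function(report, data, basis,
                                   reference = c("avg", "close", "smooth"),
                                   ref_types = LONG_SERIES_TYPES) {
  reference <- match.arg(reference)
  stopifnot(inherits(report, "cv_report"))
  ref_ids <- data$sites$site_id[data$sites$site_type %in% ref_types]
  ref_ids <- intersect(ref_ids, unique(data$obs$site_id))
  ref_ids <- setdiff(ref_ids, report$per_site$site_id)
  if (!length(ref_ids)) stop("no reference sites with observations")
  ref_obs <- data$obs[data$obs$site_id %in% ref_ids, , drop = FALSE]
  n_dropped <- 0L
  ref_j <- numeric(nrow(report$per_site))
  for (j in seq_len(nrow(report$per_site))) {
    sid <- report$per_site$site_id[j]
    tt <- data$obs$t[data$obs$site_id == sid]
    if (reference == "avg") {
      vals <- vapply(tt, function(t) {
        v <- ref_obs$value[ref_obs$t == t]
        if (length(v)) mean(exp(v)) else NA_real_
      }, 0)
    } else {
      # nearest reference site in projected km
      si <- match(sid, data$sites$site_id)
      d <- sqrt((data$sites$x_km[match(ref_ids, data$sites$site_id)] - data$sites$x_km[si])^2 +
                (data$sites$y_km[match(ref_ids, data$sites$site_id)] - data$sites$y_km[si])^2)
      near <- ref_ids[which.min(d)]
      near_obs <- ref_obs[ref_obs$site_id == near, , drop = FALSE]
      if (reference == "close") {
        vals <- vapply(tt, function(t) {
          v <- near_obs$value[near_obs$t == t]
          if (length(v)) exp(v) else NA_real_
        }, 0)
      } else {
        F <- trend_design(basis, near_obs$t)
        cf <- stats::lm.fit(F, near_obs$value)$coefficients
        vals <- exp(drop(trend_design(basis, tt) %*% cf))
      }
    }
    n_dropped <- n_dropped + sum(is.na(vals))
    ref_j[j] <- mean(vals, na.rm = TRUE)
  }
  ok <- is.finite(ref_j)
  y <- report$per_site$y[ok]
  yhat <- report$per_site$yhat[ok]
  rmse2 <- mean((y - yhat)^2)
  mse_ref <- mean((y - ref_j[ok])^2)
  list(
    r2 = max(0, 1 - rmse2 / mse_ref),
    mse_ref = mse_ref, rmse = sqrt(rmse2),
    reference = reference, n_dropped = n_dropped
  )
}

#' Candidate grid for model selection
#'
#' Enumerates the candidate model structures: number of time trends, spline
#' df per year, PLS scores per trend, and whether the coefficient fields get
#' exponential spatial smoothing or an independence structure — by default
#' the 2 x 2 x 2 x 2 = 16-candidate grid.
#'
#' @param m_options numbers of non-constant trends.
#' @param df_options spline df per year.
#' @param score_options PLS components per trend.
#' @param smooth_options logical: spatial smoothing of the beta fields.
#' @return data.frame with one row per candidate.
#' @export
candidate_grid <- function(m_options = c(1L, 2L), df_options = c(4L, 8L),
                           score_options = c(2L, 3L),
                           smooth_options = c(TRUE, FALSE)) {
  grid <- expand.grid(
    m = m_options, df_per_year = df_options, n_scores = score_options,
    spatial_smooth = smooth_options,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid[order(grid$m, grid$df_per_year, grid$n_scores, !grid$spatial_smooth), ,
       drop = FALSE]
}

#' Model selection over the candidate grid
#'
#' Runs the full stratified cross-validation for every candidate structure
#' and ranks candidates by home-site performance first (R2_CV descending,
#' then RMSE ascending), breaking remaining ties by fixed-site R2_CV —
#' home-site accuracy is prioritized because the spatial contrasts between
#' residences are the target of inference and because home sites play no
#' part in estimating trends or PLS scores, making their metrics honest.
#' Candidates that fail to fit are kept in the table with `NA` metrics and
#' ranked last.
#'
#' @param data an [st_dataset()] on the log scale with covariates.
#' @param grid a [candidate_grid()] (default: the full 16).
#' @param home_scheme,fixed_scheme,snapshot_scheme CV schemes per stratum;
#'   set a stratum's scheme to `NA` to skip it.
#' @param seed integer seed (folds and optimizer starts).
#' @param n_starts optimizer starts per fit.
#' @param control passed to [fit_ml()].
#' @param smooth_beta0,smooth_betai optional logical overrides decoupling the
#'   long-term-average field's structure from the trend-coefficient fields';
#'   by default both follow the grid's `spatial_smooth` column.
#' @return object of class `st_selection`: `table` (one row per candidate
#'   with metrics and rank), `best` (list with the winning structure, basis,
#'   features and reports), `grid`.
#' @export
model_selection_grid <- function(data, grid = candidate_grid(),
                                 home_scheme = "kfold10", fixed_scheme = "loo",
                                 snapshot_scheme = NA, seed = 1L,
                                 n_starts = 1L, control = list(),
                                 smooth_beta0 = NULL, smooth_betai = NULL) {
  stopifnot(inherits(data, "st_dataset"))
  res <- grid
  res$home_r2_cv <- res$home_rmse <- res$fixed_r2_cv <- res$fixed_rmse <- NA_real_
  res$error <- NA_character_
  best <- NULL
  home_ids <- data$sites[data$sites$site_type %in% c("home", "distributed"), , drop = FALSE]
  fixed_ids <- data$sites[data$sites$site_type %in% LONG_SERIES_TYPES, , drop = FALSE]
  snap_ids <- data$sites[data$sites$site_type == "snapshot", , drop = FALSE]
  for (cand in seq_len(nrow(grid))) {
    g <- grid[cand, ]
    out <- tryCatch({
      basis <- estimate_trend_basis(data, m = g$m, df_per_year = g$df_per_year)
      features <- build_feature_set(data, basis, n_comp = g$n_scores)
      b0 <- if (is.null(smooth_beta0)) g$spatial_smooth else smooth_beta0
      bi <- if (is.null(smooth_betai)) g$spatial_smooth else smooth_betai
      kinds <- c(
        if (b0) "exponential" else "independent",
        rep(if (bi) "exponential" else "independent", g$m)
      )
      structure_i <- st_structure(kinds)
      reports <- list()
      if (!is.na(home_scheme) && nrow(home_ids) >= 2L) {
        plan <- make_folds(home_ids, home_scheme, seed = seed)
        reports$home <- cross_validate(data, basis, features, structure_i, plan,
                                       n_starts = n_starts, seed = seed,
                                       control = control)
      }
      if (!is.na(fixed_scheme) && nrow(fixed_ids) >= 2L) {
        plan <- make_folds(fixed_ids, fixed_scheme, seed = seed)
        reports$fixed <- cross_validate(data, basis, features, structure_i, plan,
                                        n_starts = n_starts, seed = seed,
                                        control = control)
      }
      if (!is.na(snapshot_scheme) && nrow(snap_ids) >= 2L) {
        plan <- make_folds(snap_ids, snapshot_scheme, seed = seed)
        reports$snapshot <- cross_validate(data, basis, features, structure_i,
                                           plan, n_starts = n_starts,
                                           seed = seed, control = control)
      }
      list(basis = basis, features = features, structure = structure_i,
           reports = reports, beta0_smooth = b0, betai_smooth = bi)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      res$error[cand] <- conditionMessage(out)
      next
    }
    if (!is.null(out$reports$home)) {
      res$home_r2_cv[cand] <- out$reports$home$r2_cv
      res$home_rmse[cand] <- out$reports$home$rmse
    }
    if (!is.null(out$reports$fixed)) {
      res$fixed_r2_cv[cand] <- out$reports$fixed$r2_cv
      res$fixed_rmse[cand] <- out$reports$fixed$rmse
    }
    if (is.null(best) || rank_better(res[cand, ], res[best$row, ])) {
      best <- list(row = cand, candidate = out)
    }
  }
  if (is.null(best)) stop("every candidate failed to fit")
  ord <- order(!is.na(res$error),
               -ifelse(is.na(res$home_r2_cv), -Inf, res$home_r2_cv),
               ifelse(is.na(res$home_rmse), Inf, res$home_rmse),
               -ifelse(is.na(res$fixed_r2_cv), -Inf, res$fixed_r2_cv))
  res$rank <- match(seq_len(nrow(res)), ord)
  res$beta0_smooth <- ifelse(is.na(res$error),
                             if (is.null(smooth_beta0)) res$spatial_smooth else smooth_beta0, NA)
  res$betai_smooth <- ifelse(is.na(res$error),
                             if (is.null(smooth_betai)) res$spatial_smooth else smooth_betai, NA)
  structure(
    list(table = res[order(res$rank), , drop = FALSE],
         best = best$candidate, grid = grid),
    class = "st_selection"
  )
}

# lexicographic comparison: home R2_CV desc, home RMSE asc, fixed R2_CV desc
rank_better <- function(a, b) {
  av <- c(ifelse(is.na(a$home_r2_cv), -Inf, a$home_r2_cv),
          -ifelse(is.na(a$home_rmse), Inf, a$home_rmse),
          ifelse(is.na(a$fixed_r2_cv), -Inf, a$fixed_r2_cv))
  bv <- c(ifelse(is.na(b$home_r2_cv), -Inf, b$home_r2_cv),
          -ifelse(is.na(b$home_rmse), Inf, b$home_rmse),
          ifelse(is.na(b$fixed_r2_cv), -Inf, b$fixed_r2_cv))
  diff <- av - bv
  nz <- which(diff != 0)
  length(nz) > 0 && diff[nz[1]] > 0
}

#' @export
print.st_selection <- function(x, ...) {
  cat("<st_selection>", nrow(x$table), "candidates; winner:\n")
  w <- x$table[x$table$rank == 1L, , drop = FALSE]
  print(w[, c("m", "n_scores", "df_per_year", "beta0_smooth", "betai_smooth",
              "home_r2_cv", "home_rmse")], row.names = FALSE)
  invisible(x)
}
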