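#' Per-site OLS trend coefficients at long-series sites
#'
#' For each trend-source site, regresses its observed log-concentration
#' series on the trend design `[1, f_1, ..., f_m]` restricted to the site's
#' observed periods, by ordinary least squares. The fitted coefficients
#' (one intercept gamma_0 plus one gamma_i per trend) are the site-level
#' outcomes that the per-trend PLS regressions predict from geographic
#' covariates.
#'
#' @param data an [st_dataset()] on the log scale.
#' @param basis a [trend_basis()].
#' @param site_ids sites to fit (default: the basis source sites).
#' @return data.frame with `site_id` and columns `gamma0, gamma1, ...`.
#' @export
fit_site_trend_coefs <- function(data, basis, site_ids = basis$source_sites) {
  stopifnot(inherits(data, "st_dataset"), inherits(basis, "trend_basis"))
  p <- basis$m + 1L
  out <- matrix(NA_real_, length(site_ids), p)
  for (j in seq_along(site_ids)) {
    rows <- data$obs$site_id == site_ids[j]
    t <- data$obs$t[rows]
    y <- data$obs$value[rows]
    F <- trend_design(basis, t)
    if (length(y) < p || qr(F)$rank < p) {
      stop("site ", site_ids[j], " has a rank-deficient trend design (",
           length(y), " observation(s) for ", p, " coefficients)")
    }
    out[j, ] <- stats::lm.fit(F, y)$coefficients
  }
  res <- data.frame(site_id = site_ids, out)
  names(res)[-1] <- paste0("gamma", seq_len(p) - 1L)
  res
}

#' Univariate partial least squares (PLS1) by NIPALS
#'
#' Standardises the covariates (centre and unit SD, by training statistics)
#' and extracts `n_comp` orthogonal score directions, each maximising the
#' covariance between the score and the outcome given the previous
#' components, by the NIPALS algorithm with deflation. Deterministic.
#'
#' @param y numeric outcome at the training sites.
#' @param X numeric matrix of covariates at the training sites (rows named by
#'   site id is conventional but not required).
#' @param n_comp number of components (2 or 3 in the selection grid).
#' @return object of class `pls_model`: `center`, `scale`, `weights` (W),
#'   `loadings` (P), `y_loadings` (q), `rotation` (R = W (P'W)^-1, so that
#'   scores = X_std %*% R), `y_mean`, `n_comp`, `covariate_names`.
#' @export
fit_pls <- function(y, X, n_comp) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), n_comp >= 1)
  if (nrow(X) <= n_comp) stop("need more training sites than components")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance covariate(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "),
         " (run filter_covariates first)")
  }
  E <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  y_mean <- mean(y)
  f <- y - y_mean
  p <- ncol(E)
  W <- P <- matrix(0, p, n_comp)
  q <- numeric(n_comp)
  for (h in seq_len(n_comp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 1e3) {
      stop("outcome orthogonal to remaining covariate space at component ", h)
    }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(E, tt)) / tt2
    qh <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pl)
    f <- f - qh * tt
    W[, h] <- w; P[, h] <- pl; q[h] <- qh
  }
  R <- W %*% solve(crossprod(P, W))
  structure(
    list(
      center = ctr, scale = scl, weights = W, loadings = P,
      y_loadings = q, rotation = R, y_mean = y_mean, n_comp = n_comp,
      covariate_names = colnames(X)
    ),
    class = "pls_model"
  )
}

#' Score sites with a fitted PLS model
#'
#' Applies the training centre/scale and the fixed rotation; no re-fitting.
#' Scoring the training covariate matrix reproduces the training scores
#' exactly; a site whose covariates equal the training mean scores zero.
#'
#' @param model a [fit_pls()] model.
#' @param X covariate matrix with the training covariate columns.
#' @return matrix of scores, `nrow(X)` x `n_comp`.
#' @export
score_sites <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  X <- as.matrix(X)
  if (!is.null(model$covariate_names)) {
    missing <- setdiff(model$covariate_names, colnames(X))
    if (length(missing)) {
      stop("missing covariate column(s): ", paste(missing, collapse = ", "))
    }
    X <- X[, model$covariate_names, drop = FALSE]
  }
  E <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  S <- E %*% model$rotation
  colnames(S) <- paste0("comp", seq_len(ncol(S)))
  S
}

#' Predict the PLS outcome for new sites
#'
#' @param object a [fit_pls()] model.
#' @param X covariate matrix.
#' @param ... unused.
#' @return numeric predictions of the training outcome.
#' @export
predict.pls_model <- function(object, X, ...) {
  drop(score_sites(object, X) %*% object$y_loadings) + object$y_mean
}

#' Build the per-trend reduced covariate feature set
#'
#' Fits the per-site trend coefficients at the trend-source sites
#' ([fit_site_trend_coefs()]), runs one PLS1 regression per coefficient
#' (including the long-term mean, i = 0) against the geographic covariates at
#' those sites, and scores every site in the dataset. Each score matrix
#' `X_i(s)` gets a leading constant column so it can serve directly as the
#' mean design of the corresponding spatial field.
#'
#' @param data an [st_dataset()] on the log scale carrying covariates.
#' @param basis a [trend_basis()].
#' @param n_comp PLS components per trend (2 or 3 in the selection grid).
#' @param train_sites sites supplying the PLS outcomes (default: the trend
#'   source sites).
#' @return object of class `pls_feature_set`: `scores` (list, one
#'   n_sites x (1 + n_comp) matrix per trend index 0..m, rows named by site),
#'   `models` (list of [fit_pls()] objects), `site_ids`, `m`, `n_comp`.
#' @export
build_feature_set <- function(data, basis, n_comp, train_sites = basis$source_sites) {
  stopifnot(inherits(data, "st_dataset"))
  if (is.null(data$covariates)) stop("dataset carries no covariates")
  gam <- fit_site_trend_coefs(data, basis, train_sites)
  X_train <- covariate_matrix(data$covariates, gam$site_id)
  all_ids <- data$sites$site_id
  X_all <- covariate_matrix(data$covariates, all_ids)
  models <- scores <- vector("list", basis$m + 1L)
  for (i in 0:basis$m) {
    models[[i + 1L]] <- fit_pls(gam[[paste0("gamma", i)]], X_train, n_comp)
    sc <- score_sites(models[[i + 1L]], X_all)
    scores[[i + 1L]] <- cbind(const = 1, sc)
    rownames(scores[[i + 1L]]) <- all_ids
  }
  names(models) <- names(scores) <- paste0("trend", 0:basis$m)
  structure(
    list(scores = scores, models = models, site_ids = all_ids,
         m = basis$m, n_comp = n_comp),
    class = "pls_feature_set"
  )
}

#' @export
print.pls_feature_set <- function(x, ...) {
  cat("<pls_feature_set>", x$m + 1L, "trend-specific score sets (",
      x$n_comp, "components each +const ) at", length(x$site_ids), "sites\n")
  invisible(x)
}

#' Score additional locations with an existing feature set
#'
#' @param features a [build_feature_set()] result.
#' @param covariates data.frame `site_id` + covariate columns for the new
#'   locations.
#' @param site_ids ids (rows of `covariates`) to score.
#' @return list of score matrices (with constant column), one per trend.
#' @export
feature_scores_at <- function(features, covariates, site_ids) {
  X <- covariate_matrix(covariates, site_ids)
  lapply(features$models, function(mod) {
    sc <- cbind(const = 1, score_sites(mod, X))
    rownames(sc) <- site_ids
    sc
  })
}
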