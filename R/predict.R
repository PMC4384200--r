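#' Universal-kriging prediction at new locations
#'
#' Computes the conditional expectation of the log-concentration field at the
#' target locations and periods given all observations, under the fitted
#' Gaussian model with the GLS coefficient estimates plugged in. Targets far
#' from all observations revert smoothly to the mean surface
#' `sum_i f_i(t) X_i(s) alpha_i` (plus the shared period-effect adjustment in
#' periods that have observations). Predictions are back-transformed by plain
#' exponentiation; an optional lognormal bias correction
#' `exp(mu + sigma^2/2)` is available but off by default.
#'
#' @param object a fitted [fit_ml()] model (class `st_model`).
#' @param targets data.frame of target locations: `site_id`, coordinates
#'   (`x_km`/`y_km` or `lon`/`lat`), `site_type` optional (defaults to
#'   `"distributed"`).
#' @param covariates data.frame `site_id` + covariate columns covering the
#'   targets (defaults to the training covariate table).
#' @param periods integer period indices to predict (default: all).
#' @param se compute the conditional (kriging) standard error of the log
#'   prediction (slower).
#' @param bias_correct back-transform with `exp(mu + se^2/2)` instead of
#'   `exp(mu)`; requires `se = TRUE`.
#' @param condition_types site types whose observations are conditioned on
#'   (default: all).
#' @param ... unused.
#' @return object of class `st_prediction`: `locations`, `periods`, `axis`,
#'   `log_pred` (targets x periods), `pred` (exponentiated), `se_log`
#'   (targets x periods or `NULL`).
#' @export
predict.st_model <- function(object, targets, covariates = NULL,
                             periods = NULL, se = FALSE, bias_correct = FALSE,
                             condition_types = SITE_TYPES, ...) {
  stopifnot(is.data.frame(targets))
  if (bias_correct && !se) stop("bias_correct requires se = TRUE")
  data <- object$data
  if (!setequal(condition_types, SITE_TYPES)) {
    keep <- data$sites$site_id[data$sites$site_type %in% condition_types]
    data <- subset_sites(data, keep)
  }
  if (is.null(covariates)) covariates <- object$data$covariates
  if (!"site_type" %in% names(targets)) targets$site_type <- "distributed"
  tsites <- st_sites(targets)
  if (is.null(periods)) periods <- seq_along(data$axis)
  ctx <- st_context(data, object$basis, object$features)
  sol <- st_solver(ctx, object$beta, object$resid)

  # target-side mean design and scores: through the PLS models when present,
  # else by direct lookup in the stored score matrices
  S_tar <- if (!is.null(object$features$models)) {
    feature_scores_at(object$features, covariates, tsites$site_id)
  } else {
    lapply(object$features$scores, function(S) {
      missing <- setdiff(tsites$site_id, rownames(S))
      if (length(missing)) {
        stop("no stored scores for target(s): ", paste(missing, collapse = ", "))
      }
      S[tsites$site_id, , drop = FALSE]
    })
  }
  nf <- ctx$m + 1L
  nL <- nrow(tsites)
  mu_field <- matrix(0, nL, nf)   # X_i(s*) alpha_i per field
  for (i in seq_len(nf)) {
    if (ncol(S_tar[[i]]) == 0L) next  # field with empty mean design
    mu_field[, i] <- drop(S_tar[[i]] %*% object$alpha_by_field[[i]])
  }
  Ft <- ctx$Ft                     # T x nf
  mu_tar <- mu_field %*% t(Ft[periods, , drop = FALSE])  # nL x |periods|

  # residual of observations about the fitted mean
  r <- ctx$y - drop(ctx$Dmat %*% object$alpha)
  w <- drop(sol$solve(r))

  # cross-distance and collocation flags
  Dx <- outer(tsites$x_km, ctx$x_km, "-")
  Dy <- outer(tsites$y_km, ctx$y_km, "-")
  Dcross <- sqrt(Dx^2 + Dy^2)
  same <- outer(tsites$site_id, ctx$site_ids, "==")

  # beta-field contribution: sum_i f_i(t*) Kbeta_i(s*, .) Wagg_i
  site_idx <- match(ctx$obs$site_id, ctx$site_ids)
  Ft_obs <- Ft[ctx$obs$t, , drop = FALSE]
  Kcross <- lapply(seq_len(nf), function(i) {
    cov_cross(object$beta[[i]], Dcross, same)
  })
  beta_proj <- matrix(0, nL, nf)
  for (i in seq_len(nf)) {
    agg <- rowsum(Ft_obs[, i] * w, site_idx, reorder = TRUE)
    Wagg <- numeric(ctx$n)
    Wagg[as.integer(rownames(agg))] <- agg
    beta_proj[, i] <- drop(Kcross[[i]] %*% Wagg)
  }
  log_pred <- mu_tar + beta_proj %*% t(Ft[periods, , drop = FALSE])

  # residual contribution within observed periods
  t_pos <- match(periods, ctx$t_vals)
  for (k in seq_along(periods)) {
    ti <- t_pos[k]
    if (is.na(ti)) next
    rows <- ctx$rows_by_t[[ti]]
    idx <- ctx$sites_by_t[[ti]]
    Cnu <- resid_cov_cross(object$resid, Dcross[, idx, drop = FALSE],
                           same[, idx, drop = FALSE])
    log_pred[, k] <- log_pred[, k] + drop(Cnu %*% w[rows])
  }

  se_log <- NULL
  if (se) {
    se_log <- matrix(0, nL, length(periods))
    prior_beta <- vapply(seq_len(nf), function(i) {
      sp <- object$beta[[i]]
      if (sp$kind == "exponential") sp$psill + sp$nugget else sp$nugget
    }, 0)
    prior_nu <- object$resid$time_sill + object$resid$psill + object$resid$nugget
    for (k in seq_along(periods)) {
      tk <- periods[k]
      fstar <- Ft[tk, ]
      # full cross-covariance columns for this period: N x nL
      Cstar <- matrix(0, nrow(ctx$obs), nL)
      for (i in seq_len(nf)) {
        Cstar <- Cstar + (Ft_obs[, i] * fstar[i]) * t(Kcross[[i]])[site_idx, , drop = FALSE]
      }
      ti <- t_pos[k]
      if (!is.na(ti)) {
        rows <- ctx$rows_by_t[[ti]]
        idx <- ctx$sites_by_t[[ti]]
        Cstar[rows, ] <- Cstar[rows, ] +
          t(resid_cov_cross(object$resid, Dcross[, idx, drop = FALSE],
                            same[, idx, drop = FALSE]))
      }
      quad <- colSums(Cstar * sol$solve(Cstar))
      prior <- sum(fstar^2 * prior_beta) + prior_nu
      se_log[, k] <- sqrt(pmax(prior - quad, 0))
    }
  }
  pred <- if (bias_correct) exp(log_pred + se_log^2 / 2) else exp(log_pred)
  dimnames(log_pred) <- dimnames(pred) <-
    list(tsites$site_id, format(data$axis[periods]))
  structure(
    list(locations = tsites, periods = periods, axis = data$axis,
         log_pred = log_pred, pred = pred, se_log = se_log),
    class = "st_prediction"
  )
}

#' @export
print.st_prediction <- function(x, ...) {
  cat("<st_prediction>", nrow(x$log_pred), "locations x",
      ncol(x$log_pred), "periods\n")
  invisible(x)
}

#' Long-term average of back-transformed predictions
#'
#' Arithmetic mean of the exponentiated two-week predictions over the periods
#' intersecting `[from, to]`. The order matters: averaging on the
#' concentration scale (arithmetic mean of exponentials) is the exposure
#' quantity of interest and exceeds the exponentiated mean of the log
#' predictions whenever the series varies (Jensen).
#'
#' @param pred an [predict.st_model()] result.
#' @param from,to `Date` range (defaults: full prediction span).
#' @return data.frame `site_id`, `from`, `to`, `lta`.
#' @export
long_term_average <- function(pred, from = NULL, to = NULL) {
  stopifnot(inherits(pred, "st_prediction"))
  starts <- pred$axis[pred$periods]
  if (is.null(from)) from <- min(starts)
  if (is.null(to)) to <- max(starts) + 13L
  from <- as.Date(from)
  to <- as.Date(to)
  sel <- (starts <= to) & (starts + 13L >= from)
  if (!any(sel)) stop("no prediction periods intersect [", format(from), ", ", format(to), "]")
  data.frame(
    site_id = pred$locations$site_id,
    from = from, to = to,
    lta = rowMeans(pred$pred[, sel, drop = FALSE])
  )
}
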