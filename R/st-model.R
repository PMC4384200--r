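#' Covariance specification for a spatial field
#'
#' Two structures are supported for the spatially varying coefficient fields:
#' an independence model (nugget-only, variance `nugget`) and an exponential
#' spatial smoothing model `psill * exp(-d / range) + nugget * 1[d = 0]`,
#' with `range` in km, partial sill `psill` and nugget `nugget` as variances
#' on the log-concentration scale.
#'
#' @param kind `"exponential"` or `"independent"`.
#' @param range decay range in km (exponential only, > 0).
#' @param psill partial sill variance (exponential only, >= 0).
#' @param nugget micro-scale variance (>= 0).
#' @return object of class `cov_spec`.
#' @export
cov_spec <- function(kind = c("exponential", "independent"),
                     range = NULL, psill = NULL, nugget = 0) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    stopifnot(is.numeric(range), range > 0, is.numeric(psill), psill >= 0)
  } else {
    range <- NULL
    psill <- NULL
  }
  stopifnot(is.numeric(nugget), nugget >= 0)
  structure(list(kind = kind, range = range, psill = psill, nugget = nugget),
            class = "cov_spec")
}

# covariance matrix of a field spec over a square distance matrix
cov_matrix <- function(spec, D) {
  n <- nrow(D)
  if (spec$kind == "exponential") {
    spec$psill * exp(-D / spec$range) + diag(spec$nugget, n)
  } else {
    diag(spec$nugget, n)
  }
}

# cross covariance between target rows and obs-site cols; `same` marks pairs
# that are the identical physical site (nugget applies there only)
cov_cross <- function(spec, Dcross, same = NULL) {
  out <- if (spec$kind == "exponential") {
    spec$psill * exp(-Dcross / spec$range)
  } else {
    matrix(0, nrow(Dcross), ncol(Dcross))
  }
  if (!is.null(same) && spec$nugget > 0) out[same] <- out[same] + spec$nugget
  out
}

#' Residual covariance specification
#'
#' The spatiotemporal residual is independent across two-week periods; within
#' a period it is the sum of a shared random period effect (variance
#' `time_sill`, capturing region-wide short-term events), an exponential
#' spatial term, and a nugget:
#' `cov = time_sill + psill * exp(-d / range) + nugget * 1[d = 0]`.
#'
#' @param range,psill,nugget exponential covariance parameters (km, variance,
#'   variance).
#' @param time_sill variance of the shared per-period random effect.
#' @return object of class `resid_spec`.
#' @export
resid_spec <- function(range, psill, nugget, time_sill = 0) {
  stopifnot(range > 0, psill >= 0, nugget >= 0, time_sill >= 0)
  structure(list(range = range, psill = psill, nugget = nugget,
                 time_sill = time_sill),
            class = "resid_spec")
}

resid_cov_matrix <- function(spec, D) {
  n <- nrow(D)
  spec$time_sill + spec$psill * exp(-D / spec$range) + diag(spec$nugget, n)
}

resid_cov_cross <- function(spec, Dcross, same = NULL) {
  out <- spec$time_sill + spec$psill * exp(-Dcross / spec$range)
  if (!is.null(same) && spec$nugget > 0) out[same] <- out[same] + spec$nugget
  out
}

# Cholesky with escalating jitter for near-singular kernels
safe_chol <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  jit <- mean(diag(M)) * 1e-10
  while (is.null(out)) {
    if (jit > mean(diag(M))) stop("covariance matrix numerically singular")
    out <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    jit <- jit * 100
  }
  out
}

#' Precomputed likelihood context
#'
#' Assembles everything about the data layout that does not depend on the
#' covariance parameters: observation ordering (grouped by period), the
#' site distance matrix, the grouping of periods sharing an identical
#' observation pattern (their residual blocks share one factorisation), the
#' trend design, the per-trend score matrices restricted to observed sites,
#' and the stacked mean design matrix.
#'
#' @param data an [st_dataset()] on the log scale.
#' @param basis a [trend_basis()].
#' @param features a [build_feature_set()] result covering the data sites.
#' @return object of class `st_context`.
#' @export
st_context <- function(data, basis, features) {
  stopifnot(inherits(data, "st_dataset"), inherits(basis, "trend_basis"))
  if (!data$log_scale) stop("model operates on the log scale; call log_transform()")
  obs <- data$obs
  if (!nrow(obs)) stop("no observations")
  site_ids <- data$sites$site_id[data$sites$site_id %in% unique(obs$site_id)]
  n <- length(site_ids)
  m <- basis$m
  sx <- data$sites$x_km[match(site_ids, data$sites$site_id)]
  sy <- data$sites$y_km[match(site_ids, data$sites$site_id)]
  D <- as.matrix(stats::dist(cbind(sx, sy)))
  # rows already ordered by (t, site); period groupings
  site_idx <- match(obs$site_id, site_ids)
  t_vals <- sort(unique(obs$t))
  rows_by_t <- split(seq_len(nrow(obs)), factor(obs$t, levels = t_vals))
  sites_by_t <- lapply(rows_by_t, function(r) site_idx[r])
  pattern_key <- vapply(sites_by_t, paste, "", collapse = ",")
  groups <- split(seq_along(t_vals), pattern_key)
  Ft <- trend_design(basis, seq_along(data$axis))   # T x (m+1)
  # scores per field restricted to observed sites, aligned with site_ids
  S <- lapply(features$scores, function(sc) sc[site_ids, , drop = FALSE])
  p_i <- vapply(S, ncol, 0L)
  # stacked mean design: row (s,t) has f_i(t) * X_i(s) in field i's columns
  Dmat <- matrix(0, nrow(obs), sum(p_i))
  off <- c(0L, cumsum(p_i))
  for (i in seq_len(m + 1L)) {
    if (p_i[i] == 0L) next
    cols <- (off[i] + 1L):off[i + 1L]
    Dmat[, cols] <- Ft[obs$t, i] * S[[i]][site_idx, , drop = FALSE]
  }
  colnames(Dmat) <- unlist(lapply(seq_len(m + 1L), function(i) {
    if (p_i[i] == 0L) return(character(0))
    paste0("trend", i - 1L, ".", colnames(S[[i]]))
  }))
  structure(
    list(
      y = obs$value, obs = obs, site_ids = site_ids, n = n, m = m,
      D = D, x_km = sx, y_km = sy,
      t_vals = t_vals, rows_by_t = rows_by_t, sites_by_t = sites_by_t,
      groups = groups, Ft = Ft, scores = S, p_i = p_i, Dmat = Dmat,
      axis = data$axis
    ),
    class = "st_context"
  )
}

#' Factorised marginal covariance solver
#'
#' The marginal covariance of the stacked observation vector is
#' `Sigma = F Sigma_beta F' + Sigma_nu`, with `Sigma_beta` block-diagonal
#' over fields, `Sigma_nu` block-diagonal over periods, and `F` the sparse
#' expansion of the trend design. This factorisation applies the Woodbury
#' identity: solves cost one small Cholesky per residual pattern group, one
#' per field, and one of the `n * (m+1)` inner matrix, never forming the
#' dense N x N covariance.
#'
#' @param ctx an [st_context()].
#' @param beta list of [cov_spec()] (length m+1).
#' @param resid a [resid_spec()].
#' @return list with `solve(Z)` (applies `Sigma^{-1}`), `logdet`, and the
#'   pieces reused by prediction.
#' @keywords internal
st_solver <- function(ctx, beta, resid) {
  n <- ctx$n
  m <- ctx$m
  nf <- m + 1L
  # field covariance blocks and inverses
  Q_beta <- vector("list", nf)
  logdet_beta <- 0
  for (i in seq_len(nf)) {
    ch <- safe_chol(cov_matrix(beta[[i]], ctx$D))
    logdet_beta <- logdet_beta + 2 * sum(log(diag(ch)))
    Q_beta[[i]] <- chol2inv(ch)
  }
  # residual blocks per unique observation pattern
  g_of_t <- integer(length(ctx$t_vals))
  Ainv <- vector("list", length(ctx$groups))
  logdet_nu <- 0
  for (g in seq_along(ctx$groups)) {
    ts <- ctx$groups[[g]]
    idx <- ctx$sites_by_t[[ts[1]]]
    ch <- safe_chol(resid_cov_matrix(resid, ctx$D[idx, idx, drop = FALSE]))
    Ainv[[g]] <- chol2inv(ch)
    logdet_nu <- logdet_nu + length(ts) * 2 * sum(log(diag(ch)))
    g_of_t[ts] <- g
  }
  solve_nu <- function(Z) {
    Z <- as.matrix(Z)
    W <- Z
    for (ti in seq_along(ctx$t_vals)) {
      r <- ctx$rows_by_t[[ti]]
      W[r, ] <- Ainv[[g_of_t[ti]]] %*% Z[r, , drop = FALSE]
    }
    W
  }
  # inner matrix K = blockdiag(Q_beta) + F' Sigma_nu^{-1} F, built per group
  # via the Kronecker structure sum_g C_g (x) scatter(Ainv_g)
  K <- matrix(0, n * nf, n * nf)
  for (i in seq_len(nf)) {
    rr <- ((i - 1L) * n + 1L):(i * n)
    K[rr, rr] <- Q_beta[[i]]
  }
  for (g in seq_along(ctx$groups)) {
    ts <- ctx$groups[[g]]
    idx <- ctx$sites_by_t[[ts[1]]]
    Fg <- ctx$Ft[ctx$t_vals[ts], , drop = FALSE]
    Cg <- crossprod(Fg)                      # (m+1) x (m+1)
    for (i in seq_len(nf)) {
      for (j in seq_len(nf)) {
        if (Cg[i, j] == 0) next
        K[(i - 1L) * n + idx, (j - 1L) * n + idx] <-
          K[(i - 1L) * n + idx, (j - 1L) * n + idx] + Cg[i, j] * Ainv[[g]]
      }
    }
  }
  chK <- safe_chol(K)
  logdet_K <- 2 * sum(log(diag(chK)))
  # F' Z aggregation and F V expansion
  Ft_obs <- ctx$Ft[ctx$obs$t, , drop = FALSE]
  site_idx <- match(ctx$obs$site_id, ctx$site_ids)
  tmult <- function(W) {  # F' W : (n * nf) x ncol(W)
    U <- matrix(0, n * nf, ncol(W))
    for (i in seq_len(nf)) {
      agg <- rowsum(Ft_obs[, i] * W, site_idx, reorder = TRUE)
      U[(i - 1L) * n + as.integer(rownames(agg)), ] <- agg
    }
    U
  }
  fmult <- function(V) {  # F V : N x ncol(V)
    out <- matrix(0, nrow(ctx$obs), ncol(V))
    for (i in seq_len(nf)) {
      out <- out + Ft_obs[, i] * V[(i - 1L) * n + site_idx, , drop = FALSE]
    }
    out
  }
  solve_sigma <- function(Z) {
    Z <- as.matrix(Z)
    W <- solve_nu(Z)
    U <- tmult(W)
    V <- backsolve(chK, backsolve(chK, U, transpose = TRUE))
    W - solve_nu(fmult(V))
  }
  list(
    solve = solve_sigma, solve_nu = solve_nu, tmult = tmult, fmult = fmult,
    chK = chK, K = K, Q_beta = Q_beta, Ainv = Ainv, g_of_t = g_of_t,
    logdet = logdet_nu + logdet_beta + logdet_K
  )
}

# value and analytic gradient of the profiled negative log-likelihood at
# theta (log-scale parameters). The gradient uses the envelope theorem (the
# GLS alpha-hat maximizes the likelihood in alpha, so d alpha/d theta drops
# out) and the standard Gaussian identity
#   d(-2 ll)/d theta = tr(Sigma^-1 dSigma) - u' dSigma u,  u = Sigma^-1 r,
# with every trace evaluated through the low-rank/block structure.
profiled_negll_grad <- function(ctx, structure, theta) {
  par <- unpack_theta(theta, structure)
  beta <- par$beta
  resid <- par$resid
  n <- ctx$n
  nf <- ctx$m + 1L
  sol <- st_solver(ctx, beta, resid)
  Z <- cbind(ctx$y, ctx$Dmat)
  SZ <- sol$solve(Z)
  M <- crossprod(Z, SZ)
  if (ncol(ctx$Dmat) > 0L) {
    alpha <- solve(M[-1L, -1L, drop = FALSE], M[-1L, 1L])
    quad <- M[1L, 1L] - sum(M[-1L, 1L] * alpha)
    u <- drop(SZ[, 1L] - SZ[, -1L, drop = FALSE] %*% alpha)  # Sigma^-1 r
  } else {
    alpha <- numeric(0)
    quad <- M[1L, 1L]
    u <- SZ[, 1L]
  }
  N <- length(ctx$y)
  value <- 0.5 * (N * log(2 * pi) + sol$logdet + quad)

  # G = F' Sigma_nu^-1 F is K minus the Q_beta diagonal blocks
  G <- sol$K
  for (i in seq_len(nf)) {
    rr <- ((i - 1L) * n + 1L):(i * n)
    G[rr, rr] <- G[rr, rr] - sol$Q_beta[[i]]
  }
  Hinv <- chol2inv(sol$chK)
  # F' Sigma^-1 F = G - G K^-1 G
  W <- G - G %*% Hinv %*% G
  v <- drop(sol$tmult(matrix(u, ncol = 1L)))

  grad <- numeric(length(theta))
  k <- 0L
  put <- function(g) { k <<- k + 1L; grad[k] <<- g }
  for (i in seq_len(nf)) {
    rr <- ((i - 1L) * n + 1L):(i * n)
    Mb <- W[rr, rr]
    vi <- v[rr]
    sp <- beta[[i]]
    if (structure$beta[i] == "exponential") {
      E <- exp(-ctx$D / sp$range)
      dphi <- sp$psill * E * (ctx$D / sp$range)
      dsig <- sp$psill * E
      put(0.5 * (sum(Mb * dphi) - drop(vi %*% dphi %*% vi)))
      put(0.5 * (sum(Mb * dsig) - drop(vi %*% dsig %*% vi)))
      put(0.5 * sp$nugget * (sum(diag(Mb)) - sum(vi^2)))
    } else {
      put(0.5 * sp$nugget * (sum(diag(Mb)) - sum(vi^2)))
    }
  }
  # residual parameters: accumulate per pattern group
  tr_phi <- tr_sig <- tr_tau <- tr_omg <- 0
  q_phi <- q_sig <- q_tau <- q_omg <- 0
  for (g in seq_along(ctx$groups)) {
    ts <- ctx$groups[[g]]
    idx <- ctx$sites_by_t[[ts[1]]]
    ng <- length(idx)
    Dg <- ctx$D[idx, idx, drop = FALSE]
    Eg <- exp(-Dg / resid$range)
    dphi <- resid$psill * Eg * (Dg / resid$range)
    dsig <- resid$psill * Eg
    # sum over t in g of Sigma^-1 diagonal blocks:
    #   |g| A^-1 - A^-1 (sum_ij Cg[i,j] Hinv_sub[i][j]) A^-1
    Fg <- ctx$Ft[ctx$t_vals[ts], , drop = FALSE]
    Cg <- crossprod(Fg)
    B <- matrix(0, ng, ng)
    for (i in seq_len(nf)) {
      ri <- (i - 1L) * n + idx
      for (j in seq_len(nf)) {
        if (Cg[i, j] == 0) next
        B <- B + Cg[i, j] * Hinv[ri, (j - 1L) * n + idx, drop = FALSE]
      }
    }
    Ainv_g <- sol$Ainv[[g]]
    Psum <- length(ts) * Ainv_g - Ainv_g %*% B %*% Ainv_g
    # sum over t in g of u_t u_t'
    Ug <- matrix(0, ng, ng)
    for (ti in ts) Ug <- Ug + tcrossprod(u[ctx$rows_by_t[[ti]]])
    tr_phi <- tr_phi + sum(Psum * dphi); q_phi <- q_phi + sum(Ug * dphi)
    tr_sig <- tr_sig + sum(Psum * dsig); q_sig <- q_sig + sum(Ug * dsig)
    tr_tau <- tr_tau + sum(diag(Psum));  q_tau <- q_tau + sum(diag(Ug))
    tr_omg <- tr_omg + sum(Psum);        q_omg <- q_omg + sum(Ug)
  }
  put(0.5 * (tr_phi - q_phi))
  put(0.5 * (tr_sig - q_sig))
  if (structure$resid_nugget) put(0.5 * resid$nugget * (tr_tau - q_tau))
  if (structure$time_effect) put(0.5 * resid$time_sill * (tr_omg - q_omg))
  list(value = value, grad = grad, alpha = alpha)
}

#' Marginal Gaussian log-likelihood with profiled mean coefficients
#'
#' Evaluates the log-likelihood of the observed (unbalanced) log-concentration
#' vector under the hierarchical model, with the mean-field coefficient
#' vectors `alpha_i` profiled out by generalized least squares at the given
#' covariance parameters.
#'
#' @param data an [st_dataset()] on the log scale, or a prebuilt
#'   [st_context()].
#' @param basis,features trend basis and PLS features (ignored when `data` is
#'   already a context).
#' @param beta list of [cov_spec()] for fields 0..m.
#' @param resid a [resid_spec()].
#' @return list with `loglik`, `alpha` (named GLS coefficient vector),
#'   `alpha_by_field` (split per field).
#' @export
marginal_loglik <- function(data, basis = NULL, features = NULL, beta, resid) {
  ctx <- if (inherits(data, "st_context")) data else st_context(data, basis, features)
  if (length(beta) != ctx$m + 1L) stop("need one cov_spec per field 0..m")
  sol <- st_solver(ctx, beta, resid)
  Z <- cbind(ctx$y, ctx$Dmat)
  SZ <- sol$solve(Z)
  M <- crossprod(Z, SZ)
  p <- ncol(ctx$Dmat)
  if (p > 0L) {
    Add <- M[-1L, -1L, drop = FALSE]
    ady <- M[-1L, 1L]
    alpha <- solve(Add, ady)
    quad <- M[1L, 1L] - sum(ady * alpha)
  } else {
    alpha <- numeric(0)
    quad <- M[1L, 1L]
  }
  N <- length(ctx$y)
  ll <- -0.5 * (N * log(2 * pi) + sol$logdet + quad)
  names(alpha) <- colnames(ctx$Dmat)
  off <- c(0L, cumsum(ctx$p_i))
  alpha_by_field <- lapply(seq_len(ctx$m + 1L), function(i) {
    alpha[(off[i] + 1L):off[i + 1L]]
  })
  names(alpha_by_field) <- names(ctx$scores)
  list(loglik = ll, alpha = alpha, alpha_by_field = alpha_by_field)
}

## ---- parameter packing ----------------------------------------------------

# structure: list(beta = character vector of kinds (length m+1),
#                 time_effect = TRUE/FALSE, resid_nugget = TRUE/FALSE)
#' Model structure specification
#'
#' Names the covariance kind of each coefficient field and which residual
#' variance components are present; this is what the model-selection grid
#' toggles.
#'
#' @param beta_kinds character vector, `"exponential"` or `"independent"`,
#'   one per field 0..m.
#' @param time_effect include the shared per-period random effect.
#' @param resid_nugget include the residual nugget.
#' @return list of class `st_structure`.
#' @export
st_structure <- function(beta_kinds, time_effect = TRUE, resid_nugget = TRUE) {
  beta_kinds <- match.arg(beta_kinds, c("exponential", "independent"),
                          several.ok = TRUE)
  structure(list(beta = beta_kinds, time_effect = isTRUE(time_effect),
                 resid_nugget = isTRUE(resid_nugget)),
            class = "st_structure")
}

theta_names <- function(structure) {
  nm <- character(0)
  for (i in seq_along(structure$beta)) {
    tag <- paste0("beta", i - 1L)
    nm <- c(nm, if (structure$beta[i] == "exponential") {
      paste0(tag, c(".log_range", ".log_psill", ".log_nugget"))
    } else {
      paste0(tag, ".log_nugget")
    })
  }
  nm <- c(nm, "resid.log_range", "resid.log_psill")
  if (structure$resid_nugget) nm <- c(nm, "resid.log_nugget")
  if (structure$time_effect) nm <- c(nm, "resid.log_time_sill")
  nm
}

unpack_theta <- function(theta, structure) {
  k <- 0L
  take <- function() { k <<- k + 1L; exp(theta[k]) }
  beta <- lapply(structure$beta, function(kind) {
    if (kind == "exponential") {
      cov_spec("exponential", range = take(), psill = take(), nugget = take())
    } else {
      cov_spec("independent", nugget = take())
    }
  })
  resid <- resid_spec(
    range = take(), psill = take(),
    nugget = if (structure$resid_nugget) take() else 0,
    time_sill = if (structure$time_effect) take() else 0
  )
  list(beta = beta, resid = resid)
}

pack_params <- function(beta, resid, structure) {
  th <- numeric(0)
  for (i in seq_along(structure$beta)) {
    sp <- beta[[i]]
    th <- c(th, if (structure$beta[i] == "exponential") {
      log(c(sp$range, sp$psill, sp$nugget))
    } else {
      log(sp$nugget)
    })
  }
  th <- c(th, log(resid$range), log(resid$psill))
  if (structure$resid_nugget) th <- c(th, log(resid$nugget))
  if (structure$time_effect) th <- c(th, log(resid$time_sill))
  th
}

# data-driven starting values: split the variance of per-site OLS trend-fit
# residuals between the residual components, and the variance of the gamma
# coefficients (after regression on the scores) between field sill and nugget
init_theta <- function(ctx, structure) {
  nf <- ctx$m + 1L
  med_d <- stats::median(ctx$D[upper.tri(ctx$D)])
  if (!is.finite(med_d) || med_d <= 0) med_d <- 10
  gam <- matrix(NA_real_, ctx$n, nf)
  rvar <- numeric(0)
  site_idx <- match(ctx$obs$site_id, ctx$site_ids)
  for (s in seq_len(ctx$n)) {
    r <- which(site_idx == s)
    F <- ctx$Ft[ctx$obs$t[r], , drop = FALSE]
    if (length(r) > nf && qr(F)$rank == nf) {
      fit <- stats::lm.fit(F, ctx$y[r])
      gam[s, ] <- fit$coefficients
      if (length(r) > nf + 2L) rvar <- c(rvar, stats::var(fit$residuals))
    }
  }
  v_resid <- max(mean(rvar, na.rm = TRUE), 1e-3)
  if (!is.finite(v_resid)) v_resid <- 0.05
  beta <- vector("list", nf)
  for (i in seq_len(nf)) {
    g <- gam[, i]
    ok <- is.finite(g)
    vg <- if (sum(ok) > ncol(ctx$scores[[i]]) + 1L) {
      fit <- stats::lm.fit(ctx$scores[[i]][ok, , drop = FALSE], g[ok])
      stats::var(fit$residuals)
    } else {
      stats::var(g[ok])
    }
    vg <- max(vg, 1e-4, na.rm = TRUE)
    beta[[i]] <- if (structure$beta[i] == "exponential") {
      cov_spec("exponential", range = med_d / 4, psill = vg / 2, nugget = vg / 2)
    } else {
      cov_spec("independent", nugget = vg)
    }
  }
  resid <- resid_spec(
    range = med_d / 4,
    psill = v_resid / 3,
    nugget = if (structure$resid_nugget) v_resid / 3 else 0,
    time_sill = if (structure$time_effect) v_resid / 3 else 0
  )
  pack_params(beta, resid, structure)
}

#' Fit the spatiotemporal model by maximum likelihood
#'
#' Maximises the profiled marginal log-likelihood over the log-transformed
#' covariance parameters with L-BFGS-B, from `n_starts` seeded starting
#' points (a data-driven start plus jittered replicates), keeping the best.
#' Mean coefficients are recovered by GLS at the optimum.
#'
#' @param data an [st_dataset()] on the log scale.
#' @param basis a [trend_basis()].
#' @param features a [build_feature_set()] covering the data sites.
#' @param structure an [st_structure()] (default: exponential everywhere,
#'   time effect and residual nugget on).
#' @param init optional list(beta, resid) of starting values.
#' @param n_starts number of optimizer starts.
#' @param seed integer seed controlling the start jitter.
#' @param control passed to [stats::optim()] (`maxit` capped at 500 by
#'   default; convergence tolerance `factr` corresponds to ~1e-6 relative).
#' @return object of class `st_model`: `beta` (cov specs), `resid`,
#'   `alpha`/`alpha_by_field`, `loglik`, `structure`, `basis`, `features`,
#'   `data`, `converged`, `n_evals`.
#' @export
fit_ml <- function(data, basis, features, structure = NULL, init = NULL,
                   n_starts = 3, seed = 1L, control = list()) {
  ctx <- st_context(data, basis, features)
  if (is.null(structure)) {
    structure <- st_structure(rep("exponential", ctx$m + 1L))
  }
  if (length(structure$beta) != ctx$m + 1L) {
    stop("structure must name a covariance kind for each field 0..", ctx$m)
  }
  # value and analytic gradient share one computation, memoized on theta
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    out <- if (any(!is.finite(theta)) || any(abs(theta) > 30)) {
      NULL
    } else {
      tryCatch(profiled_negll_grad(ctx, structure, theta),
               error = function(e) NULL)
    }
    if (is.null(out) || !is.finite(out$value)) {
      out <- list(value = 1e10, grad = rep(0, length(theta)))
    }
    cache$key <- key
    cache$val <- out
    out
  }
  negll <- function(theta) evaluate(theta)$value
  negll_gr <- function(theta) evaluate(theta)$grad
  th0 <- if (!is.null(init)) pack_params(init$beta, init$resid, structure)
         else init_theta(ctx, structure)
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e9), control)
  set.seed(seed)
  best <- NULL
  n_evals <- 0L
  for (s in seq_len(n_starts)) {
    th_s <- if (s == 1L) th0 else th0 + stats::rnorm(length(th0), sd = 0.75)
    fit <- tryCatch(
      stats::optim(th_s, negll, gr = negll_gr, method = "L-BFGS-B",
                   lower = -25, upper = 25, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_evals <- n_evals + fit$counts[1L]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("optimizer failed at all ", n_starts, " start(s)")
  }
  par <- unpack_theta(best$par, structure)
  ml <- marginal_loglik(ctx, beta = par$beta, resid = par$resid)
  structure(
    list(
      beta = par$beta, resid = par$resid,
      alpha = ml$alpha, alpha_by_field = ml$alpha_by_field,
      loglik = ml$loglik, theta = best$par, structure = structure,
      basis = basis, features = features, data = data,
      converged = best$convergence == 0, n_evals = n_evals
    ),
    class = "st_model"
  )
}

#' @export
print.st_model <- function(x, ...) {
  cat("<st_model> log-likelihood", format(x$loglik, digits = 8), "\n")
  for (i in seq_along(x$beta)) {
    sp <- x$beta[[i]]
    cat("  beta", i - 1L, ": ", sp$kind,
        if (sp$kind == "exponential") {
          sprintf(" (range %.1f km, psill %.4f, nugget %.4f)",
                  sp$range, sp$psill, sp$nugget)
        } else {
          sprintf(" (variance %.4f)", sp$nugget)
        }, "\n", sep = "")
  }
  cat(sprintf("  residual: range %.1f km, psill %.4f, nugget %.4f, time sill %.4f\n",
              x$resid$range, x$resid$psill, x$resid$nugget, x$resid$time_sill))
  invisible(x)
}

#' Simulate from the hierarchical model
#'
#' Exact generative counterpart of the likelihood: draws each coefficient
#' field `beta_i ~ N(X_i alpha_i, Sigma_i)` over the given sites, then for
#' each period an independent residual field (shared period effect +
#' exponential spatial field + nugget), and assembles
#' `C(s,t) = sum_i f_i(t) beta_i(s) + nu(s,t)` at the requested pattern.
#'
#' @param sites an [st_sites()] table.
#' @param basis a [trend_basis()].
#' @param scores list of score matrices (rows named by site id, constant
#'   column included), one per field 0..m.
#' @param alpha list of coefficient vectors matching the score columns.
#' @param beta list of [cov_spec()] per field.
#' @param resid a [resid_spec()].
#' @param pattern data.frame `site_id`, `t`: which (site, period) pairs to
#'   observe. Defaults to the full grid.
#' @param seed integer seed.
#' @return list with `data` (an [st_dataset()] on the log scale), `beta_fields`
#'   (n x (m+1) matrix of realised fields) and `full` (n x T matrix of the
#'   complete latent log field, for truth comparisons).
#' @export
simulate_st <- function(sites, basis, scores, alpha, beta, resid,
                        pattern = NULL, seed = 1L) {
  stopifnot(inherits(sites, "st_sites"))
  set.seed(seed)
  n <- nrow(sites)
  T_ <- length(basis$axis)
  D <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
  nf <- basis$m + 1L
  B <- matrix(0, n, nf)
  for (i in seq_len(nf)) {
    mu <- drop(scores[[i]][sites$site_id, , drop = FALSE] %*% alpha[[i]])
    C <- cov_matrix(beta[[i]], D)
    B[, i] <- if (all(C == 0)) mu else mu + drop(crossprod(safe_chol(C), stats::rnorm(n)))
  }
  Ft <- trend_design(basis, seq_len(T_))
  M <- B %*% t(Ft)                     # n x T mean + field part
  Cnu <- resid_cov_matrix(resid, D)
  if (any(Cnu != 0)) {
    chN <- safe_chol(Cnu)
    E <- crossprod(chN, matrix(stats::rnorm(n * T_), n, T_))
    M <- M + E
  }
  if (is.null(pattern)) {
    pattern <- expand.grid(site_id = sites$site_id, t = seq_len(T_),
                           stringsAsFactors = FALSE)
  }
  obs <- data.frame(
    site_id = as.character(pattern$site_id),
    t = as.integer(pattern$t),
    value = M[cbind(match(pattern$site_id, sites$site_id), pattern$t)]
  )
  data <- st_dataset(obs, sites, basis$axis, covariates = NULL,
                     log_scale = TRUE)
  list(data = data, beta_fields = B, full = M)
}
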