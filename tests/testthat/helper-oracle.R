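# Dense joint-Gaussian oracle, built entry by entry from the covariance
# kernels and never through the package's structured likelihood path.

dense_cov <- function(obs, sites, basis, beta, resid) {
  sid <- match(obs$site_id, sites$site_id)
  D <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
  Ft <- cbind(1, basis$values)
  N <- nrow(obs)
  Sig <- matrix(0, N, N)
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      sa <- sid[a]; sb <- sid[b]
      v <- 0
      for (i in seq_along(beta)) {
        sp <- beta[[i]]
        cv <- if (sp$kind == "exponential") sp$psill * exp(-D[sa, sb] / sp$range) else 0
        if (sa == sb) cv <- cv + sp$nugget
        v <- v + Ft[obs$t[a], i] * Ft[obs$t[b], i] * cv
      }
      if (obs$t[a] == obs$t[b]) {
        v <- v + resid$time_sill + resid$psill * exp(-D[sa, sb] / resid$range) +
          (sa == sb) * resid$nugget
      }
      Sig[a, b] <- v
    }
  }
  Sig
}

dense_design <- function(obs, sites, basis, scores) {
  sid <- match(obs$site_id, sites$site_id)
  Ft <- cbind(1, basis$values)
  do.call(cbind, lapply(seq_along(scores), function(i) {
    Ft[obs$t, i] * scores[[i]][sid, , drop = FALSE]
  }))
}

dense_loglik <- function(data, basis, scores, beta, resid) {
  obs <- data$obs
  Sig <- dense_cov(obs, data$sites, basis, beta, resid)
  Dm <- dense_design(obs, data$sites, basis, scores)
  Si <- solve(Sig)
  A <- t(Dm) %*% Si %*% Dm
  b <- t(Dm) %*% Si %*% obs$value
  alpha <- solve(A, b)
  r <- obs$value - Dm %*% alpha
  ll <- -0.5 * (nrow(obs) * log(2 * pi) +
                as.numeric(determinant(Sig)$modulus) +
                as.numeric(t(r) %*% Si %*% r))
  list(loglik = ll, alpha = drop(alpha))
}

# conditional mean at target (site, period) pairs given the observations,
# with supplied mean coefficients
dense_conditional_mean <- function(data, basis, scores, beta, resid,
                                   alpha_by_field, target_sites, target_t) {
  obs <- data$obs
  all_sites <- data$sites
  Sig <- dense_cov(obs, all_sites, basis, beta, resid)
  sid <- match(obs$site_id, all_sites$site_id)
  D <- as.matrix(stats::dist(cbind(all_sites$x_km, all_sites$y_km)))
  Ft <- cbind(1, basis$values)
  mu_obs <- rowSums(sapply(seq_along(scores), function(i) {
    Ft[obs$t, i] * drop(scores[[i]][sid, , drop = FALSE] %*% alpha_by_field[[i]])
  }))
  w <- solve(Sig, obs$value - mu_obs)
  kern <- function(sa, sb, ta, tb) {
    v <- 0
    for (i in seq_along(beta)) {
      sp <- beta[[i]]
      cv <- if (sp$kind == "exponential") sp$psill * exp(-D[sa, sb] / sp$range) else 0
      if (sa == sb) cv <- cv + sp$nugget
      v <- v + Ft[ta, i] * Ft[tb, i] * cv
    }
    if (ta == tb) {
      v <- v + resid$time_sill + resid$psill * exp(-D[sa, sb] / resid$range) +
        (sa == sb) * resid$nugget
    }
    v
  }
  vapply(seq_along(target_sites), function(k) {
    si <- match(target_sites[k], all_sites$site_id)
    tt <- target_t[k]
    cvec <- vapply(seq_len(nrow(obs)), function(a) kern(si, sid[a], tt, obs$t[a]), 0)
    mu <- sum(vapply(seq_along(scores), function(i) {
      Ft[tt, i] * drop(scores[[i]][target_sites[k], , drop = FALSE] %*% alpha_by_field[[i]])
    }, 0))
    mu + sum(cvec * w)
  }, 0)
}

# wrap raw score matrices as a feature set (bypassing PLS) for model tests
as_feature_set <- function(scores, n_comp = NULL) {
  structure(
    list(scores = scores, models = NULL,
         site_ids = rownames(scores[[1]]),
         m = length(scores) - 1L,
         n_comp = if (is.null(n_comp)) ncol(scores[[1]]) - 1L else n_comp),
    class = "pls_feature_set"
  )
}

# random small unbalanced model instance for oracle comparisons
random_instance <- function(seed, n_max = 15L, T_max = 25L) {
  set.seed(seed)
  # enough sites and periods that the 6-9 column GLS design stays full rank
  n <- sample(6:n_max, 1)
  T_ <- sample(8:T_max, 1)
  m <- sample(1:2, 1)
  ax <- build_time_axis(as.Date("2005-01-05"),
                        as.Date("2005-01-05") + 14L * T_ + 1L)
  sites <- st_sites(data.frame(
    site_id = sprintf("s%02d", seq_len(n)),
    site_type = sample(c("aqs", "fixed", "home"), n, replace = TRUE),
    x_km = runif(n, 0, 60), y_km = runif(n, 0, 60)
  ))
  raw <- matrix(rnorm(T_ * m), T_, m)
  basis <- trend_basis(stfield:::normalize_trends(raw), ax)
  scores <- lapply(seq_len(m + 1L), function(i) {
    sc <- cbind(const = 1, matrix(rnorm(n * 2), n, 2,
                                  dimnames = list(NULL, c("c1", "c2"))))
    rownames(sc) <- sites$site_id
    sc
  })
  names(scores) <- paste0("trend", seq_len(m + 1L) - 1L)
  beta <- lapply(seq_len(m + 1L), function(i) {
    if (runif(1) < 0.5) {
      cov_spec("exponential", range = runif(1, 5, 40),
               psill = runif(1, 0.05, 0.5), nugget = runif(1, 0.01, 0.2))
    } else {
      cov_spec("independent", nugget = runif(1, 0.05, 0.4))
    }
  })
  resid <- resid_spec(range = runif(1, 10, 50), psill = runif(1, 0.05, 0.4),
                      nugget = runif(1, 0.01, 0.2),
                      time_sill = runif(1, 0, 0.3))
  alpha <- lapply(seq_len(m + 1L), function(i) rnorm(3, sd = 0.5))
  pat <- expand.grid(site_id = sites$site_id, t = seq_len(T_),
                     stringsAsFactors = FALSE)
  pat <- pat[runif(nrow(pat)) > 0.35, ]
  # every site needs at least one observation
  missing_sites <- setdiff(sites$site_id, pat$site_id)
  if (length(missing_sites)) {
    pat <- rbind(pat, data.frame(site_id = missing_sites,
                                 t = sample(T_, length(missing_sites), replace = TRUE)))
  }
  sim <- simulate_st(sites, basis, scores, alpha, beta, resid,
                     pattern = pat, seed = seed + 1000L)
  list(data = sim$data, sites = sites, basis = basis, scores = scores,
       features = as_feature_set(scores), beta = beta, resid = resid,
       alpha = alpha, sim = sim)
}

# append an unobserved site to a dataset's site table (for oracle targets)
add_far_site <- function(data, site_row) {
  sites <- rbind(as.data.frame(data$sites)[, c("site_id", "site_type", "x_km", "y_km")],
                 site_row[, c("site_id", "site_type", "x_km", "y_km")])
  sites$cluster_id <- NA_character_
  st_dataset(data$obs, st_sites(sites), data$axis, data$covariates,
             data$log_scale, data$units)
}
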