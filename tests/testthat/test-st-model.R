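test_that("scalar instance matches the closed-form Gaussian density", {
  ax <- build_time_axis(as.Date("2005-01-05"), as.Date("2005-02-05"))
  sites <- st_sites(data.frame(site_id = "a", site_type = "aqs", x_km = 0, y_km = 0))
  y <- 1.3
  d <- st_dataset(data.frame(site_id = "a", t = 1, value = y), sites, ax,
                  log_scale = TRUE)
  f <- stfield:::normalize_trends(matrix(rnorm(length(ax))))
  basis <- trend_basis(f, ax)
  # no mean columns at all: zero-column score matrices profile nothing out
  scores <- lapply(1:2, function(i) {
    m <- matrix(numeric(0), 1, 0)
    rownames(m) <- "a"
    m
  })
  names(scores) <- c("trend0", "trend1")
  beta <- list(cov_spec("independent", nugget = 0.2),
               cov_spec("independent", nugget = 0.1))
  resid <- resid_spec(range = 10, psill = 0.3, nugget = 0.05, time_sill = 0.15)
  v <- 0.2 + 0.1 * f[1, 1]^2 + 0.3 + 0.05 + 0.15
  ml <- marginal_loglik(d, basis, as_feature_set(scores, 0L), beta = beta, resid = resid)
  expect_equal(ml$loglik, -0.5 * (log(2 * pi * v) + y^2 / v), tolerance = 1e-10)
})

test_that("structured likelihood equals the dense oracle on random instances", {
  for (seed in 1:8) {
    inst <- random_instance(seed)
    ml <- marginal_loglik(inst$data, inst$basis, inst$features,
                          beta = inst$beta, resid = inst$resid)
    dl <- dense_loglik(inst$data, inst$basis, inst$scores, inst$beta, inst$resid)
    expect_lt(abs(ml$loglik - dl$loglik), 1e-6)
    expect_equal(unname(ml$alpha), unname(dl$alpha), tolerance = 1e-8)
  }
})

test_that("rescaling data and variances shifts the likelihood as the oracle says", {
  inst <- random_instance(101)
  scale2 <- function(sp) {
    if (sp$kind == "exponential") {
      cov_spec("exponential", range = sp$range, psill = 2 * sp$psill,
               nugget = 2 * sp$nugget)
    } else {
      cov_spec("independent", nugget = 2 * sp$nugget)
    }
  }
  beta2 <- lapply(inst$beta, scale2)
  resid2 <- resid_spec(inst$resid$range, 2 * inst$resid$psill,
                       2 * inst$resid$nugget, 2 * inst$resid$time_sill)
  d2 <- inst$data
  d2$obs$value <- sqrt(2) * d2$obs$value
  ml2 <- marginal_loglik(d2, inst$basis, inst$features, beta = beta2, resid = resid2)
  dl2 <- dense_loglik(d2, inst$basis, inst$scores, beta2, resid2)
  expect_lt(abs(ml2$loglik - dl2$loglik), 1e-6)
})

test_that("analytic likelihood gradient matches finite differences", {
  inst <- random_instance(7)
  structure_ <- st_structure(vapply(inst$beta, function(b) b$kind, ""))
  theta <- stfield:::pack_params(inst$beta, inst$resid, structure_)
  ctx <- st_context(inst$data, inst$basis, inst$features)
  out <- stfield:::profiled_negll_grad(ctx, structure_, theta)
  fd <- vapply(seq_along(theta), function(k) {
    h <- 1e-6
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (stfield:::profiled_negll_grad(ctx, structure_, tp)$value -
     stfield:::profiled_negll_grad(ctx, structure_, tm)$value) / (2 * h)
  }, 0)
  expect_equal(out$grad, fd, tolerance = 1e-5)
})

test_that("simulation is seeded, exact in the degenerate case, and moment-correct", {
  set.seed(30)
  n <- 3
  T_ <- 4
  ax <- build_time_axis(as.Date("2005-01-05"), as.Date("2005-01-05") + 14L * T_ + 1L)
  sites <- st_sites(data.frame(
    site_id = c("a", "b", "c"), site_type = "aqs",
    x_km = c(0, 5, 20), y_km = c(0, 0, 10)
  ))
  f <- stfield:::normalize_trends(matrix(seq(-1, 1, length.out = T_)))
  basis <- trend_basis(f, ax)
  scores <- lapply(1:2, function(i) {
    sc <- cbind(const = 1, z = c(-1, 0, 1)); rownames(sc) <- sites$site_id; sc
  })
  names(scores) <- c("trend0", "trend1")
  alpha <- list(c(2, 1), c(0.5, -0.5))
  # all variances zero: the field is exactly the deterministic mean surface
  beta0 <- list(cov_spec("independent", nugget = 0),
                cov_spec("independent", nugget = 0))
  resid0 <- resid_spec(range = 1, psill = 0, nugget = 0, time_sill = 0)
  sim <- simulate_st(sites, basis, scores, alpha, beta0, resid0, seed = 4)
  mu <- outer(drop(scores[[1]] %*% alpha[[1]]), rep(1, T_)) +
    outer(drop(scores[[2]] %*% alpha[[2]]), f[, 1])
  expect_equal(sim$full, mu, ignore_attr = TRUE)
  # same seed, same dataset
  beta1 <- list(cov_spec("exponential", range = 10, psill = 0.3, nugget = 0.1),
                cov_spec("independent", nugget = 0.2))
  resid1 <- resid_spec(range = 15, psill = 0.25, nugget = 0.1, time_sill = 0.2)
  s1 <- simulate_st(sites, basis, scores, alpha, beta1, resid1, seed = 9)
  s2 <- simulate_st(sites, basis, scores, alpha, beta1, resid1, seed = 9)
  expect_identical(s1$data$obs, s2$data$obs)
  # empirical covariance at one period over replicates matches the kernel
  reps <- vapply(1:2000, function(r) {
    simulate_st(sites, basis, scores, alpha, beta1, resid1,
                pattern = data.frame(site_id = sites$site_id, t = 1L),
                seed = r)$data$obs$value
  }, numeric(3))
  emp <- stats::cov(t(reps))
  pat <- data.frame(site_id = sites$site_id, t = 1L)
  theo <- dense_cov(pat, sites, basis, beta1, resid1)
  expect_lt(max(abs(emp - theo)), 0.07)  # Monte-Carlo error at 2000 draws
  # distinct periods are uncorrelated beyond the beta-field contribution
  reps2 <- lapply(1:2000, function(r) {
    simulate_st(sites, basis, scores, alpha,
                list(cov_spec("independent", nugget = 0),
                     cov_spec("independent", nugget = 0)),
                resid1,
                pattern = data.frame(site_id = c("a", "a"), t = c(1L, 2L)),
                seed = 10000 + r)$data$obs$value
  })
  reps2 <- do.call(rbind, reps2)
  expect_lt(abs(stats::cov(reps2[, 1], reps2[, 2])), 0.02)
})

test_that("maximum likelihood beats truth in-sample and is deterministic", {
  set.seed(31)
  inst <- random_instance(55)
  structure_ <- st_structure(vapply(inst$beta, function(b) b$kind, ""))
  fit1 <- fit_ml(inst$data, inst$basis, inst$features, structure_,
                 n_starts = 2, seed = 3)
  fit2 <- fit_ml(inst$data, inst$basis, inst$features, structure_,
                 n_starts = 2, seed = 3)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
  ml_truth <- marginal_loglik(inst$data, inst$basis, inst$features,
                              beta = inst$beta, resid = inst$resid)
  expect_gte(fit1$loglik, ml_truth$loglik - 1e-3)
})

test_that("a spatially uncorrelated field fits with a vanishing partial sill", {
  set.seed(32)
  n <- 40
  T_ <- 30
  ax <- build_time_axis(as.Date("2005-01-05"), as.Date("2005-01-05") + 14L * T_ + 1L)
  sites <- st_sites(data.frame(
    site_id = sprintf("s%02d", 1:n), site_type = "aqs",
    x_km = runif(n, 0, 60), y_km = runif(n, 0, 60)
  ))
  f <- stfield:::normalize_trends(matrix(sin(2 * pi * (1:T_) / 15)))
  basis <- trend_basis(f, ax)
  scores <- lapply(1:2, function(i) {
    sc <- matrix(1, n, 1, dimnames = list(sites$site_id, "const")); sc
  })
  names(scores) <- c("trend0", "trend1")
  alpha <- list(2, 0.5)
  beta_true <- list(cov_spec("independent", nugget = 0.3),
                    cov_spec("independent", nugget = 0.05))
  resid_true <- resid_spec(range = 20, psill = 0.1, nugget = 0.05, time_sill = 0)
  sim <- simulate_st(sites, basis, scores, alpha, beta_true, resid_true, seed = 12)
  fs <- as_feature_set(scores, 0L)
  fit <- fit_ml(sim$data, basis, fs,
                st_structure(c("exponential", "independent"), time_effect = FALSE),
                n_starts = 2, seed = 1)
  # the misspecified exponential component should collapse toward independence:
  # its structured variance stays well under the true nugget variance
  expect_lt(fit$beta[[1]]$psill, 0.1)
  expect_gt(fit$beta[[1]]$nugget + fit$beta[[1]]$psill, 0.15)
})
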