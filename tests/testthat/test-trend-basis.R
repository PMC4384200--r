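toy_axis <- function(T_) {
  build_time_axis(as.Date("2005-01-05"), as.Date("2005-01-05") + 14L * T_ + 1L)
}

test_that("EM imputation leaves complete matrices and observed entries alone", {
  set.seed(10)
  X <- matrix(rnorm(60), 12, 5)
  expect_equal(em_impute(X, k = 2), X, ignore_attr = TRUE)
  Xm <- X
  Xm[1, 1] <- NA
  out <- em_impute(Xm, k = 2)
  expect_equal(out[-1, ], X[-1, ], ignore_attr = TRUE)
  Xbad <- X
  Xbad[-1, 2] <- NA
  expect_error(em_impute(Xbad, k = 1), "fewer than 2")
})

test_that("EM imputation reconstructs a rank-1 matrix from 80% of entries", {
  set.seed(11)
  u <- rnorm(30)
  v <- rnorm(8)
  X <- tcrossprod(u, v)
  miss <- matrix(runif(length(X)) < 0.2, nrow(X))
  Xm <- X
  Xm[miss] <- NA
  out <- em_impute(Xm, k = 1, tol = 1e-12, max_iter = 500)
  expect_lt(max(abs(out[miss] - X[miss])), 1e-6)
})

test_that("SVD trends recover a shared temporal pattern up to sign", {
  set.seed(12)
  T_ <- 40
  g <- sin(2 * pi * (1:T_) / 20)
  X <- sapply(1:10, function(j) g * runif(1, 0.5, 2) + rnorm(1))
  tr <- derive_raw_trends(X, m = 1)
  expect_gt(abs(cor(tr[, 1], g)), 1 - 1e-10)
  # sign convention: positive loading on the first column
  expect_gt(cor(tr[, 1], X[, 1] - mean(X[, 1])), 0)
  expect_error(derive_raw_trends(X, m = 10), "m must be")
  expect_error(derive_raw_trends(matrix(5, 10, 4), m = 1), "degenerate")
})

test_that("pure-noise matrices yield a weak leading singular value ratio", {
  set.seed(13)
  X <- matrix(rnorm(40 * 12), 40, 12)
  tr <- derive_raw_trends(X, m = 1)
  sv <- attr(tr, "singular_values")
  Xs <- sapply(1:12, function(j) sin(2 * pi * (1:40) / 20) * 3 + rnorm(40, sd = 0.2))
  svs <- attr(derive_raw_trends(Xs, m = 1), "singular_values")
  expect_lt(sv[1] / sv[2], svs[1] / svs[2])  # structure separates the spectrum
  expect_lt(sv[1] / sv[2], 2)
})

test_that("spline smoothing projects, tracks seasonality, and shrinks variation", {
  T_ <- 104  # 4 years
  ax <- toy_axis(T_)
  tt <- seq_len(T_)
  # a straight line lies in the natural-spline span, so projection fixes it
  lin <- scale(tt)[, 1]
  sm <- smooth_trends(matrix(lin), ax, df_per_year = 8)
  rawn <- stfield:::normalize_trends(matrix(lin))
  expect_lt(max(abs(sm$values - rawn)), 1e-8)
  # smoothing is a projection: applying it twice changes nothing
  wig <- sin(2 * pi * tt / 5) + rnorm(T_, sd = 0.3)
  s1 <- smooth_trends(matrix(wig), ax, df_per_year = 4)
  s2 <- smooth_trends(s1$values, ax, df_per_year = 4)
  expect_lt(max(abs(s1$values - s2$values)), 1e-10)
  # an annual sinusoid is tracked at 8 df/year
  yf <- as.numeric(as.Date(ax) - as.Date(ax)[1]) / 365.25
  sinu <- sin(2 * pi * yf) + rnorm(T_, sd = 0.05)
  sm8 <- smooth_trends(matrix(sinu), ax, df_per_year = 8)
  expect_gt(cor(sm8$values[, 1], sinu), 0.99)
  # fewer df give a smoother (lower total variation) curve
  sm4 <- smooth_trends(matrix(sinu), ax, df_per_year = 4)
  tv <- function(x) sum(abs(diff(x)))
  expect_lt(tv(sm4$values[, 1]), tv(sm8$values[, 1]))
  expect_error(smooth_trends(matrix(rnorm(10)), toy_axis(10), df_per_year = 30),
               "df")
})

test_that("trend basis columns are zero-mean unit-RMS and the design adds f0", {
  set.seed(14)
  ax <- toy_axis(52)
  b <- smooth_trends(matrix(rnorm(52 * 2), 52, 2), ax, df_per_year = 8)
  expect_equal(colMeans(b$values), c(f1 = 0, f2 = 0))
  expect_equal(sqrt(colMeans(b$values^2)), c(f1 = 1, f2 = 1))
  Fd <- trend_design(b, c(1, 10))
  expect_equal(dim(Fd), c(2L, 3L))
  expect_equal(Fd[, 1], c(f0 = 1, f0 = 1), ignore_attr = TRUE)
})

test_that("the full estimation path recovers a generating trend", {
  set.seed(15)
  T_ <- 104
  ax <- toy_axis(T_)
  yf <- as.numeric(as.Date(ax) - as.Date(ax)[1]) / 365.25
  f1 <- stfield:::normalize_trends(matrix(sin(2 * pi * yf) - 0.5 * yf))[, 1]
  n <- 12
  sites <- st_sites(data.frame(
    site_id = sprintf("s%02d", 1:n), site_type = "aqs",
    x_km = runif(n, 0, 50), y_km = runif(n, 0, 50)
  ))
  make_data <- function(miss_frac) {
    obs <- do.call(rbind, lapply(1:n, function(j) {
      keep <- runif(T_) >= miss_frac
      data.frame(site_id = sites$site_id[j], t = which(keep),
                 value = (2 + 0.3 * j) + (0.5 + 0.1 * j) * f1[keep] +
                   rnorm(sum(keep), sd = 0.05))
    }))
    st_dataset(obs, sites, ax, log_scale = TRUE)
  }
  b_full <- estimate_trend_basis(make_data(0), m = 1, df_per_year = 8)
  expect_gt(abs(cor(b_full$values[, 1], f1)), 0.99)
  expect_setequal(b_full$source_sites, sites$site_id)
  b_miss <- estimate_trend_basis(make_data(0.3), m = 1, df_per_year = 8)
  expect_gt(abs(cor(b_miss$values[, 1], f1)), 0.97)
})

test_that("two orthogonal generating trends are recovered as a span", {
  set.seed(16)
  T_ <- 104
  ax <- toy_axis(T_)
  yf <- as.numeric(as.Date(ax) - as.Date(ax)[1]) / 365.25
  F2 <- stfield:::normalize_trends(cbind(sin(2 * pi * yf), yf - mean(yf)))
  n <- 12
  sites <- st_sites(data.frame(
    site_id = sprintf("s%02d", 1:n), site_type = c(rep("aqs", 10), "fixed", "fixed"),
    x_km = runif(n, 0, 50), y_km = runif(n, 0, 50)
  ))
  obs <- do.call(rbind, lapply(1:n, function(j) {
    data.frame(site_id = sites$site_id[j], t = 1:T_,
               value = 2 + rnorm(1) * F2[, 1] + rnorm(1) * F2[, 2] +
                 rnorm(T_, sd = 0.05))
  }))
  d <- st_dataset(obs, sites, ax, log_scale = TRUE)
  b <- estimate_trend_basis(d, m = 2, df_per_year = 8)
  for (i in 1:2) {
    r2 <- summary(stats::lm(F2[, i] ~ b$values))$r.squared
    expect_gt(r2, 0.95)
  }
})

test_that("trend estimation is deterministic and sign-stable", {
  set.seed(17)
  T_ <- 52
  ax <- toy_axis(T_)
  n <- 6
  sites <- st_sites(data.frame(
    site_id = sprintf("s%02d", 1:n), site_type = "aqs",
    x_km = runif(n, 0, 50), y_km = runif(n, 0, 50)
  ))
  f <- sin(2 * pi * (1:T_) / 26)
  obs <- do.call(rbind, lapply(1:n, function(j) {
    data.frame(site_id = sites$site_id[j], t = 1:T_,
               value = 1 + (0.5 + 0.2 * j) * f + rnorm(T_, sd = 0.1))
  }))
  d <- st_dataset(obs, sites, ax, log_scale = TRUE)
  b1 <- estimate_trend_basis(d, m = 1, df_per_year = 8)
  b2 <- estimate_trend_basis(d, m = 1, df_per_year = 8)
  expect_identical(b1$values, b2$values)
  # positive loading on the first source site, so the trend tracks +f
  expect_gt(cor(b1$values[, 1], f), 0)
})

test_that("residual lag-1 autocorrelation is small under the model", {
  set.seed(18)
  T_ <- 80
  ax <- toy_axis(T_)
  n <- 8
  sites <- st_sites(data.frame(
    site_id = sprintf("s%02d", 1:n), site_type = "aqs",
    x_km = runif(n, 0, 50), y_km = runif(n, 0, 50)
  ))
  f <- stfield:::normalize_trends(matrix(cos(2 * pi * (1:T_) / 26)))
  obs <- do.call(rbind, lapply(1:n, function(j) {
    data.frame(site_id = sites$site_id[j], t = 1:T_,
               value = 2 + 0.5 * f[, 1] + rnorm(T_, sd = 0.2))
  }))
  d <- st_dataset(obs, sites, ax, log_scale = TRUE)
  b <- estimate_trend_basis(d, m = 1, df_per_year = 4)
  diag <- residual_autocorrelation(d, b)
  expect_lt(abs(diag$mean_lag1), 0.2)
})
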