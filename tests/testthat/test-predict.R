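# assemble an st_model by hand around known parameters (bypassing fit_ml)
manual_model <- function(inst) {
  ml <- marginal_loglik(inst$data, inst$basis, inst$features,
                        beta = inst$beta, resid = inst$resid)
  structure(
    list(beta = inst$beta, resid = inst$resid,
         alpha = ml$alpha, alpha_by_field = ml$alpha_by_field,
         loglik = ml$loglik, basis = inst$basis, features = inst$features,
         data = inst$data,
         structure = st_structure(vapply(inst$beta, function(b) b$kind, ""))),
    class = "st_model"
  )
}

test_that("kriging matches the dense conditional mean on random instances", {
  for (seed in c(3, 14, 27)) {
    inst <- random_instance(seed, n_max = 12L, T_max = 15L)
    model <- manual_model(inst)
    targets <- as.data.frame(inst$sites[1:3, ])
    T_ <- length(inst$data$axis)
    pr <- predict(model, targets = targets, periods = seq_len(T_))
    # oracle needs target scores; targets are existing sites here
    for (tt in unique(c(1L, T_ %/% 2L, T_))) {
      oracle <- dense_conditional_mean(
        inst$data, inst$basis, inst$scores, inst$beta, inst$resid,
        model$alpha_by_field, targets$site_id, rep(tt, nrow(targets))
      )
      expect_lt(max(abs(pr$log_pred[, tt] - oracle)), 1e-8)
    }
  }
})

test_that("a collocated target reproduces the observation as nuggets vanish", {
  inst <- random_instance(8, n_max = 8L, T_max = 10L)
  inst$beta <- lapply(inst$beta, function(sp) {
    if (sp$kind == "exponential") {
      cov_spec("exponential", range = sp$range, psill = sp$psill, nugget = 0)
    } else {
      sp
    }
  })
  inst$resid <- resid_spec(inst$resid$range, inst$resid$psill, 1e-12,
                           inst$resid$time_sill)
  model <- manual_model(inst)
  ob <- inst$data$obs[5, ]
  pr <- predict(model, targets = as.data.frame(
    inst$sites[inst$sites$site_id == ob$site_id, ]
  ), periods = ob$t)
  expect_equal(pr$log_pred[1, 1], ob$value, tolerance = 1e-5)
})

test_that("remote targets revert to the mean surface plus the period effect", {
  inst <- random_instance(21, n_max = 8L, T_max = 10L)
  model <- manual_model(inst)
  far <- data.frame(site_id = "far", site_type = "distributed",
                    x_km = 5000, y_km = 5000)
  # score the remote site like an average site: covariates at training mean
  sc_far <- lapply(inst$scores, function(S) {
    m <- matrix(c(1, colMeans(S[, -1, drop = FALSE])), 1)
    rownames(m) <- "far"
    colnames(m) <- colnames(S)
    m
  })
  model2 <- model
  model2$features <- as_feature_set(lapply(seq_along(inst$scores), function(i) {
    rbind(inst$scores[[i]], sc_far[[i]])
  }))
  T_ <- length(inst$data$axis)
  pr <- predict(model2, targets = far, periods = seq_len(T_))
  Ft <- cbind(1, inst$basis$values)
  mu <- drop(Ft %*% vapply(seq_along(sc_far), function(i) {
    drop(sc_far[[i]] %*% model$alpha_by_field[[i]])
  }, 0))
  # at exponential range scales of tens of km, 5000 km is numerically infinite,
  # but the shared period random effect still adjusts observed periods
  obs_t <- sort(unique(inst$data$obs$t))
  dev <- pr$log_pred[1, ] - mu
  expect_gt(max(abs(dev[obs_t])), 0)
  if (model$resid$time_sill > 0.05) {
    expect_gt(stats::sd(dev[obs_t]), 0)
  }
  unobs <- setdiff(seq_len(T_), obs_t)
  if (length(unobs)) expect_lt(max(abs(dev[unobs])), 1e-8)
  # oracle agreement holds out to the remote limit too
  oracle <- dense_conditional_mean(
    add_far_site(inst$data, far), inst$basis,
    lapply(seq_along(inst$scores), function(i) rbind(inst$scores[[i]], sc_far[[i]])),
    inst$beta, inst$resid, model$alpha_by_field, "far", obs_t[1]
  )
  expect_lt(abs(pr$log_pred[1, obs_t[1]] - oracle), 1e-8)
})

test_that("raising an isolated observation raises nearby predictions", {
  set.seed(33)
  ax <- build_time_axis(as.Date("2005-01-05"), as.Date("2005-03-20"))
  sites <- st_sites(data.frame(
    site_id = c("lone", "other"), site_type = "aqs",
    x_km = c(0, 50), y_km = c(0, 0)
  ))
  f <- stfield:::normalize_trends(matrix(rnorm(length(ax))))
  basis <- trend_basis(f, ax)
  # a single period is observed, so only the long-term mean gets a design
  # column (a second constant column would be collinear with it)
  scores <- list(trend0 = matrix(1, 2, 1, dimnames = list(sites$site_id, "const")),
                 trend1 = matrix(numeric(0), 2, 0,
                                 dimnames = list(sites$site_id, NULL)))
  beta <- list(cov_spec("exponential", range = 10, psill = 0.3, nugget = 0.01),
               cov_spec("independent", nugget = 0.01))
  resid <- resid_spec(range = 10, psill = 0.1, nugget = 0.05, time_sill = 0)
  mk <- function(y1) {
    d <- st_dataset(data.frame(site_id = c("lone", "other"), t = c(1L, 1L),
                               value = c(y1, 2)), sites, ax, log_scale = TRUE)
    inst <- list(data = d, sites = sites, basis = basis, scores = scores,
                 features = as_feature_set(scores), beta = beta, resid = resid)
    model <- manual_model(inst)
    near <- data.frame(site_id = "near", site_type = "distributed",
                       x_km = 2, y_km = 0)
    model$features <- as_feature_set(lapply(scores, function(S) {
      m <- matrix(1, 3, ncol(S), dimnames = list(c(sites$site_id, "near"), colnames(S)))
      m[, colnames(S), drop = FALSE]
    }))
    predict(model, targets = near, periods = 1L)$log_pred[1, 1]
  }
  expect_gt(mk(3.0), mk(2.0))
})

test_that("long-term averages use the arithmetic mean of exponentiated predictions", {
  ax <- build_time_axis(as.Date("2005-01-05"), as.Date("2005-04-01"))
  pred <- structure(
    list(locations = st_sites(data.frame(site_id = "p", site_type = "distributed",
                                         x_km = 0, y_km = 0)),
         periods = seq_along(ax), axis = ax,
         log_pred = matrix(log(10), 1, length(ax)),
         pred = matrix(10, 1, length(ax)), se_log = NULL),
    class = "st_prediction"
  )
  expect_equal(long_term_average(pred)$lta, 10)
  pred$log_pred[1, ] <- log(c(8, 12, rep(10, length(ax) - 2)))
  pred$pred <- exp(pred$log_pred)
  lta2 <- long_term_average(pred, from = as.Date(ax[1]), to = as.Date(ax[2]) + 13)
  expect_equal(lta2$lta, 10)
  # Jensen: arithmetic mean of exponentials exceeds exponential of the mean
  expect_gt(lta2$lta, exp(mean(pred$log_pred[1, 1:2])))
  expect_error(long_term_average(pred, from = as.Date("1990-01-01"),
                                 to = as.Date("1990-02-01")), "intersect")
})

test_that("kriging standard errors shrink to zero at collocated targets", {
  inst <- random_instance(40, n_max = 8L, T_max = 8L)
  inst$beta <- lapply(inst$beta, function(sp) {
    if (sp$kind == "exponential") {
      cov_spec("exponential", sp$range, psill = sp$psill, nugget = 0)
    } else sp
  })
  inst$resid <- resid_spec(inst$resid$range, inst$resid$psill, 1e-12,
                           inst$resid$time_sill)
  model <- manual_model(inst)
  ob <- inst$data$obs[1, ]
  pr <- predict(model, targets = as.data.frame(
    inst$sites[inst$sites$site_id == ob$site_id, ]
  ), periods = ob$t, se = TRUE)
  expect_lt(pr$se_log[1, 1], 1e-4)
  expect_equal(pr$pred, exp(pr$log_pred))
})
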