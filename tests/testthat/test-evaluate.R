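test_that("fold schemes respect tier design: sizes, LOO, unsplit clusters", {
  home <- data.frame(site_id = sprintf("h%02d", 1:20))
  f <- make_folds(home, "kfold10", seed = 2)
  expect_equal(sort(unique(f$fold)), 1:10)
  expect_true(all(table(f$fold) == 2L))
  fixed <- data.frame(site_id = sprintf("f%d", 1:7))
  f2 <- make_folds(fixed, "loo")
  expect_equal(sort(f2$fold), 1:7)
  snap <- data.frame(site_id = sprintf("s%02d", 1:12),
                     cluster_id = rep(sprintf("c%d", 1:4), each = 3))
  f3 <- make_folds(snap, "kfold10_clustered", seed = 5)
  split_check <- tapply(f3$fold, snap$cluster_id, function(x) length(unique(x)))
  expect_true(all(split_check == 1L))
  expect_error(make_folds(data.frame(site_id = c("a", "b")), "kfold10_clustered"),
               "cluster_id")
  # determinism in the seed
  expect_identical(make_folds(home, "kfold10", seed = 9),
                   make_folds(home, "kfold10", seed = 9))
})

test_that("MSE-based R2 measures fit to the 1-1 line, unlike squared correlation", {
  y <- c(10, 12, 15, 9, 14, 11)
  m <- cv_metrics(y, y)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2_cv, 1)
  expect_equal(m$r2_cvreg, 1)
  # grand-mean predictions: RMSE^2 = MSE_obs exactly, R2_CV truncates to 0
  m2 <- cv_metrics(y, rep(mean(y), length(y)))
  expect_equal(m2$rmse^2, m2$mse_obs)
  expect_equal(m2$r2_cv, 0)
  # constant shift: perfect correlation but poor 1-1 fit
  shift <- 3 * stats::sd(y)
  m3 <- cv_metrics(y, y + shift)
  expect_equal(m3$r2_cv, 0)
  expect_equal(m3$r2_cvreg, 1)
})

test_that("metrics are invariant to site ordering", {
  set.seed(41)
  y <- rnorm(15, 10)
  yh <- y + rnorm(15, sd = 0.5)
  perm <- sample(15)
  m1 <- cv_metrics(y, yh)
  m2 <- cv_metrics(y[perm], yh[perm])
  expect_equal(m1$rmse, m2$rmse)
  expect_equal(m1$r2_cv, m2$r2_cv)
})

test_that("candidate grid enumerates the sixteen structure choices", {
  g <- candidate_grid()
  expect_equal(nrow(g), 16L)
  expect_setequal(unique(g$m), c(1L, 2L))
  expect_setequal(unique(g$df_per_year), c(4L, 8L))
  expect_setequal(unique(g$n_scores), c(2L, 3L))
  expect_setequal(unique(g$spatial_smooth), c(TRUE, FALSE))
  expect_equal(nrow(unique(g)), 16L)
})

# small campaign shared by the CV tests
cv_fixture <- function(seed = 42) {
  cfg <- scenario_config(
    n_aqs = 6L, n_fixed = 2L, n_home = 12L, n_snapshot_clusters = 3L,
    cluster_size = 3L, years = 1.5, m_true = 1L, n_targets = 4L, seed = seed
  )
  camp <- generate_campaign(cfg)
  data <- log_transform(camp$data)
  basis <- estimate_trend_basis(data, m = 1, df_per_year = 4)
  features <- build_feature_set(data, basis, n_comp = 2)
  list(camp = camp, data = data, basis = basis, features = features,
       structure = st_structure(rep("exponential", 2)))
}

test_that("cross-validation refits per fold and reports per-site means", {
  fx <- cv_fixture()
  home <- fx$data$sites[fx$data$sites$site_type == "home", ]
  plan <- make_folds(home, "kfold10", seed = 1)
  rep <- cross_validate(fx$data, fx$basis, fx$features, fx$structure, plan,
                        n_starts = 1, control = list(maxit = 60, factr = 1e11))
  expect_s3_class(rep, "cv_report")
  expect_setequal(rep$per_site$site_id, home$site_id)
  expect_true(all(rep$per_site$y > 0))
  expect_gte(rep$r2_cv, 0)
  expect_lte(rep$r2_cv, 1)
  expect_equal(rep$rmse^2, mean((rep$per_site$y - rep$per_site$yhat)^2))
  # observed site means equal the data's own means on the original scale
  sid <- rep$per_site$site_id[1]
  expect_equal(rep$per_site$y[1],
               mean(exp(fx$data$obs$value[fx$data$obs$site_id == sid])))
})

test_that("temporally adjusted R2 references behave at their degenerate points", {
  fx <- cv_fixture()
  home <- fx$data$sites[fx$data$sites$site_type == "home", ]
  # synthetic report whose predictions equal the regional-average reference
  ref_ids <- fx$data$sites$site_id[fx$data$sites$site_type %in% c("aqs", "fixed")]
  ref_obs <- fx$data$obs[fx$data$obs$site_id %in% ref_ids, ]
  avg_pred <- vapply(home$site_id, function(sid) {
    tt <- fx$data$obs$t[fx$data$obs$site_id == sid]
    mean(vapply(tt, function(t) mean(exp(ref_obs$value[ref_obs$t == t])), 0))
  }, 0)
  y <- vapply(home$site_id, function(sid) {
    mean(exp(fx$data$obs$value[fx$data$obs$site_id == sid]))
  }, 0)
  rep_avg <- structure(
    list(per_site = data.frame(site_id = home$site_id, y = y, yhat = avg_pred),
         scheme = "kfold10"),
    class = "cv_report"
  )
  out <- r2_temporally_adjusted(rep_avg, fx$data, fx$basis, "avg")
  expect_equal(out$r2, 0)  # model == reference predictor
  # perfect predictions against an imperfect reference give R2 = 1
  rep_perfect <- rep_avg
  rep_perfect$per_site$yhat <- y
  for (ref in c("avg", "close", "smooth")) {
    out2 <- r2_temporally_adjusted(rep_perfect, fx$data, fx$basis, ref)
    expect_equal(out2$r2, 1)
  }
})

test_that("spatially informative predictions beat temporal references, and only then", {
  # strong spatial contrast: the adjusted and unadjusted R2 roughly agree;
  # no spatial contrast: adjusted R2 collapses while unadjusted may stay high
  fx <- cv_fixture()
  home <- fx$data$sites[fx$data$sites$site_type == "home", ]
  y <- vapply(home$site_id, function(sid) {
    mean(exp(fx$data$obs$value[fx$data$obs$site_id == sid]))
  }, 0)
  ref_ids <- fx$data$sites$site_id[fx$data$sites$site_type %in% c("aqs", "fixed")]
  ref_obs <- fx$data$obs[fx$data$obs$site_id %in% ref_ids, ]
  avg_pred <- vapply(home$site_id, function(sid) {
    tt <- fx$data$obs$t[fx$data$obs$site_id == sid]
    mean(vapply(tt, function(t) mean(exp(ref_obs$value[ref_obs$t == t])), 0))
  }, 0)
  good <- structure(list(per_site = data.frame(site_id = home$site_id, y = y,
                                               yhat = y + rnorm(length(y), sd = 0.02 * mean(y)))),
                    class = "cv_report")
  temporal_only <- structure(list(per_site = data.frame(site_id = home$site_id, y = y,
                                                        yhat = avg_pred)),
                             class = "cv_report")
  r_good <- r2_temporally_adjusted(good, fx$data, fx$basis, "avg")$r2
  r_temp <- r2_temporally_adjusted(temporal_only, fx$data, fx$basis, "avg")$r2
  expect_gt(r_good, 0.5)
  expect_equal(r_temp, 0)
})

test_that("model selection ranks home-site accuracy first and never splits clusters", {
  fx <- cv_fixture()
  grid <- candidate_grid(m_options = 1L, df_options = 4L,
                         score_options = 2L, smooth_options = c(TRUE, FALSE))
  sel <- model_selection_grid(fx$data, grid = grid, seed = 1, n_starts = 1,
                              control = list(maxit = 60, factr = 1e11))
  expect_equal(nrow(sel$table), 2L)
  expect_equal(sel$table$rank, 1:2)
  top <- sel$table[1, ]
  other <- sel$table[2, ]
  better <- top$home_r2_cv > other$home_r2_cv ||
    (top$home_r2_cv == other$home_r2_cv && top$home_rmse <= other$home_rmse)
  expect_true(better)
  expect_s3_class(sel$best$reports$home, "cv_report")
})
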