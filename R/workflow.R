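#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], with
#' every module-level knob at its default. Supply overrides as a (possibly
#' nested) list or a YAML file path; unknown keys are an error, so typos in
#' configs fail before any compute.
#'
#' @param overrides named list (or YAML file path) of settings to override.
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    region = "synthetic-region",
    pollutant = "pm25",
    seed = 1L,
    stages = c("synth", "preprocess", "trends", "pls", "fit", "predict"),
    out = "stfield-run",
    synth = list(),                      # scenario_config() overrides
    preprocess = list(
      completeness_min = 0.75, min_years = 2, quarter_min_frac = 0.10,
      landuse_max = 0.10
    ),
    trends = list(m = 2L, df_per_year = 4L),
    pls = list(n_scores = 2L),
    fit = list(spatial_smooth = TRUE, n_starts = 3L),
    cv = list(home_scheme = "kfold10", fixed_scheme = "loo"),
    select = list(run = FALSE),
    predict = list(targets = "distributed")
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, path = "config")
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", path, "$", nm)
    }
    if (is.list(base[[nm]]) && is.list(over[[nm]]) && nm != "synth") {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste0(path, "$", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Run the modeling pipeline end to end
#'
#' Executes the requested stages in dependency order — synthetic campaign
#' generation (or CSV ingest), preprocessing filters, trend estimation, PLS
#' feature construction, maximum-likelihood fitting, optional
#' cross-validation / model selection, and prediction with long-term
#' averages — writing each stage's artifacts (CSV/JSON) under the output
#' directory. Deterministic given the configuration: the serialized config
#' and its MD5 hash are recorded alongside every run.
#'
#' @param config a [default_config()] list, a YAML file path, or an override
#'   list.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "run_config")) config <- default_config(config)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, pretty = TRUE)
  # hash the analysis-relevant configuration: output location excluded, so
  # identical settings give identical hashes wherever the run lands
  canon <- unclass(config)
  canon$out <- NULL
  canon_path <- tempfile()
  jsonlite::write_json(canon, canon_path, auto_unbox = TRUE, pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(canon_path))
  unlink(canon_path)
  res <- list(config = config, config_hash = cfg_hash)
  stages <- config$stages
  log <- list(config_hash = cfg_hash)

  if ("synth" %in% stages) {
    sc <- do.call(scenario_config, c(config$synth, list(seed = config$seed)))
    campaign <- generate_campaign(sc)
    res$campaign <- campaign
    write_st_dataset(campaign$data, file.path(out_dir, "synth"))
    jsonlite::write_json(
      list(config_hash = cfg_hash, n_obs = nrow(campaign$data$obs),
           n_sites = nrow(campaign$data$sites),
           n_below_lod = campaign$truth$n_below_lod),
      file.path(out_dir, "synth", "truth_meta.json"), auto_unbox = TRUE
    )
    jsonlite::write_json(
      list(
        config_hash = cfg_hash,
        params = list(beta = lapply(campaign$truth$params$beta, unclass),
                      resid = unclass(campaign$truth$params$resid)),
        alpha = campaign$truth$alpha,
        target_ids = campaign$truth$target_ids,
        lta = as.list(campaign$truth$lta[campaign$truth$target_ids])
      ),
      file.path(out_dir, "synth", "truth.json"), auto_unbox = TRUE, digits = NA
    )
    data <- campaign$data
  } else {
    data <- res$data_in
  }

  if ("preprocess" %in% stages) {
    pp <- config$preprocess
    fm <- filter_monitors(data, min_years = pp$min_years,
                          quarter_min_frac = pp$quarter_min_frac)
    monitor_ids <- fm$data$sites$site_id[
      fm$data$sites$site_type %in% c(LONG_SERIES_TYPES, "home", "snapshot")]
    monitor_ids <- intersect(monitor_ids, unique(fm$data$obs$site_id))
    participant_ids <- fm$data$sites$site_id[fm$data$sites$site_type == "distributed"]
    fc <- filter_covariates(
      fm$data$covariates, monitor_ids, participant_ids,
      landuse_names = grep("^lu_", names(fm$data$covariates), value = TRUE),
      landuse_max = pp$landuse_max
    )
    keep_cov <- c("site_id", fc$kept)
    fm$data$covariates <- fm$data$covariates[, keep_cov, drop = FALSE]
    data <- log_transform(fm$data)
    res$filter_report <- list(monitors = fm$report, covariates = fc)
    jsonlite::write_json(
      list(config_hash = cfg_hash,
           excluded_sites = fm$report$excluded_sites,
           excluded_covariates = fc$excluded_covariates),
      file.path(out_dir, "filter_report.json"), auto_unbox = TRUE
    )
    res$data <- data
  }

  if ("trends" %in% stages) {
    basis <- estimate_trend_basis(data, m = config$trends$m,
                                  df_per_year = config$trends$df_per_year)
    res$basis <- basis
    tr <- data.frame(period_start = format(basis$axis), basis$values)
    utils::write.csv(tr, file.path(out_dir, "trends.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = cfg_hash, m = basis$m,
           df_per_year = basis$df_per_year,
           source_sites = basis$source_sites,
           singular_values = basis$singular_values),
      file.path(out_dir, "trend_meta.json"), auto_unbox = TRUE, digits = NA
    )
  }

  if ("pls" %in% stages) {
    features <- build_feature_set(data, res$basis, n_comp = config$pls$n_scores)
    res$features <- features
    sc_long <- do.call(rbind, lapply(seq_along(features$scores), function(i) {
      data.frame(site_id = rownames(features$scores[[i]]),
                 trend_index = i - 1L,
                 features$scores[[i]][, -1, drop = FALSE])
    }))
    utils::write.csv(sc_long, file.path(out_dir, "pls_scores.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = cfg_hash, n_comp = features$n_comp,
           models = lapply(features$models, function(m) {
             list(center = as.list(m$center), scale = as.list(m$scale),
                  rotation = m$rotation, y_loadings = m$y_loadings,
                  y_mean = m$y_mean)
           })),
      file.path(out_dir, "pls_model.json"), auto_unbox = TRUE, digits = NA
    )
  }

  if ("fit" %in% stages) {
    kinds <- rep(if (config$fit$spatial_smooth) "exponential" else "independent",
                 res$basis$m + 1L)
    model <- fit_ml(data, res$basis, res$features,
                    st_structure(kinds),
                    n_starts = config$fit$n_starts, seed = config$seed)
    res$model <- model
    jsonlite::write_json(
      list(
        config_hash = cfg_hash, loglik = model$loglik,
        beta = lapply(model$beta, unclass),
        resid = unclass(model$resid),
        alpha = as.list(model$alpha)
      ),
      file.path(out_dir, "model_params.json"), auto_unbox = TRUE, digits = NA
    )
  }

  if ("cv" %in% stages || isTRUE(config$select$run) || "select" %in% stages) {
    sel <- model_selection_grid(
      data,
      home_scheme = config$cv$home_scheme,
      fixed_scheme = config$cv$fixed_scheme,
      seed = config$seed
    )
    res$selection <- sel
    utils::write.csv(sel$table, file.path(out_dir, "selection_table.csv"),
                     row.names = FALSE)
    reports <- sel$best$reports
    if (length(reports)) {
      utils::write.csv(
        do.call(rbind, lapply(names(reports), function(nm) {
          data.frame(stratum = nm, reports[[nm]]$per_site)
        })),
        file.path(out_dir, "cv_report.csv"), row.names = FALSE
      )
      jsonlite::write_json(
        c(list(config_hash = cfg_hash),
          lapply(reports, function(r) {
            list(scheme = r$scheme, n = r$n, rmse = r$rmse,
                 r2_cv = r$r2_cv, r2_cvreg = r$r2_cvreg)
          })),
        file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }

  if ("predict" %in% stages && !is.null(res$model)) {
    tgt_type <- config$predict$targets
    targets <- as.data.frame(data$sites[data$sites$site_type %in% tgt_type, ,
                                        drop = FALSE])
    if (nrow(targets)) {
      pr <- predict(res$model, targets = targets, covariates = data$covariates)
      lta <- long_term_average(pr)
      res$prediction <- pr
      res$lta <- lta
      pred_long <- data.frame(
        location_id = rep(rownames(pr$log_pred), ncol(pr$log_pred)),
        period_start = rep(colnames(pr$log_pred), each = nrow(pr$log_pred)),
        log_pred = as.vector(pr$log_pred),
        pred = as.vector(pr$pred),
        se_log = if (is.null(pr$se_log)) NA_real_ else as.vector(pr$se_log)
      )
      utils::write.csv(pred_long, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE)
      names(lta)[names(lta) == "site_id"] <- "location_id"
      utils::write.csv(lta, file.path(out_dir, "ltas.csv"), row.names = FALSE)
    }
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(res)
}
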