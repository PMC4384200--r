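#' Synthetic monitoring-campaign scenario configuration
#'
#' Describes a synthetic region emulating the unbalanced multi-tier
#' monitoring design: a few dozen regulatory (`aqs`) sites with multi-year
#' series and missing stretches, a handful of `fixed` study sites with a
#' contiguous block of two-week samples, many `home` sites visited 1--3 times
#' in different seasons, and `snapshot` clusters observed in 3 seasonal
#' periods. Defaults are sized like a mid-sized metropolitan campaign
#' (29 regulatory, 5 fixed, 86 home, 26 clusters of 4 snapshot sites) on a
#' 75-km region, with two generating time trends (one slow trend plus one
#' seasonal) and log-scale variance components typical of two-week
#' concentration data.
#'
#' @param n_aqs,n_fixed,n_home,n_snapshot_clusters,cluster_size site counts.
#' @param region_size_km side of the square region, km.
#' @param years span of the time axis.
#' @param m_true number of generating non-constant trends (1 or 2).
#' @param n_latent number of latent smooth spatial factors that drive both
#'   the informative covariates and the coefficient-field means. Geographic
#'   covariate sets are massively collinear (road, traffic, land-use and
#'   vegetation measures proxy a few underlying gradients), which is what
#'   makes 2--3 PLS scores sufficient; the generator reproduces that
#'   structure.
#' @param n_informative,n_noise covariate counts: noisy linear proxies of
#'   the latent factors, and pure-noise columns.
#' @param proxy_noise_sd idiosyncratic noise SD of each informative covariate
#'   about its latent-factor combination (latents have unit SD).
#' @param cov_range_km spatial correlation length of the latent factors.
#' @param n_distance_like how many informative covariates are exponentiated
#'   to a skewed, distance-like scale.
#' @param beta0_mean long-term mean of log concentration at the region
#'   centre (default `log(13)`, a typical fine-particulate level in ug/m3).
#' @param alpha_sd SD of the per-latent weights on the long-term-mean field;
#'   with the default 3 latents this gives covariate-driven site-mean log SD
#'   of roughly 0.25, i.e. site means spread 10--25% about the regional
#'   mean, typical of fine-particulate networks.
#' @param trend_alpha_sd per-latent weight SD of the trend-coefficient
#'   fields (smaller: seasonal amplitude varies less across a region than
#'   the long-term mean).
#' @param trend_mean regional mean of each trend-coefficient field on the
#'   unit-RMS trend scale (recycled over trends). The defaults give common
#'   seasonal/long-term swings of roughly 25--40% of the concentration
#'   level, typical of two-week pollutant series.
#' @param beta_range_km,beta_psill,beta_nugget exponential covariance of the
#'   coefficient fields (shared by all fields here).
#' @param resid_range_km,resid_psill,resid_nugget,resid_time_sill residual
#'   covariance components.
#' @param aqs_gap_rate i.i.d. missingness rate of regulatory observations on
#'   top of one contiguous multi-period outage per site.
#' @param home_visits_range inclusive range of two-week visits per home site.
#' @param lod_quantile when non-`NULL`, the limit of detection is set at this
#'   quantile of the generated concentrations and smaller values are
#'   substituted with LOD/2.
#' @param n_targets held-out prediction locations carried in the truth
#'   bundle.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_aqs = 29L, n_fixed = 5L, n_home = 86L,
                            n_snapshot_clusters = 26L, cluster_size = 4L,
                            region_size_km = 75, years = 4,
                            m_true = 2L,
                            n_latent = 3L, n_informative = 20L, n_noise = 10L,
                            proxy_noise_sd = 0.3,
                            cov_range_km = 20, n_distance_like = 2L,
                            beta0_mean = log(13), alpha_sd = 0.14,
                            trend_alpha_sd = 0.03,
                            trend_mean = c(0.35, 0.25),
                            beta_range_km = 10, beta_psill = 0.01,
                            beta_nugget = 0.0025,
                            resid_range_km = 30, resid_psill = 0.04,
                            resid_nugget = 0.01, resid_time_sill = 0.04,
                            aqs_gap_rate = 0.10,
                            home_visits_range = c(1L, 3L),
                            lod_quantile = NULL, n_targets = 150L,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_aqs + n_fixed >= 2L, m_true >= 1L, years > 0)
  class(cfg) <- "scenario_config"
  cfg
}

# smooth Gaussian field over site coordinates (exponential kernel)
gp_field <- function(x, y, range_km, sd = 1) {
  D <- as.matrix(stats::dist(cbind(x, y)))
  ch <- safe_chol(sd^2 * exp(-D / range_km) + diag(1e-8, length(x)))
  drop(crossprod(ch, stats::rnorm(length(x))))
}

#' Generate site locations and geographic covariates for a scenario
#'
#' Sites are placed uniformly over the square region (snapshot sites in
#' tight clusters around uniformly placed cluster centres, mimicking
#' near-source gradient sampling). A few latent smooth spatial factors are
#' drawn as Gaussian fields; each informative covariate is a noisy linear
#' proxy of the latents (a subset exponentiated to a skewed distance-like
#' scale), emulating the strong collinearity of real geographic covariate
#' sets; noise covariates are i.i.d. The true coefficient-field mean
#' surfaces are linear in the latents with seeded weights, so downstream
#' recovery is checkable against truth.
#'
#' @param config a [scenario_config()].
#' @return list with `sites` (an [st_sites()] incl. `n_targets` held-out
#'   `distributed` locations), `covariates` (data.frame for all sites),
#'   `latents` (site-by-factor matrix), `alpha_latent` (true latent weights
#'   per field) and `field_means` (true mean surface of each field at all
#'   sites).
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  L <- config$region_size_km
  ids <- types <- clus <- character(0)
  xs <- ys <- numeric(0)
  add <- function(k, type, prefix, cl = NA_character_, x = NULL, y = NULL) {
    if (k <= 0) return(invisible())
    ids <<- c(ids, sprintf("%s%03d", prefix, seq_len(k) + sum(types == type)))
    types <<- c(types, rep(type, k))
    clus <<- c(clus, rep(cl, k))
    xs <<- c(xs, if (is.null(x)) stats::runif(k, 0, L) else x)
    ys <<- c(ys, if (is.null(y)) stats::runif(k, 0, L) else y)
  }
  add(config$n_aqs, "aqs", "aqs")
  add(config$n_fixed, "fixed", "fix")
  add(config$n_home, "home", "home")
  for (cl in seq_len(config$n_snapshot_clusters)) {
    cx <- stats::runif(1, 0, L)
    cy <- stats::runif(1, 0, L)
    k <- config$cluster_size
    add(k, "snapshot", sprintf("snap_c%02d_", cl), sprintf("c%02d", cl),
        x = pmin(pmax(cx + stats::rnorm(k, sd = 1), 0), L),
        y = pmin(pmax(cy + stats::rnorm(k, sd = 1), 0), L))
  }
  add(config$n_targets, "distributed", "target")
  sites <- st_sites(data.frame(
    site_id = ids, site_type = types, x_km = xs, y_km = ys, cluster_id = clus
  ))
  n <- nrow(sites)
  # latent smooth factors driving both covariates and field means,
  # standardized across sites so the scenario's signal level is a fixed
  # condition rather than a per-seed draw
  latents <- vapply(seq_len(config$n_latent), function(j) {
    f <- gp_field(sites$x_km, sites$y_km, config$cov_range_km)
    (f - mean(f)) / stats::sd(f)
  }, numeric(n))
  inform <- seq_len(config$n_informative)
  loadings <- matrix(stats::rnorm(config$n_latent * config$n_informative),
                     config$n_latent, config$n_informative)
  loadings <- sweep(loadings, 2L, sqrt(colSums(loadings^2)), "/")
  cov <- matrix(0, n, config$n_informative + config$n_noise)
  cov[, inform] <- latents %*% loadings +
    stats::rnorm(n * config$n_informative, sd = config$proxy_noise_sd)
  skew <- utils::head(inform, config$n_distance_like)
  for (j in skew) cov[, j] <- exp(cov[, j])   # lognormal, distance-like skew
  for (j in setdiff(seq_len(ncol(cov)), inform)) cov[, j] <- stats::rnorm(n)
  colnames(cov) <- c(
    sprintf("geo_%02d", inform),
    sprintf("noise_%02d", seq_len(config$n_noise))
  )
  # true field means: intercept + latent-weighted surfaces
  nf <- config$m_true + 1L
  # effect sizes are fixed conditions: random direction, fixed norm
  sds <- c(config$alpha_sd, rep(config$trend_alpha_sd, config$m_true))
  alpha_latent <- vapply(sds, function(s) {
    w <- stats::rnorm(config$n_latent)
    w / sqrt(sum(w^2)) * s * sqrt(config$n_latent)
  }, numeric(config$n_latent))
  intercepts <- c(config$beta0_mean,
                  rep_len(config$trend_mean, config$m_true))
  field_means <- sweep(latents %*% alpha_latent, 2L, intercepts, "+")
  colnames(field_means) <- paste0("trend", 0:config$m_true)
  rownames(field_means) <- sites$site_id
  rownames(latents) <- sites$site_id
  list(
    sites = sites,
    covariates = data.frame(site_id = sites$site_id, cov,
                            stringsAsFactors = FALSE),
    latents = latents, alpha_latent = alpha_latent,
    field_means = field_means
  )
}

# seasonal helpers on the two-week grid
year_frac <- function(axis) {
  doy <- as.integer(format(axis + 7L, "%j"))   # period midpoint day-of-year
  doy / 365.25
}

# generating trends: one slow multi-year drift with a mild annual cycle,
# plus (m_true = 2) a pure annual cycle in quadrature
true_trends <- function(axis, m_true) {
  T_ <- length(axis)
  yf <- year_frac(axis)
  lin <- seq(-1, 1, length.out = T_)
  f1 <- -0.9 * lin + 0.5 * cos(2 * pi * yf)
  f <- cbind(f1)
  if (m_true >= 2L) f <- cbind(f, sin(2 * pi * yf))
  if (m_true >= 3L) f <- cbind(f, cos(4 * pi * yf))
  normalize_trends(f)
}

#' Generate a full synthetic monitoring campaign
#'
#' Builds the region ([generate_covariates()]), the two-week axis, the
#' generating smooth trends, and the observation schedule of each tier:
#' regulatory sites cover the whole axis minus one contiguous outage and
#' i.i.d. gaps; fixed sites a contiguous ~4-year block; home sites 1--3
#' visits in distinct seasons; snapshot clusters three seasonal periods
#' (winter, summer, and one of spring/fall, shared within a cluster). Log
#' concentrations are then simulated from the hierarchical model with the
#' configured true parameters, optionally left-censored at the LOD, and
#' returned on the original concentration scale alongside the truth bundle.
#'
#' @param config a [scenario_config()].
#' @return list of class `st_campaign`: `data` (an [st_dataset()], original
#'   scale, with covariates; held-out `distributed` target locations carry no
#'   observations), `truth` (list: `trends`, `basis`, `beta_fields`, `alpha`
#'   — covariate weights recast on the score scale is *not* provided; alpha
#'   here is per-field truth on the covariate scale —, `params`, `full_log`
#'   latent field, `target_ids`, `lta` true long-term averages of the
#'   realised field at every site, `n_below_lod`), and `config`.
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  region <- generate_covariates(config)
  sites <- region$sites
  start <- as.Date("2005-01-05")   # a Wednesday
  axis <- build_time_axis(start, start + round(config$years * 365.25))
  T_ <- length(axis)
  f <- true_trends(axis, config$m_true)
  basis <- trend_basis(f, axis)
  # the true mean design is the latent factor surfaces
  scores <- lapply(seq_len(config$m_true + 1L), function(i) {
    sc <- cbind(const = 1, region$latents)
    rownames(sc) <- sites$site_id
    sc
  })
  names(scores) <- paste0("trend", 0:config$m_true)
  intercepts <- c(config$beta0_mean,
                  rep_len(config$trend_mean, config$m_true))
  alpha <- lapply(seq_len(config$m_true + 1L), function(i) {
    c(intercepts[i], region$alpha_latent[, i])
  })
  beta <- replicate(config$m_true + 1L, cov_spec(
    "exponential", range = config$beta_range_km,
    psill = config$beta_psill, nugget = config$beta_nugget
  ), simplify = FALSE)
  resid <- resid_spec(
    range = config$resid_range_km, psill = config$resid_psill,
    nugget = config$resid_nugget, time_sill = config$resid_time_sill
  )
  set.seed(config$seed + 1L)
  pattern <- schedule_observations(sites, axis, config)
  sim <- simulate_st(sites, basis, scores, alpha, beta, resid,
                     pattern = pattern, seed = config$seed + 2L)
  obs <- sim$data$obs
  obs$value <- exp(obs$value)      # back to concentration scale
  n_below <- 0L
  lod <- NULL
  if (!is.null(config$lod_quantile)) {
    lod <- stats::quantile(obs$value, config$lod_quantile, names = FALSE)
    n_below <- sum(obs$value < lod)
    obs$value <- substitute_lod(obs$value, lod)
  }
  data <- st_dataset(obs, sites, axis, covariates = region$covariates,
                     log_scale = FALSE)
  lta <- rowMeans(exp(sim$full))
  names(lta) <- sites$site_id
  structure(
    list(
      data = data,
      truth = list(
        trends = f, basis = basis, beta_fields = sim$beta_fields,
        alpha = alpha, field_means = region$field_means,
        params = list(beta = beta, resid = resid),
        full_log = sim$full,
        target_ids = sites$site_id[sites$site_type == "distributed"],
        lta = lta, lod = lod, n_below_lod = n_below
      ),
      config = config
    ),
    class = "st_campaign"
  )
}

# observation schedule per tier; seasons are calendar quarters
schedule_observations <- function(sites, axis, config) {
  T_ <- length(axis)
  q <- quarters(axis + 7L)
  rows <- list()
  push <- function(sid, tt) {
    rows[[length(rows) + 1L]] <<- data.frame(site_id = sid, t = tt)
  }
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    type <- sites$site_type[i]
    if (type %in% c("aqs", "reference")) {
      tt <- seq_len(T_)
      # one contiguous outage of up to ~6 months, then i.i.d. gaps
      gap_len <- sample.int(max(1L, T_ %/% 8L), 1L)
      gap_at <- sample.int(T_ - gap_len + 1L, 1L)
      tt <- setdiff(tt, gap_at:(gap_at + gap_len - 1L))
      tt <- tt[stats::runif(length(tt)) > config$aqs_gap_rate]
      push(sid, tt)
    } else if (type == "fixed") {
      block <- min(T_, ceiling(4 * 365.25 / 14))
      s0 <- sample.int(T_ - block + 1L, 1L)
      push(sid, s0:(s0 + block - 1L))
    } else if (type == "home") {
      nv <- sample(seq(config$home_visits_range[1], config$home_visits_range[2]), 1L)
      # spread visits over distinct seasons where possible
      qs <- sample(c("Q1", "Q2", "Q3", "Q4"), nv)
      tt <- vapply(qs, function(qq) {
        cand <- which(q == qq)
        if (!length(cand)) sample.int(T_, 1L) else sample(cand, 1L)
      }, 0L)
      push(sid, unique(tt))
    }
    # snapshot handled per cluster below
  }
  snap <- sites[sites$site_type == "snapshot", , drop = FALSE]
  for (cl in unique(snap$cluster_id)) {
    qs <- c("Q1", "Q3", sample(c("Q2", "Q4"), 1L))
    tt <- vapply(qs, function(qq) {
      cand <- which(q == qq)
      if (!length(cand)) sample.int(T_, 1L) else sample(cand, 1L)
    }, 0L)
    for (sid in snap$site_id[snap$cluster_id == cl]) push(sid, tt)
  }
  do.call(rbind, rows)
}
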