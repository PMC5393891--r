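#' Default stable-density surface
#'
#' Smooth surface giving expected stable elephant density (elephants/km^2)
#' as a log-additive function of mean EVI, the proportion of area within
#' 12 km of water, and PIKE. The default coefficients are calibrated so
#' zero-poaching densities span 0.23-4.30 elephants/km^2 across the default
#' covariate box (EVI 0.05-0.404, water 0.1-1) — the range reported for
#' ecological benchmarks of large savanna protected areas — with density
#' increasing in productivity and water and decreasing in poaching.
#'
#' @param evi mean Enhanced Vegetation Index, in `[0, 1]`.
#' @param water proportion of the area within 12 km of water, in `[0, 1]`.
#' @param pike proportion of illegally killed elephants, in `[0, 1]`.
#' @return expected density (elephants/km^2), vectorised.
#' @export
default_stable_surface <- function(evi, water, pike) {
  0.158 * exp(4.6 * evi + 1.45 * water - 2.2 * pike)
}

#' Specify a synthetic elephant study
#'
#' Bundles every parameter of the synthetic-data generator: number of
#' protected areas, covariate ranges, the poaching (PIKE) process, count
#' survey error, the ground-truth stable-density surface and the
#' negative-binomial dispersion of ecological scatter around it. Defaults
#' reproduce the scale of the continental study the package is built around:
#' 73 protected areas of 1,020-47,666 km^2, mean EVI up to 0.404, and a
#' dispersion of 3.10.
#'
#' @param n_areas number of protected areas.
#' @param area_range_km2 length-2 positive range of areas (km^2); sampled
#'   log-uniformly to mimic the right skew of real protected-area sizes.
#' @param evi_range,water_range length-2 ranges in `[0, 1]`; sampled
#'   uniformly.
#' @param pike_coefs coefficients `(intercept, evi, water)` of the true
#'   logit-linear PIKE process. The defaults give site PIKE spanning
#'   roughly 0.05-0.90 with mean near 0.4, matching the spread of
#'   empirical carcass ratios (whose observed minimum is 0.00) while
#'   keeping poaching only weakly tied to the habitat covariates.
#' @param pike_logit_sd SD of site-level noise on the PIKE logit.
#' @param carcass_rate expected carcasses found per monitored site per year.
#' @param survey_cv coefficient of variation of count survey error (>= 0).
#' @param total_count_prop proportion of counts that are total counts
#'   (reported with SE = 0).
#' @param true_surface function `(evi, water, pike) -> density` giving the
#'   ground-truth expected stable density (elephants/km^2).
#' @param nb_dispersion negative-binomial dispersion theta (> 0) of
#'   ecological scatter of stable sizes around the surface
#'   (variance = mu + mu^2/theta).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_areas = 73,
                            area_range_km2 = c(1020, 47666),
                            evi_range = c(0.05, 0.404),
                            water_range = c(0.1, 1),
                            pike_coefs = c(0.4, -1.5, -0.8),
                            pike_logit_sd = 1.0,
                            carcass_rate = 6,
                            survey_cv = 0.1,
                            total_count_prop = 0.2,
                            true_surface = default_stable_surface,
                            nb_dispersion = 3.10,
                            seed = 1L) {
  chk_range <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < lo || r[2] > hi)
      stop(nm, " must be an ordered range within [", lo, ", ", hi, "]")
  }
  if (n_areas < 0 || n_areas != round(n_areas)) stop("n_areas must be a non-negative integer")
  chk_range(area_range_km2, "area_range_km2", lo = 0)
  chk_range(evi_range, "evi_range", 0, 1)
  chk_range(water_range, "water_range", 0, 1)
  if (survey_cv < 0) stop("survey_cv must be >= 0")
  if (total_count_prop < 0 || total_count_prop > 1) stop("total_count_prop must be in [0, 1]")
  if (!is.function(true_surface)) stop("true_surface must be a function")
  if (!is.finite(nb_dispersion) || nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  structure(list(
    n_areas = as.integer(n_areas), area_range_km2 = area_range_km2,
    evi_range = evi_range, water_range = water_range,
    pike_coefs = pike_coefs, pike_logit_sd = pike_logit_sd,
    carcass_rate = carcass_rate, survey_cv = survey_cv,
    total_count_prop = total_count_prop, true_surface = true_surface,
    nb_dispersion = nb_dispersion, seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Generate a synthetic protected-area covariate table
#'
#' Draws `n_areas` protected areas with areas log-uniform in
#' `area_range_km2`, EVI and water proportions uniform within their ranges,
#' a true PIKE from the logit-linear process in the spec, and ground-truth
#' stable densities from the spec surface. Ecological scatter of true stable
#' size around the surface is negative binomial with the spec dispersion.
#'
#' @param spec a [simulation_spec()].
#' @return a data frame with one row per area: `area_id`, `name`, `country`,
#'   `area_km2`, `evi`, `prop_12_water`, `true_pike`,
#'   `true_density_current` (realised stable density under current PIKE),
#'   `true_density_benchmark` (surface density at PIKE = 0),
#'   `recent_estimate`, `recent_year`.
#' @export
generate_protected_areas <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_areas
  if (n == 0) {
    return(data.frame(area_id = character(), name = character(),
                      country = character(), area_km2 = numeric(),
                      evi = numeric(), prop_12_water = numeric(),
                      true_pike = numeric(), true_density_current = numeric(),
                      true_density_benchmark = numeric(),
                      recent_estimate = numeric(), recent_year = integer()))
  }
  area <- exp(runif(n, log(spec$area_range_km2[1]), log(spec$area_range_km2[2])))
  evi <- runif(n, spec$evi_range[1], spec$evi_range[2])
  water <- runif(n, spec$water_range[1], spec$water_range[2])
  b <- spec$pike_coefs
  pike <- plogis(b[1] + b[2] * evi + b[3] * water + rnorm(n, 0, spec$pike_logit_sd))
  mu_cur <- spec$true_surface(evi, water, pike)
  mu_ben <- spec$true_surface(evi, water, 0)
  if (any(mu_cur < 0) || any(mu_ben < 0)) stop("true_surface returned a negative density")
  # realised equilibrium size scatters around the surface (NB); this is the
  # level a stable time series fluctuates about
  size_cur <- rnbinom(n, mu = pmax(mu_cur * area, 1e-8), size = spec$nb_dispersion)
  dens_cur <- pmax(size_cur, 1) / area
  # recent estimates emulate depleted populations: median near 13% of
  # benchmark, a handful near or above it
  depletion <- pmin(exp(rnorm(n, log(0.134), 0.9)), 1.2)
  recent <- round(depletion * mu_ben * area)
  data.frame(
    area_id = sprintf("PA%03d", seq_len(n)),
    name = sprintf("Synthetic Protected Area %d", seq_len(n)),
    country = sprintf("Country%02d", 1 + (seq_len(n) - 1) %% 21),
    area_km2 = area, evi = evi, prop_12_water = water,
    true_pike = pike, true_density_current = dens_cur,
    true_density_benchmark = mu_ben,
    recent_estimate = recent,
    recent_year = sample(2005:2015, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate a count time series for one protected area
#'
#' Produces a yearly sequence of population estimates following one of the
#' five candidate growth trajectories, with survey error drawn from a normal
#' distribution truncated at zero (SD = `survey_cv` x expected count) and a
#' reported SE equal to `survey_cv` x estimate. Total counts
#' (`survey_cv = 0`) are exact with SE = 0.
#'
#' @param area one-row data frame (or list) with `area_id` and `area_km2`.
#' @param model_id one of `"null"`, `"linear"`, `"exponential"`,
#'   `"logistic"`, `"gompertz"`.
#' @param true_params named list/vector of trajectory parameters on the
#'   density scale (see [evaluate_growth_model()]).
#' @param n_counts number of counts (>= 2).
#' @param survey_cv coefficient of variation of survey error (>= 0).
#' @param years optional vector of survey years (default every other year
#'   from 1995).
#' @param reliability survey reliability class label for all counts.
#' @param seed optional integer seed.
#' @return data frame `area_id, year, estimate, se, reliability`.
#' @export
generate_time_series <- function(area, model_id, true_params, n_counts,
                                 survey_cv, years = NULL, reliability = "A",
                                 seed = NULL) {
  if (n_counts < 2) stop("n_counts must be >= 2")
  if (survey_cv < 0) stop("survey_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(years)) years <- seq(1995, by = 2, length.out = n_counts)
  if (length(years) != n_counts) stop("years must have length n_counts")
  t <- years - years[1]
  dens <- evaluate_growth_model(model_id, true_params, t)
  expected <- dens * area$area_km2
  est <- rnorm_trunc0(n_counts, expected, survey_cv * expected)
  data.frame(area_id = area$area_id, year = years, estimate = est,
             se = survey_cv * est, reliability = reliability,
             stringsAsFactors = FALSE)
}

#' Generate a stable-density training table with known truth
#'
#' Emulates the training set that the benchmark GAM is fitted to: `n_train`
#' areas with covariates, a ground-truth expected density from the spec
#' surface, and an observed stable size built from two noise layers: the
#' realised equilibrium is negative binomial around surface x area
#' (ecological scatter, dispersion `nb_dispersion`), and the observed
#' density adds survey error, truncated normal with
#' `se = se_cv` x density — the same uncertainty the SE column reports.
#'
#' @param spec a [simulation_spec()].
#' @param n_train number of training areas (default 18, the size of the
#'   study's training set).
#' @param se_cv relative SE attached to observed stable densities
#'   (default 0.25, the scale typical of equilibrium densities extracted
#'   from short aerial-survey time series).
#' @return list with `training` (data frame `area_id, area_km2, evi,
#'   prop_12_water, pike, stable_size, stable_density, stable_density_se,
#'   log_area, true_density`) and `surface` (the ground-truth function).
#' @export
generate_stable_density_training <- function(spec, n_train = 18,
                                             se_cv = 0.25) {
  stopifnot(inherits(spec, "simulation_spec"))
  spec2 <- spec
  spec2$n_areas <- as.integer(n_train)
  pa <- generate_protected_areas(spec2)
  mu <- spec$true_surface(pa$evi, pa$prop_12_water, pa$true_pike)
  if (any(mu < 0)) stop("true_surface returned a negative density")
  size <- rnbinom(n_train, mu = pmax(mu * pa$area_km2, 1e-8),
                  size = spec$nb_dispersion)
  dens_eco <- pmax(size, 1) / pa$area_km2
  # measurement layer: the density extracted from a count series is the
  # equilibrium plus survey error, which is what the SE column describes
  dens <- rnorm_trunc0(n_train, dens_eco, se_cv * dens_eco)
  training <- data.frame(
    area_id = pa$area_id, area_km2 = pa$area_km2, evi = pa$evi,
    prop_12_water = pa$prop_12_water, pike = pa$true_pike,
    stable_size = dens * pa$area_km2, stable_density = dens,
    stable_density_se = se_cv * dens, log_area = log(pa$area_km2),
    true_density = mu, stringsAsFactors = FALSE
  )
  list(training = training, surface = spec$true_surface)
}

#' Generate carcass records for monitored sites
#'
#' Per site-year carcass records with illegal carcasses binomial around each
#' site's true PIKE: `illegal ~ Binomial(total, true_pike)`.
#'
#' @param sites character vector of site ids.
#' @param true_pike per-site true PIKE in `[0, 1]` (recycled).
#' @param totals either a single expected per-site-year carcass count
#'   (Poisson draws) or, with `totals_exact = TRUE`, a vector of exact
#'   per-site totals placed in the first year.
#' @param years carcass-monitoring years.
#' @param totals_exact use `totals` as exact per-site totals.
#' @param seed optional integer seed.
#' @return data frame `site_id, year, illegal_carcasses, total_carcasses,
#'   true_pike`.
#' @export
generate_carcass_records <- function(sites, true_pike, totals = 6,
                                     years = 2002:2014, totals_exact = FALSE,
                                     seed = NULL) {
  if (any(true_pike < 0 | true_pike > 1)) stop("true_pike must be in [0, 1]")
  if (any(totals < 0)) stop("totals must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  true_pike <- rep_len(true_pike, length(sites))
  if (totals_exact) {
    totals <- rep_len(totals, length(sites))
    if (any(totals != round(totals))) stop("exact totals must be integers")
    df <- data.frame(site_id = sites, year = years[1],
                     total_carcasses = as.integer(totals),
                     true_pike = true_pike, stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(site_id = sites, year = years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$total_carcasses <- rpois(nrow(grid), rep(totals, length.out = length(sites))[
      match(grid$site_id, sites)])
    grid$true_pike <- true_pike[match(grid$site_id, sites)]
    df <- grid
  }
  df$illegal_carcasses <- rbinom(nrow(df), df$total_carcasses, df$true_pike)
  df[, c("site_id", "year", "illegal_carcasses", "total_carcasses", "true_pike")]
}

#' Generate a complete synthetic study dataset
#'
#' Builds all three pipeline inputs with known ground truth: the
#' protected-area table, count time series for a subset of areas (by default
#' 18 stable, 4 exponentially changing, 1 linearly changing — the dynamics
#' mix of the study's 23 adequate series — plus ineligible series that the
#' eligibility filter must reject), and carcass records for a monitored
#' subset (default 43 sites).
#'
#' The stable (null-dynamics) areas fluctuate around their realised
#' equilibrium density (`true_density_current`), so the stable densities a
#' downstream fit extracts are negative-binomial draws around the spec
#' surface — exactly the ecological scatter the benchmark GAM assumes.
#'
#' @param spec a [simulation_spec()].
#' @param n_null,n_exponential,n_linear numbers of eligible series by
#'   generating dynamics.
#' @param n_ineligible number of additional series that fail eligibility
#'   (too short, unreliable class, or population < 500).
#' @param n_monitored number of areas with carcass (PIKE) monitoring.
#' @param n_counts counts per eligible series.
#' @return list with `areas`, `counts`, `carcasses` data frames and `truth`
#'   (the areas table including `true_*` columns plus the spec).
#' @export
generate_study_dataset <- function(spec, n_null = 18, n_exponential = 4,
                                   n_linear = 1, n_ineligible = 10,
                                   n_monitored = 43, n_counts = 8) {
  stopifnot(inherits(spec, "simulation_spec"))
  pa <- generate_protected_areas(spec)
  n_dyn <- n_null + n_exponential + n_linear
  if (n_dyn + n_ineligible > nrow(pa))
    stop("more series requested than areas available")
  set.seed(stage_seed(spec$seed, 2L))
  # areas with largest realised populations get usable series, echoing the
  # >= 500 individuals criterion
  pop <- pa$true_density_current * pa$area_km2
  ord <- order(pop, decreasing = TRUE)
  dyn_idx <- ord[seq_len(n_dyn)]
  model_of <- rep(c("null", "exponential", "linear"),
                  c(n_null, n_exponential, n_linear))
  model_of <- sample(model_of)
  counts <- vector("list", n_dyn + n_ineligible)
  for (i in seq_len(n_dyn)) {
    a <- pa[dyn_idx[i], ]
    d0 <- a$true_density_current
    params <- switch(model_of[i],
      null = list(K = d0),
      exponential = list(N0 = d0, r = sample(c(-0.06, 0.06), 1)),
      linear = list(a = d0, b = 0.04 * d0))
    cv <- if (runif(1) < spec$total_count_prop) 0 else spec$survey_cv
    counts[[i]] <- generate_time_series(a, model_of[i], params, n_counts,
                                        survey_cv = cv)
  }
  inel_idx <- ord[n_dyn + seq_len(n_ineligible)]
  for (j in seq_len(n_ineligible)) {
    a <- pa[inel_idx[j], ]
    params <- list(K = a$true_density_current)
    mode <- j %% 3
    counts[[n_dyn + j]] <- switch(as.character(mode),
      "0" = generate_time_series(a, "null", params, 3, spec$survey_cv),
      "1" = generate_time_series(a, "null", params, n_counts, spec$survey_cv,
                                 reliability = "C"),
      "2" = {
        ts <- generate_time_series(a, "null", params, n_counts, spec$survey_cv)
        ts$estimate <- ts$estimate * 300 / max(ts$estimate)  # < 500 animals
        ts$se <- spec$survey_cv * ts$estimate
        ts
      })
  }
  counts <- do.call(rbind, counts)
  dyn_truth <- data.frame(area_id = pa$area_id[dyn_idx],
                          true_model = model_of, stringsAsFactors = FALSE)
  # carcass monitoring targets the major populations first (the areas with
  # usable time series), with the remaining monitored sites drawn at random
  n_monitored <- min(n_monitored, nrow(pa))
  extra <- setdiff(seq_len(nrow(pa)), dyn_idx)
  mon_idx <- sort(c(dyn_idx[seq_len(min(n_dyn, n_monitored))],
                    sample(extra, max(0, n_monitored - n_dyn))))
  carc <- generate_carcass_records(pa$area_id[mon_idx],
                                   pa$true_pike[mon_idx],
                                   totals = spec$carcass_rate,
                                   seed = stage_seed(spec$seed, 3L))
  amalg <- amalgamate_carcasses(carc)
  pa$pike_empirical <- NA_real_
  ok <- amalg$total >= 20
  pa$pike_empirical[match(amalg$site_id[ok], pa$area_id)] <-
    amalg$illegal[ok] / amalg$total[ok]
  areas <- pa[, c("area_id", "name", "country", "area_km2", "evi",
                  "prop_12_water", "pike_empirical", "recent_estimate",
                  "recent_year")]
  list(areas = areas,
       counts = counts,
       carcasses = carc[, c("site_id", "year", "illegal_carcasses",
                            "total_carcasses")],
       truth = list(areas = pa, dynamics = dyn_truth, spec = spec))
}

#' Write a synthetic study dataset to CSV files
#'
#' Writes `areas.csv`, `counts.csv` and `carcasses.csv` in the schemas the
#' pipeline consumes, plus `truth.csv` (the per-area ground truth: true
#' PIKE and true stable densities) for recovery tests.
#'
#' @param dataset a [generate_study_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(dataset$areas, "areas.csv")
  wr(dataset$counts, "counts.csv")
  wr(dataset$carcasses, "carcasses.csv")
  wr(dataset$truth$areas, "truth.csv")
  invisible(dir)
}
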