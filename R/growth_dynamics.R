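GROWTH_MODELS <- c("null", "linear", "exponential", "logistic", "gompertz")

#' Evaluate a candidate growth trajectory
#'
#' Density (elephants/km^2) at time `t` (years since the first count) for
#' the five candidate models:
#' \describe{
#'   \item{null}{`K` — no trend, density fluctuates about an equilibrium.}
#'   \item{linear}{`a + b t`.}
#'   \item{exponential}{`N0 exp(r t)`.}
#'   \item{logistic}{`K / (1 + ((K - N0)/N0) exp(-r t))`.}
#'   \item{gompertz}{`K exp(log(N0/K) exp(-r t))`.}
#' }
#'
#' @param model_id one of `"null"`, `"linear"`, `"exponential"`,
#'   `"logistic"`, `"gompertz"`.
#' @param params named list/vector with the parameters the model needs
#'   (`K`, `r`, `N0`, `a`, `b`).
#' @param t numeric vector of years since the first count.
#' @return density vector.
#' @export
evaluate_growth_model <- function(model_id, params, t) {
  model_id <- match.arg(model_id, GROWTH_MODELS)
  p <- as.list(params)
  need <- function(nms) {
    miss <- setdiff(nms, names(p))
    if (length(miss)) stop("missing parameter(s) for ", model_id, ": ",
                           paste(miss, collapse = ", "))
  }
  switch(model_id,
    null = { need("K"); rep_len(p$K, length(t)) },
    linear = { need(c("a", "b")); p$a + p$b * t },
    exponential = {
      need(c("N0", "r"))
      if (p$N0 <= 0) stop("N0 must be > 0 for the exponential model")
      p$N0 * exp(p$r * t)
    },
    logistic = {
      need(c("K", "N0", "r"))
      if (p$N0 <= 0 || p$K <= 0) stop("K and N0 must be > 0 for the logistic model")
      p$K / (1 + ((p$K - p$N0) / p$N0) * exp(-p$r * t))
    },
    gompertz = {
      need(c("K", "N0", "r"))
      if (p$N0 <= 0 || p$K <= 0) stop("K and N0 must be > 0 for the Gompertz model")
      p$K * exp(log(p$N0 / p$K) * exp(-p$r * t))
    })
}

#' Small-sample-corrected AIC for least-squares fits
#'
#' `AICc = n log(rss/n) + 2k + 2k(k+1)/(n - k - 1)`, with `k` counting all
#' estimated parameters including the residual variance. A model with
#' `n <= k + 1` is inadmissible and gets `NA`; an exact fit
#' (`rss <= rss_floor`) gets `-Inf` by convention so it always wins.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of observations.
#' @param k number of estimated parameters including the error variance.
#' @param rss_floor threshold under which a fit is treated as exact.
#' @return AICc value (vectorised).
#' @export
aicc <- function(rss, n, k, rss_floor = 1e-12) {
  out <- ifelse(n <= k + 1, NA_real_,
                n * log(pmax(rss, rss_floor) / n) + 2 * k +
                  2 * k * (k + 1) / (n - k - 1))
  out[rss <= rss_floor & n > k + 1] <- -Inf
  out
}

#' Keep count time series adequate for trend assessment
#'
#' A series qualifies when, restricting to counts from `min_year` onwards
#' with reliability in the accepted classes, it has at least `min_counts`
#' counts and a population of at least `min_pop` individuals (largest
#' qualifying estimate).
#'
#' @param counts data frame `area_id, year, estimate, se, reliability`.
#' @param min_pop minimum population size (default 500).
#' @param min_counts minimum number of qualifying counts (default 5).
#' @param min_year earliest qualifying survey year (default 1989).
#' @param reliability accepted survey-reliability classes (default A and B).
#' @return list with `eligible` (named list of per-area data frames, sorted
#'   by year) and `summary` (per-area counts kept/dropped with a reason for
#'   exclusion).
#' @export
filter_eligible_series <- function(counts, min_pop = 500, min_counts = 5,
                                   min_year = 1989,
                                   reliability = c("A", "B")) {
  stopifnot(all(c("area_id", "year", "estimate", "se", "reliability") %in%
                  names(counts)))
  split_counts <- split(counts, counts$area_id)
  eligible <- list()
  summ <- lapply(names(split_counts), function(id) {
    s <- split_counts[[id]]
    keep <- s$year >= min_year & s$reliability %in% reliability
    q <- s[keep, , drop = FALSE]
    q <- q[order(q$year), , drop = FALSE]
    reason <- NA_character_
    if (nrow(q) < min_counts) reason <- "too_few_counts"
    else if (max(q$estimate) < min_pop) reason <- "population_below_minimum"
    if (is.na(reason)) eligible[[id]] <<- q
    data.frame(area_id = id, n_counts = nrow(s), n_qualifying = nrow(q),
               eligible = is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  list(eligible = eligible, summary = do.call(rbind, summ))
}

# density series and time origin for a series
series_density <- function(series, area_km2 = NULL) {
  a <- area_km2 %||% series$area_km2[1] %||% attr(series, "area_km2")
  if (is.null(a) || is.na(a)) stop("area_km2 must be supplied (column or argument)")
  list(t = series$year - min(series$year), dens = series$estimate / a, area = a)
}

#' Fit one candidate growth model to a count time series
#'
#' Least squares on the density scale (estimate / area) against years since
#' the first count. The null and linear models have closed-form solutions;
#' exponential, logistic and Gompertz use bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with multiple starts (`K0` = mean of the last
#' three densities, `N0` = first density, the log-scale OLS slope as the
#' exponential rate start) and positivity bounds on `K` and `N0`.
#'
#' @param series data frame `year, estimate` (ordered), plus `area_km2`
#'   column or via the argument.
#' @param model_id candidate model id.
#' @param area_km2 area (km^2) if not a column of `series`.
#' @return object of class `growth_fit`: list with `model_id`, `params`,
#'   `rss`, `n`, `k`, `aicc`, `converged`, `fitted`.
#' @export
fit_growth_model <- function(series, model_id, area_km2 = NULL) {
  model_id <- match.arg(model_id, GROWTH_MODELS)
  sd_ <- series_density(series, area_km2)
  t <- sd_$t; dens <- sd_$dens; n <- length(dens)
  done <- function(params, rss, k, converged = TRUE) {
    structure(list(model_id = model_id, params = params, rss = rss, n = n,
                   k = k, aicc = if (converged) aicc(rss, n, k) else Inf,
                   converged = converged,
                   fitted = if (converged)
                     evaluate_growth_model(model_id, params, t) else NULL,
                   t = t, density = dens),
              class = "growth_fit")
  }
  if (model_id == "null") {
    K <- mean(dens)
    return(done(c(K = K), sum((dens - K)^2), k = 2))
  }
  if (model_id == "linear") {
    cf <- ols_line(t, dens)
    return(done(c(a = cf$a, b = cf$b), cf$rss, k = 3))
  }
  # Levenberg-Marquardt on the residual function directly (the formula
  # interface is far too slow inside 1000-run robustness loops)
  N0_0 <- max(dens[1], 1e-6)
  K_0 <- max(mean(tail(dens, 3)), 1e-6)
  r_log <- if (all(dens > 0)) ols_line(t, log(dens))$b else NA
  if (model_id == "exponential") {
    resid_fn <- function(p) p[1] * exp(p[2] * t) - dens
    starts <- lapply(if (is.na(r_log)) c(-0.05, 0.05) else r_log,
                     function(r) c(N0_0, r))
    lower <- c(1e-10, -5); upper <- c(Inf, 5)
    nm <- c("N0", "r"); k <- 3
  } else {
    resid_fn <- if (model_id == "logistic")
      function(p) p[1] / (1 + ((p[1] - p[2]) / p[2]) * exp(-p[3] * t)) - dens
    else
      function(p) p[1] * exp(log(p[2] / p[1]) * exp(-p[3] * t)) - dens
    starts <- list(c(K_0, N0_0, 0.1), c(2 * K_0, 0.5 * N0_0, 0.3))
    lower <- c(1e-10, 1e-10, -5); upper <- c(Inf, Inf, 5)
    nm <- c("K", "N0", "r"); k <- 4
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(st, lower, upper, resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    return(done(params = NULL, rss = Inf, k = k, converged = FALSE))
  }
  done(setNames(best$par, nm), best$rss, k = k)
}

# closed-form OLS of y on x (slope, intercept, rss, two-sided slope p)
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  res <- y - a - b * x
  rss <- sum(res^2)
  p <- if (n > 2 && rss > 0) {
    se_b <- sqrt(rss / (n - 2) / sxx)
    2 * stats::pt(abs(b / se_b), n - 2, lower.tail = FALSE)
  } else NA_real_
  list(a = a, b = b, rss = rss, p = p)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth fit:", x$model_id, "(n =", x$n, ")\n")
  if (x$converged) {
    cat("  params:", paste(names(x$params),
                           signif(x$params, 4), sep = "=", collapse = ", "), "\n")
    cat("  rss =", signif(x$rss, 4), " AICc =", signif(x$aicc, 5), "\n")
  } else cat("  did not converge\n")
  invisible(x)
}

#' Two-sided test for a linear trend in density
#'
#' Ordinary least squares of density on calendar year; returns the two-sided
#' p-value for the slope. Used to confirm that populations classed as stable
#' show no significant change over time. A series with zero density variance
#' returns slope 0 and p = 1.
#'
#' @inheritParams fit_growth_model
#' @return list with `slope` and `p_value`.
#' @export
test_linear_trend <- function(series, area_km2 = NULL) {
  sd_ <- series_density(series, area_km2)
  if (length(sd_$t) < 3) stop("need at least 3 counts")
  if (var(sd_$t) == 0) stop("years have zero variance")
  if (var(sd_$dens) == 0) return(list(slope = 0, p_value = 1))
  fit <- ols_line(sd_$t, sd_$dens)
  list(slope = fit$b, p_value = if (is.na(fit$p)) 0 else fit$p)
}

#' Select the best growth model for a series by AICc
#'
#' Fits all admissible candidates (a candidate needs `n > k + 1`) and picks
#' the minimum-AICc model; AICc ties are broken towards fewer parameters.
#'
#' @inheritParams fit_growth_model
#' @param models candidate ids to compare.
#' @param linear_trend also run [test_linear_trend()] (skipped inside
#'   Monte Carlo robustness loops for speed).
#' @return object of class `model_selection`: list with `table` (per-model
#'   `model, k, rss, aicc, delta_aicc, converged, admissible`),
#'   `best_model_id`, `fits` (named list of `growth_fit`s),
#'   `linear_trend_p`.
#' @export
select_best_model <- function(series, area_km2 = NULL,
                              models = GROWTH_MODELS,
                              linear_trend = TRUE) {
  fits <- lapply(models, function(m) fit_growth_model(series, m, area_km2))
  names(fits) <- models
  tab <- data.frame(
    model = models,
    k = vapply(fits, function(f) f$k, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  tab$admissible <- tab$converged & !is.na(tab$aicc)
  if (sum(tab$admissible) < 2) stop("fewer than 2 admissible candidate fits")
  amin <- min(tab$aicc[tab$admissible])
  tab$delta_aicc <- ifelse(tab$admissible,
                           ifelse(is.infinite(amin) & is.infinite(tab$aicc),
                                  0, tab$aicc - amin), NA_real_)
  tied <- which(tab$admissible & tab$delta_aicc <= 1e-8)
  best <- tied[which.min(tab$k[tied])]
  lt <- if (linear_trend)
    tryCatch(test_linear_trend(series, area_km2),
             error = function(e) list(slope = NA_real_, p_value = NA_real_))
  else list(slope = NA_real_, p_value = NA_real_)
  structure(list(table = tab, best_model_id = tab$model[best], fits = fits,
                 linear_trend_p = lt$p_value),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Best model:", x$best_model_id,
      " (linear-trend p =", signif(x$linear_trend_p, 3), ")\n")
  print(x$table[, c("model", "k", "rss", "aicc", "delta_aicc")],
        row.names = FALSE)
  invisible(x)
}

#' Robustness of model selection under count uncertainty
#'
#' Simulates `n_sims` versions of a series by drawing each count from a
#' normal distribution (truncated at zero) with its reported estimate and
#' SE, re-runs model selection on each, and reports (a) the proportion of
#' runs whose best model matches the original selection and (b) the stable
#' density and its SE as the mean and SD of the null-model equilibrium `K`
#' fitted to each simulated series. Series whose counts all have SE = 0 are
#' degenerate: robustness is 1 and the SE is 0.
#'
#' @inheritParams fit_growth_model
#' @param n_sims number of Monte Carlo series (default 1000).
#' @param seed integer seed.
#' @param models candidate ids.
#' @return list with `robustness`, `stable_density`, `stable_density_se`,
#'   `best_model_id`, `n_sims`, `n_failed`, `match_counts`.
#' @export
assess_robustness <- function(series, area_km2 = NULL, n_sims = 1000,
                              seed = 1L, models = GROWTH_MODELS) {
  orig <- select_best_model(series, area_km2, models)
  sd_ <- series_density(series, area_km2)
  if (all(series$se == 0)) {
    K <- mean(sd_$dens)
    return(list(robustness = 1, stable_density = K, stable_density_se = 0,
                best_model_id = orig$best_model_id, n_sims = n_sims,
                n_failed = 0L,
                match_counts = setNames(n_sims, orig$best_model_id)))
  }
  set.seed(seed)
  picks <- character(n_sims)
  Ks <- numeric(n_sims)
  failed <- 0L
  sim <- series
  for (i in seq_len(n_sims)) {
    sim$estimate <- rnorm_trunc0(nrow(series), series$estimate, series$se)
    sel <- tryCatch(select_best_model(sim, area_km2, models,
                                      linear_trend = FALSE),
                    error = function(e) NULL)
    if (is.null(sel)) { failed <- failed + 1L; picks[i] <- NA; Ks[i] <- NA; next }
    picks[i] <- sel$best_model_id
    Ks[i] <- mean(sim$estimate / sd_$area)  # null-model K of the simulated series
  }
  ok <- !is.na(picks)
  list(robustness = mean(picks[ok] == orig$best_model_id),
       stable_density = mean(Ks[ok]), stable_density_se = sd(Ks[ok]),
       best_model_id = orig$best_model_id, n_sims = n_sims,
       n_failed = failed, match_counts = table(picks[ok]))
}

#' Extract stable densities from all eligible series
#'
#' Runs model selection, the linear-trend check and the count-uncertainty
#' robustness assessment for every eligible series, and extracts stable
#' densities (with SEs) from the series where the null model is selected.
#' Series best described by linear or exponential change are excluded from
#' training, as are (if any) logistic/Gompertz selections.
#'
#' @param eligible named list of per-area series (see
#'   [filter_eligible_series()]); each needs an `area_km2` column or a
#'   matching entry in `areas`.
#' @param areas optional data frame `area_id, area_km2` to supply areas.
#' @param n_sims robustness Monte Carlo size.
#' @param seed master seed (per-series seeds derived from it).
#' @return list with `selection_report` (one row per series: best model,
#'   per-model AICc columns, robustness, linear-trend p) and
#'   `stable_densities` (`area_id, density, se, n_sims` for null-selected
#'   series).
#' @export
extract_stable_densities <- function(eligible, areas = NULL, n_sims = 1000,
                                     seed = 1L) {
  rows <- list(); stab <- list()
  for (i in seq_along(eligible)) {
    id <- names(eligible)[i]
    s <- eligible[[id]]
    a <- if (!is.null(areas)) areas$area_km2[match(id, areas$area_id)] else NULL
    sel <- select_best_model(s, a)
    rob <- assess_robustness(s, a, n_sims = n_sims,
                             seed = stage_seed(seed, i))
    ai <- setNames(as.list(sel$table$aicc), paste0("aicc_", sel$table$model))
    rows[[id]] <- data.frame(area_id = id, n_counts = nrow(s),
                             best_model = sel$best_model_id, ai,
                             robustness = rob$robustness,
                             linear_trend_p = sel$linear_trend_p,
                             stringsAsFactors = FALSE)
    if (sel$best_model_id == "null") {
      stab[[id]] <- data.frame(area_id = id, density = rob$stable_density,
                               se = rob$stable_density_se,
                               n_sims = n_sims, stringsAsFactors = FALSE)
    }
  }
  list(selection_report = do.call(rbind, rows),
       stable_densities = if (length(stab)) do.call(rbind, stab) else
         data.frame(area_id = character(), density = numeric(),
                    se = numeric(), n_sims = integer()))
}
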