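#' Predict stable sizes for protected areas under a PIKE scenario
#'
#' Response-scale predictions from the selected benchmark GAM for every
#' protected area, under current PIKE or with PIKE overridden (0 for the
#' ecological-benchmark scenario). An area is flagged as extrapolating when
#' any covariate falls outside the training range.
#'
#' @param fit a [fit_benchmark_gam()] object.
#' @param areas data frame with `area_id, area_km2, evi, prop_12_water` and
#'   `pike` (unless overridden).
#' @param pike_override optional constant replacing every area's PIKE
#'   (0 gives the ecological benchmark).
#' @param scenario label stored in the output (default `"current_pike"`, or
#'   `"zero_pike"` when `pike_override = 0`).
#' @return data frame `area_id, scenario, pike_used, predicted_size,
#'   predicted_density, extrapolation`.
#' @export
predict_scenario <- function(fit, areas, pike_override = NULL,
                             scenario = NULL) {
  stopifnot(inherits(fit, "benchmark_gam"))
  need <- c("area_id", "area_km2", "evi", "prop_12_water")
  miss <- setdiff(need, names(areas))
  if (length(miss)) stop("areas is missing column(s): ",
                         paste(miss, collapse = ", "))
  nd <- areas
  nd$log_area <- log(nd$area_km2)
  if (!is.null(pike_override)) {
    nd$pike <- pike_override
  } else if (!"pike" %in% names(nd)) {
    bad <- areas$area_id[1]
    stop("no PIKE value for area ", bad, " (and no override)")
  }
  if (anyNA(nd$pike)) stop("missing PIKE for area(s): ",
                           paste(nd$area_id[is.na(nd$pike)], collapse = ", "))
  if (is.null(scenario))
    scenario <- if (!is.null(pike_override) && all(pike_override == 0))
      "zero_pike" else "current_pike"
  vars <- setdiff(names(fit$covariate_ranges), "log_area")
  extra <- rep(FALSE, nrow(nd))
  for (v in vars) {
    r <- fit$covariate_ranges[[v]]
    extra <- extra | nd[[v]] < r[1] | nd[[v]] > r[2]
  }
  size <- as.numeric(predict(fit, nd, type = "response"))
  data.frame(area_id = nd$area_id, scenario = scenario, pike_used = nd$pike,
             predicted_size = size, predicted_density = size / nd$area_km2,
             extrapolation = extra, stringsAsFactors = FALSE)
}

#' Deficits of recent estimates against ecological benchmarks
#'
#' Per area: `deficit = recent - benchmark` (negative values are missing
#' elephants) and `pct_of_benchmark = 100 * recent / benchmark`. Totals
#' obey the accounting identity `sum(recent) = sum(benchmark) +
#' sum(deficit)`; `net_deficit` is reported as the positive total shortfall
#' `sum(benchmark) - sum(recent)`.
#'
#' @param benchmarks data frame `area_id, predicted_size` (the zero-PIKE
#'   scenario predictions).
#' @param recent data frame `area_id, recent_estimate`.
#' @return list with `records` (per-area data frame) and `totals` (list
#'   `sum_recent, sum_benchmark, net_deficit, n_deficit, n_surplus`).
#' @export
compute_deficits <- function(benchmarks, recent) {
  m <- match(benchmarks$area_id, recent$area_id)
  if (anyNA(m)) stop("unmatched area_id(s): ",
                     paste(benchmarks$area_id[is.na(m)], collapse = ", "))
  b <- benchmarks$predicted_size
  r <- recent$recent_estimate[m]
  if (any(b <= 0)) stop("benchmarks must be > 0")
  rec <- data.frame(area_id = benchmarks$area_id, recent_estimate = r,
                    benchmark_size = b, deficit = r - b,
                    pct_of_benchmark = 100 * r / b, stringsAsFactors = FALSE)
  list(records = rec,
       totals = list(sum_recent = sum(r), sum_benchmark = sum(b),
                     net_deficit = sum(b) - sum(r),
                     n_deficit = sum(r < b), n_surplus = sum(r >= b)))
}

#' Headline summary statistics
#'
#' The report-level numbers of the analysis: the median recent density as a
#' percentage of benchmark, counts of areas at <= 5%, <= 10% and >= 75% of
#' benchmark, the cumulative percentage (100 x total recent / total
#' benchmark), the Spearman correlation between recent estimates and
#' current-PIKE predictions, the OLS regression of recent density on
#' benchmark density, and the concentration of the total deficit in the
#' `top_k` highest-deficit areas.
#'
#' @param deficits output of [compute_deficits()].
#' @param predictions_current current-PIKE [predict_scenario()] output.
#' @param areas data frame `area_id, area_km2` (for the density
#'   regression).
#' @param top_k how many highest-deficit areas to aggregate (default 10).
#' @return named list of summary statistics.
#' @export
summarize_headlines <- function(deficits, predictions_current, areas,
                                top_k = 10) {
  rec <- deficits$records
  tot <- deficits$totals
  m <- match(rec$area_id, predictions_current$area_id)
  pred_cur <- predictions_current$predicted_size[m]
  a <- areas$area_km2[match(rec$area_id, areas$area_id)]
  dens_recent <- rec$recent_estimate / a
  dens_bench <- rec$benchmark_size / a
  # a benchmark surface with no covariate effect is constant in density,
  # which makes the regression singular; report NAs in that case
  if (var(dens_bench) > 0) {
    ols <- lm(dens_recent ~ dens_bench)
    sm <- suppressWarnings(summary(ols))
    ols_cf <- coef(ols)
    fs <- sm$fstatistic %||% c(NA_real_, NA_real_, NA_real_)
    ols_stats <- list(slope = unname(ols_cf[2]), intercept = unname(ols_cf[1]),
                      r2 = sm$r.squared, f = unname(fs[1]),
                      p = if (is.na(fs[1])) NA_real_ else
                        unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
  } else {
    ols_stats <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                      f = NA_real_, p = NA_real_)
  }
  shortfall <- pmax(-rec$deficit, 0)  # positive missing elephants
  ord <- order(shortfall, decreasing = TRUE)
  topk_sum <- sum(shortfall[ord[seq_len(min(top_k, length(ord)))]])
  sp <- suppressWarnings(
    cor.test(rec$recent_estimate, pred_cur, method = "spearman",
             exact = FALSE))
  list(
    n_areas = nrow(rec),
    median_pct_of_benchmark = median(rec$pct_of_benchmark),
    min_pct_of_benchmark = min(rec$pct_of_benchmark),
    n_le_5_pct = sum(rec$pct_of_benchmark <= 5),
    n_le_10_pct = sum(rec$pct_of_benchmark <= 10),
    n_ge_75_pct = sum(rec$pct_of_benchmark >= 75),
    cumulative_pct = 100 * tot$sum_recent / tot$sum_benchmark,
    sum_recent = tot$sum_recent,
    sum_benchmark = tot$sum_benchmark,
    net_deficit = tot$net_deficit,
    n_deficit = tot$n_deficit,
    n_surplus = tot$n_surplus,
    spearman_recent_vs_current = unname(sp$estimate),
    spearman_p = sp$p.value,
    ols_slope = ols_stats$slope,
    ols_intercept = ols_stats$intercept,
    ols_r2 = ols_stats$r2,
    ols_f = ols_stats$f,
    ols_p = ols_stats$p,
    top_k = top_k,
    top_k_deficit = topk_sum,
    rest_deficit = sum(shortfall) - topk_sum)
}
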