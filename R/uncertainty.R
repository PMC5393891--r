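#' Simulate training datasets for outer Monte Carlo draws
#'
#' Each outer draw pairs (a) stable densities drawn from a normal
#' distribution truncated at zero given each estimate and its SE with
#' (b) modeled PIKE values drawn on the linear-predictor scale,
#' `plogis(rnorm(eta, eta_se))`; empirical PIKE values are held fixed.
#'
#' @param stable data frame `area_id, density, se`.
#' @param pike data frame `area_id, pike, eta, eta_se, source`
#'   (`source == "modeled"` rows are redrawn). May be `NULL` when every
#'   PIKE is empirical.
#' @param n_outer number of outer draws.
#' @param seed integer seed.
#' @return list of `n_outer` elements, each a list with `density` and
#'   `pike` named vectors.
#' @export
simulate_training_datasets <- function(stable, pike = NULL, n_outer = 1000,
                                       seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_outer), function(i) {
    d <- rnorm_trunc0(nrow(stable), stable$density, stable$se)
    names(d) <- stable$area_id
    p <- NULL
    if (!is.null(pike)) {
      p <- pike$pike
      mod <- pike$source == "modeled"
      if (any(mod))
        p[mod] <- plogis(rnorm(sum(mod), pike$eta[mod], pike$eta_se[mod]))
      names(p) <- pike$area_id
    }
    list(density = d, pike = p)
  })
}

#' Nested Monte Carlo propagation of pipeline uncertainty
#'
#' Propagates three uncertainty sources into every prediction, deficit and
#' total: stable-density SEs and modeled-PIKE SEs enter through `n_outer`
#' re-drawn training datasets, each of which the GAM is refitted to
#' (dispersion re-estimated by a one-step profile update from the point
#' fit); GAM coefficient uncertainty enters through `n_inner` draws per
#' refit from the multivariate-normal posterior of the penalized
#' coefficients. Predictions for each draw are made for every area under
#' the current-PIKE and zero-PIKE scenarios, and aggregates (totals, net
#' deficit) are recomputed per draw, never from per-area summaries.
#'
#' @param fit the point [fit_benchmark_gam()] fit; its training table must
#'   carry `stable_density` and `stable_density_se` columns (plus
#'   `pike_eta`, `pike_eta_se`, `pike_source` if any training PIKE is
#'   modeled).
#' @param areas data frame `area_id, area_km2, evi, prop_12_water, pike`
#'   plus (optionally) `pike_eta, pike_eta_se, pike_source` and
#'   `recent_estimate`.
#' @param n_outer,n_inner Monte Carlo sizes (`n_outer * n_inner` draws per
#'   target; the full-scale analysis uses 1000 x 1000, testing 100 x 100).
#' @param seed integer seed.
#' @param coef_uncertainty draw coefficients from the posterior
#'   (default `TRUE`); `FALSE` uses the refit's point coefficients, so that
#'   with all SEs equal to zero the propagation collapses exactly to the
#'   deterministic pipeline.
#' @param max_fail_prop abort if more than this proportion of outer refits
#'   fail (default 0.1).
#' @return object of class `mc_propagation`: list with `draws` (matrices
#'   `current`, `zero`, each `n_draws x n_areas`), `deficits` (same shape;
#'   `recent - zero`, negative values are missing elephants), `totals`
#'   (per-draw data frame `total_current`, `total_zero` and `net_deficit`,
#'   the positive shortfall `total_zero - sum(recent)`), `area_ids`,
#'   `recent`, `n_outer`, `n_inner`, `n_failed`.
#' @export
propagate_uncertainty <- function(fit, areas, n_outer = 100, n_inner = 100,
                                  seed = 1L, coef_uncertainty = TRUE,
                                  max_fail_prop = 0.1) {
  stopifnot(inherits(fit, "benchmark_gam"))
  tr <- fit$training
  if (!all(c("stable_density", "stable_density_se") %in% names(tr)))
    stop("fit$training must carry stable_density and stable_density_se")
  n_area <- nrow(areas)
  has_recent <- "recent_estimate" %in% names(areas)
  recent <- if (has_recent) areas$recent_estimate else rep(NA_real_, n_area)
  tr_mod <- if ("pike_source" %in% names(tr)) tr$pike_source == "modeled"
            else rep(FALSE, nrow(tr))
  ar_mod <- if ("pike_source" %in% names(areas)) areas$pike_source == "modeled"
            else rep(FALSE, n_area)
  nd_cur <- areas
  nd_cur$log_area <- log(nd_cur$area_km2)
  nd_zero <- nd_cur
  nd_zero$pike <- 0
  n_total <- n_outer * n_inner
  draws_cur <- matrix(NA_real_, n_total, n_area)
  draws_zero <- matrix(NA_real_, n_total, n_area)
  set.seed(seed)
  n_failed <- 0L
  filled <- 0L
  log_area <- nd_cur$log_area
  for (i in seq_len(n_outer)) {
    tr_i <- tr
    tr_i$stable_density <- rnorm_trunc0(nrow(tr), tr$stable_density,
                                        tr$stable_density_se)
    tr_i$stable_size <- tr_i$stable_density * exp(tr$log_area)
    if (any(tr_mod))
      tr_i$pike[tr_mod] <- plogis(rnorm(sum(tr_mod), tr$pike_eta[tr_mod],
                                        tr$pike_eta_se[tr_mod]))
    refit <- tryCatch(
      fit_benchmark_gam(tr_i, fit$formula_id, k = fit$k, theta = fit$theta,
                        theta_update = TRUE),
      error = function(e) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    g <- refit$gam
    if (coef_uncertainty) {
      # posterior draws with dispersion uncertainty: the coefficient
      # covariance conditions on the moment-estimated dispersion, so scale
      # each draw by an inverse-chi-square factor on the residual df
      # (the unknown-scale normal posterior), as in Gaussian simulation
      dfres <- max(refit$n - refit$edf, 2)
      z <- mgcv::rmvn(n_inner, numeric(length(coef(g))), g$Vp)
      if (n_inner == 1) z <- matrix(z, nrow = 1)
      scl <- sqrt(dfres / stats::rchisq(n_inner, dfres))
      betas <- sweep(z, 1, scl, `*`)
      betas <- sweep(betas, 2, coef(g), `+`)
    } else {
      betas <- matrix(coef(g), n_inner, length(coef(g)), byrow = TRUE)
    }
    nd_cur_i <- nd_cur
    if (any(ar_mod))
      nd_cur_i$pike[ar_mod] <- plogis(rnorm(sum(ar_mod), areas$pike_eta[ar_mod],
                                            areas$pike_eta_se[ar_mod]))
    Xc <- predict(g, newdata = nd_cur_i, type = "lpmatrix")
    Xz <- predict(g, newdata = nd_zero, type = "lpmatrix")
    rows <- filled + seq_len(n_inner)
    draws_cur[rows, ] <- t(exp(Xc %*% t(betas) + log_area))
    draws_zero[rows, ] <- t(exp(Xz %*% t(betas) + log_area))
    filled <- filled + n_inner
  }
  if (n_failed > max_fail_prop * n_outer)
    stop(n_failed, " of ", n_outer, " outer refits failed")
  draws_cur <- draws_cur[seq_len(filled), , drop = FALSE]
  draws_zero <- draws_zero[seq_len(filled), , drop = FALSE]
  deficits <- if (has_recent)
    sweep(-draws_zero, 2, recent, `+`) else NULL
  totals <- data.frame(total_current = rowSums(draws_cur),
                       total_zero = rowSums(draws_zero))
  if (has_recent) totals$net_deficit <- totals$total_zero - sum(recent)
  structure(list(draws = list(current = draws_cur, zero = draws_zero),
                 deficits = deficits, totals = totals,
                 area_ids = areas$area_id, recent = recent,
                 n_outer = n_outer, n_inner = n_inner, n_failed = n_failed),
            class = "mc_propagation")
}

#' Summarise Monte Carlo draws
#'
#' Empirical median, SD, and asymmetric 95% prediction interval (2.5th and
#' 97.5th percentiles, linear-interpolation quantiles) of a draw vector.
#'
#' @param draws numeric vector (>= 100 draws) or matrix (columns are
#'   targets).
#' @param target_id id label(s) for the output rows.
#' @param min_draws minimum number of draws required.
#' @return data frame `target_id, median, se, lo_2_5, hi_97_5, n_draws`.
#' @export
summarize_mc <- function(draws, target_id = NULL, min_draws = 100) {
  if (is.matrix(draws)) {
    ids <- target_id %||% colnames(draws) %||% seq_len(ncol(draws))
    out <- do.call(rbind, lapply(seq_len(ncol(draws)), function(j)
      summarize_mc(draws[, j], ids[j], min_draws)))
    return(out)
  }
  draws <- draws[is.finite(draws)]
  if (length(draws) < min_draws)
    stop("need at least ", min_draws, " draws")
  q <- quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  data.frame(target_id = as.character(target_id %||% "target"),
             median = q[2], se = sd(draws), lo_2_5 = q[1], hi_97_5 = q[3],
             n_draws = length(draws), stringsAsFactors = FALSE)
}

#' Full Monte Carlo summary table for a propagation
#'
#' One row per area x scenario, per-area deficit rows, and the aggregate
#' totals (collective current-PIKE size, collective benchmark, net
#' deficit), each summarised as in [summarize_mc()].
#'
#' @param prop an [propagate_uncertainty()] object.
#' @param min_draws passed to [summarize_mc()].
#' @return data frame in [summarize_mc()] format.
#' @export
summarize_propagation <- function(prop, min_draws = 100) {
  stopifnot(inherits(prop, "mc_propagation"))
  blocks <- list(
    summarize_mc(prop$draws$current,
                 paste0(prop$area_ids, ":current_pike"), min_draws),
    summarize_mc(prop$draws$zero,
                 paste0(prop$area_ids, ":zero_pike"), min_draws))
  if (!is.null(prop$deficits))
    blocks <- c(blocks, list(
      summarize_mc(prop$deficits, paste0(prop$area_ids, ":deficit"),
                   min_draws)))
  blocks <- c(blocks, list(
    summarize_mc(prop$totals$total_current, "total:current_pike", min_draws),
    summarize_mc(prop$totals$total_zero, "total:zero_pike", min_draws)))
  if (!is.null(prop$totals$net_deficit))
    blocks <- c(blocks, list(
      summarize_mc(prop$totals$net_deficit, "total:net_deficit", min_draws)))
  do.call(rbind, blocks)
}
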