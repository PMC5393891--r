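GAM_FORMULAS <- c("null", "evi_water", "evi_water_pike")

gam_formula <- function(formula_id, k = 3) {
  rhs <- switch(formula_id,
    null = "1",
    evi_water = sprintf("s(evi, k = %d) + s(prop_12_water, k = %d)", k, k),
    evi_water_pike = sprintf(
      "s(evi, k = %d) + s(prop_12_water, k = %d) + s(pike, k = %d)", k, k, k),
    stop("unknown formula_id: ", formula_id))
  as.formula(paste("stable_size_int ~", rhs, "+ offset(log_area)"))
}

# NB dispersion theta from Pearson residuals with a df correction: choose
# theta so that X^2 / (n - edf) = 1. Direct ML given fitted means ignores
# the effective degrees of freedom the penalized fit consumes and
# overstates theta badly at small n.
theta_pearson <- function(y, mu, edf, interval = c(0.02, 1e6)) {
  dfres <- max(length(y) - edf, 1)
  # f increases in theta (less assumed overdispersion -> bigger X^2)
  f <- function(th) sum((y - mu)^2 / (mu + mu^2 / th)) / dfres - 1
  if (f(interval[1]) > 0) return(interval[1])
  if (f(interval[2]) < 0) return(interval[2])
  stats::uniroot(f, interval, tol = 1e-4)$root
}

fit_gam_at_theta <- function(training, formula_id, theta, k) {
  mgcv::gam(gam_formula(formula_id, k), data = training,
            family = mgcv::negbin(theta), method = "GCV.Cp")
}

#' Fit a negative-binomial benchmark GAM
#'
#' Fits stable population size to smooth functions of EVI, water
#' availability and PIKE with `log(area)` as an offset, so the model is
#' effectively one of density. Each smooth is a thin-plate regression
#' spline with basis dimension at most 3 to keep the response shapes
#' simple; smoothing parameters are chosen by the prediction-error
#' (GCV/UBRE) criterion. The negative-binomial dispersion theta
#' (variance = mu + mu^2/theta) is estimated outside the smoothing loop by
#' iterating refits with a Pearson moment condition, `X^2 / (n - edf) = 1`,
#' which corrects for the effective degrees of freedom the fit consumes;
#' when a starting `theta` is supplied only a one-step update is done
#' (refitting once if theta moves by more than 50%), which is how Monte
#' Carlo refits re-estimate dispersion cheaply.
#' Stable sizes are rounded to the nearest integer before fitting
#' (negative-binomial support).
#'
#' @param training data frame with `stable_size` (> 0), `evi`,
#'   `prop_12_water`, `pike` (for the full model) and `log_area`.
#' @param formula_id one of `"null"`, `"evi_water"`, `"evi_water_pike"`.
#' @param k basis dimension per smooth (default 3).
#' @param theta optional fixed/starting dispersion.
#' @param theta_update with `theta` supplied, do the one-step profile
#'   update (default `TRUE`); `FALSE` holds theta fixed.
#' @return object of class `benchmark_gam`: list with `gam` (the mgcv fit),
#'   `formula_id`, `k`, `theta`, `edf` (total effective df), `k_eff`
#'   (`edf` + 1 for theta), `loglik`, `aicc`, `metrics` (`r2, r2_adj, cor,
#'   dev_expl`), `training`, `covariate_ranges`.
#' @export
fit_benchmark_gam <- function(training, formula_id = "evi_water_pike",
                              k = 3, theta = NULL, theta_update = TRUE) {
  formula_id <- match.arg(formula_id, GAM_FORMULAS)
  if (nrow(training) < 6) stop("need at least 6 training rows")
  if (any(training$stable_size <= 0)) stop("stable sizes must be > 0")
  tr <- training
  tr$stable_size_int <- pmax(round(tr$stable_size), 1)
  vars <- switch(formula_id, null = character(),
                 evi_water = c("evi", "prop_12_water"),
                 evi_water_pike = c("evi", "prop_12_water", "pike"))
  if (any(!is.finite(as.matrix(tr[, c(vars, "log_area")]))))
    stop("non-finite covariates")
  y <- tr$stable_size_int
  if (is.null(theta)) {
    # outer estimation: iterate fit <-> Pearson-df update to convergence
    theta <- 1
    fit <- fit_gam_at_theta(tr, formula_id, theta, k)
    for (it in 1:8) {
      th2 <- theta_pearson(y, fitted(fit), sum(fit$edf))
      if (abs(log(th2 / theta)) < 0.01) { theta <- th2; break }
      theta <- th2
      fit <- fit_gam_at_theta(tr, formula_id, theta, k)
    }
    fit <- fit_gam_at_theta(tr, formula_id, theta, k)
  } else {
    fit <- fit_gam_at_theta(tr, formula_id, theta, k)
    if (theta_update) {
      th2 <- theta_pearson(y, fitted(fit), sum(fit$edf))
      if (abs(log(th2 / theta)) > log(1.5)) {
        theta <- th2
        fit <- fit_gam_at_theta(tr, formula_id, theta, k)
        theta <- theta_pearson(y, fitted(fit), sum(fit$edf))
      } else theta <- th2
    }
  }
  if (!fit$converged) stop("GAM did not converge for ", formula_id)
  mu <- fitted(fit)
  n <- nrow(tr)
  edf <- sum(fit$edf)
  k_eff <- edf + 1  # + dispersion
  ll <- sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  aicc_val <- if (n - k_eff - 1 > 0)
    -2 * ll + 2 * k_eff + 2 * k_eff * (k_eff + 1) / (n - k_eff - 1) else NA_real_
  r2 <- 1 - sum((y - mu)^2) / sum((y - mean(y))^2)
  metrics <- list(
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - k_eff - 1),
    cor = if (sd(mu) > 0 && sd(y) > 0) cor(y, mu) else NA_real_,
    dev_expl = summary(fit)$dev.expl)
  rng <- lapply(tr[, c(vars, "log_area"), drop = FALSE], range)
  structure(list(gam = fit, formula_id = formula_id, k = k, theta = theta,
                 edf = edf, k_eff = k_eff, loglik = ll, aicc = aicc_val,
                 metrics = metrics, training = tr, covariate_ranges = rng,
                 n = n),
            class = "benchmark_gam")
}

#' @export
print.benchmark_gam <- function(x, ...) {
  cat("Negative-binomial benchmark GAM (", x$formula_id, ")\n", sep = "")
  cat("  n =", x$n, " edf =", signif(x$edf, 4),
      " theta =", signif(x$theta, 4), "\n")
  cat("  AICc =", signif(x$aicc, 6),
      " deviance explained =", signif(100 * x$metrics$dev_expl, 3), "%\n")
  invisible(x)
}

#' Predict from a benchmark GAM
#'
#' Response-scale predictions include the log-area offset, so predicted
#' stable size is exactly proportional to area at fixed covariates.
#'
#' @param object a [fit_benchmark_gam()] fit.
#' @param newdata data frame with the model covariates and `log_area`.
#' @param type `"response"` (stable size), `"link"`, or `"lpmatrix"` (the
#'   linear-predictor design matrix, excluding the offset).
#' @param ... unused.
#' @export
predict.benchmark_gam <- function(object, newdata, type = "response", ...) {
  predict(object$gam, newdata = newdata, type = type)
}

#' Willmott's index of agreement
#'
#' `D = 1 - sum((P - O)^2) / sum((|P - Obar| + |O - Obar|)^2)`, in `[0, 1]`
#' with 1 meaning perfect prediction.
#'
#' @param obs,pred observed and predicted values.
#' @return scalar index.
#' @export
willmott_d <- function(obs, pred) {
  ob <- mean(obs)
  denom <- sum((abs(pred - ob) + abs(obs - ob))^2)
  if (denom == 0) return(NA_real_)
  1 - sum((pred - obs)^2) / denom
}

#' Mean bias error
#'
#' `MBE = mean(pred - obs)`; measures average skew of prediction errors.
#'
#' @inheritParams willmott_d
#' @export
mean_bias_error <- function(obs, pred) mean(pred - obs)

#' Leave-one-out cross-validation metrics for a benchmark GAM
#'
#' Refits the model excluding each training row in turn (theta held at the
#' full-fit estimate for stability on n-1 rows) and predicts the held-out
#' stable size on the response scale. Returns the cross-validation
#' correlation (cvCOR), Willmott's index of agreement (D) and the mean bias
#' error (MBE). Folds whose refit fails are dropped and counted.
#'
#' @inheritParams fit_benchmark_gam
#' @return list with `cvcor`, `willmott_d`, `mbe`, `pred`, `obs`,
#'   `n_failed`.
#' @export
loocv_metrics <- function(training, formula_id = "evi_water_pike", k = 3,
                          theta = NULL) {
  if (nrow(training) < 3) stop("need at least 3 rows for LOOCV")
  full <- fit_benchmark_gam(training, formula_id, k = k, theta = theta)
  n <- nrow(training)
  pred <- obs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      fit_benchmark_gam(training[-i, , drop = FALSE], formula_id, k = k,
                        theta = full$theta, theta_update = FALSE),
      error = function(e) NULL)
    if (is.null(fit_i)) next
    pred[i] <- as.numeric(predict(fit_i, training[i, , drop = FALSE],
                                  type = "response"))
    obs[i] <- full$training$stable_size_int[i]
  }
  ok <- !is.na(pred)
  list(cvcor = cor(obs[ok], pred[ok]),
       willmott_d = willmott_d(obs[ok], pred[ok]),
       mbe = mean_bias_error(obs[ok], pred[ok]),
       pred = pred, obs = obs, n_failed = sum(!ok))
}

#' Fit and compare the candidate benchmark GAMs
#'
#' Fits the three candidates (null, EVI + water, EVI + water + PIKE),
#' tabulates AICc, delta-AICc, AICc weights, in-sample fit metrics and
#' LOOCV metrics, and selects the lowest-AICc model. A candidate that fails
#' to fit is marked inadmissible and selection proceeds over the rest.
#'
#' @inheritParams fit_benchmark_gam
#' @param formulas candidate formula ids.
#' @return object of class `gam_selection`: list with `table`, `fits`
#'   (named list of `benchmark_gam`s), `best_formula_id`.
#' @export
select_benchmark_gam <- function(training, formulas = GAM_FORMULAS, k = 3) {
  fits <- setNames(vector("list", length(formulas)), formulas)
  rows <- list()
  for (f in formulas) {
    fit <- tryCatch(fit_benchmark_gam(training, f, k = k),
                    error = function(e) NULL)
    fits[[f]] <- fit
    cv <- if (!is.null(fit))
      tryCatch(loocv_metrics(training, f, k = k, theta = fit$theta),
               error = function(e) list(cvcor = NA, willmott_d = NA, mbe = NA))
      else list(cvcor = NA, willmott_d = NA, mbe = NA)
    rows[[f]] <- data.frame(
      formula_id = f,
      admissible = !is.null(fit),
      aicc = if (!is.null(fit)) fit$aicc else NA_real_,
      edf = if (!is.null(fit)) fit$edf else NA_real_,
      theta = if (!is.null(fit)) fit$theta else NA_real_,
      r2 = if (!is.null(fit)) fit$metrics$r2 else NA_real_,
      r2_adj = if (!is.null(fit)) fit$metrics$r2_adj else NA_real_,
      cor = if (!is.null(fit)) fit$metrics$cor else NA_real_,
      dev_expl = if (!is.null(fit)) fit$metrics$dev_expl else NA_real_,
      cvcor = cv$cvcor, willmott_d = cv$willmott_d, mbe = cv$mbe,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$admissible)) stop("no candidate GAM could be fitted")
  amin <- min(tab$aicc[tab$admissible], na.rm = TRUE)
  tab$delta_aicc <- tab$aicc - amin
  w <- exp(-0.5 * tab$delta_aicc); w[!tab$admissible | is.na(w)] <- 0
  tab$weight <- w / sum(w)
  best <- tab$formula_id[tab$admissible][which.min(tab$aicc[tab$admissible])]
  structure(list(table = tab, fits = fits, best_formula_id = best),
            class = "gam_selection")
}

#' @export
print.gam_selection <- function(x, ...) {
  cat("Benchmark GAM selection (best:", x$best_formula_id, ")\n")
  print(x$table[, c("formula_id", "aicc", "delta_aicc", "weight", "r2_adj",
                    "dev_expl", "cvcor", "willmott_d", "mbe")],
        row.names = FALSE)
  invisible(x)
}

#' Leverage and influence diagnostics
#'
#' Hat values (leverage) straight from the penalized fit, and Cook's
#' distances from the GLM-style approximation
#' `D_i = r_p,i^2 h_i / (phi * p * (1 - h_i)^2)` with Pearson residuals,
#' `p` the total effective degrees of freedom and `phi` the Pearson
#' dispersion estimate. Flags follow the usual rules of thumb: leverage
#' above 3x the mean hat value, influence above Cook's distance 1.
#'
#' @param fit a [fit_benchmark_gam()] object.
#' @return data frame `area_id, hat, cook, high_leverage, influential`.
#' @export
gam_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "benchmark_gam"))
  g <- fit$gam
  h <- g$hat
  rp <- residuals(g, type = "pearson")
  p <- fit$edf
  phi <- sum(rp^2) / (fit$n - p)
  cook <- rp^2 * h / (phi * p * (1 - h)^2)
  data.frame(
    area_id = fit$training$area_id %||% seq_len(fit$n),
    hat = h, cook = cook,
    high_leverage = h > 3 * mean(h),
    influential = cook > 1,
    stringsAsFactors = FALSE)
}

#' Refit without one training row and compare predictions
#'
#' Drops the given row, refits, and correlates the two models' predicted
#' stable sizes over the training rows whose covariates stay inside the
#' reduced model's covariate ranges. Used to assess the impact of
#' influential points.
#'
#' @inheritParams fit_benchmark_gam
#' @param drop_row row index (or `area_id`) to exclude.
#' @return list with `fit_full`, `fit_reduced`, `within_range` (logical per
#'   remaining row), `correlation` of the two prediction vectors.
#' @export
sensitivity_refit <- function(training, drop_row,
                              formula_id = "evi_water_pike", k = 3) {
  if (is.character(drop_row))
    drop_row <- match(drop_row, training$area_id)
  if (is.na(drop_row) || drop_row < 1 || drop_row > nrow(training))
    stop("drop_row not found")
  fit_full <- fit_benchmark_gam(training, formula_id, k = k)
  reduced <- training[-drop_row, , drop = FALSE]
  fit_red <- fit_benchmark_gam(reduced, formula_id, k = k)
  vars <- setdiff(names(fit_red$covariate_ranges), "log_area")
  within <- rep(TRUE, nrow(reduced))
  for (v in vars) {
    r <- fit_red$covariate_ranges[[v]]
    within <- within & reduced[[v]] >= r[1] & reduced[[v]] <= r[2]
  }
  p_full <- as.numeric(predict(fit_full, reduced[within, , drop = FALSE]))
  p_red <- as.numeric(predict(fit_red, reduced[within, , drop = FALSE]))
  list(fit_full = fit_full, fit_reduced = fit_red, within_range = within,
       correlation = cor(p_full, p_red))
}
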