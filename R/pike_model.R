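#' Amalgamate carcass records per site
#'
#' Sums illegal and total carcass counts per site over the monitoring
#' window. Pooling years minimises the stochastic variability of the PIKE
#' ratio (illegal carcasses / total carcasses).
#'
#' @param records data frame `site_id, year, illegal_carcasses,
#'   total_carcasses`.
#' @param years years to include (default 2002-2014, the carcass-monitoring
#'   window).
#' @return data frame `site_id, illegal, total, n_years` (one row per site
#'   with any in-window record).
#' @export
amalgamate_carcasses <- function(records, years = 2002:2014) {
  stopifnot(all(c("site_id", "year", "illegal_carcasses",
                  "total_carcasses") %in% names(records)))
  if (any(records$illegal_carcasses > records$total_carcasses))
    stop("illegal carcasses exceed total carcasses in some record(s)")
  if (any(records$illegal_carcasses < 0 | records$total_carcasses < 0))
    stop("carcass counts must be >= 0")
  w <- records[records$year %in% years, , drop = FALSE]
  if (nrow(w) == 0)
    return(data.frame(site_id = character(), illegal = numeric(),
                      total = numeric(), n_years = integer()))
  agg <- aggregate(cbind(illegal = illegal_carcasses,
                         total = total_carcasses) ~ site_id, data = w, sum)
  ny <- aggregate(year ~ site_id, data = w, function(y) length(unique(y)))
  agg$n_years <- ny$year[match(agg$site_id, ny$site_id)]
  agg[order(agg$site_id), , drop = FALSE]
}

#' Drop sites with too few carcasses
#'
#' Sites whose amalgamated carcass total is below `min_total` give PIKE
#' ratios too noisy to use and are excluded.
#'
#' @param amalgamated output of [amalgamate_carcasses()].
#' @param min_total minimum amalgamated carcass count (default 20).
#' @return the retained rows; excluded site ids in attribute `"excluded"`.
#'   Warns when no site is retained.
#' @export
filter_low_carcass_sites <- function(amalgamated, min_total = 20) {
  keep <- amalgamated$total >= min_total
  out <- amalgamated[keep, , drop = FALSE]
  attr(out, "excluded") <- amalgamated$site_id[!keep]
  if (nrow(out) == 0) warning("no sites retained at min_total = ", min_total)
  out
}

# logit and its binomial SE with a Haldane 0.5 continuity correction so the
# boundary ratios 0 and 1 stay finite on the linear-predictor scale
logit_with_se <- function(illegal, total) {
  eta <- qlogis((illegal + 0.5) / (total + 1))
  se <- sqrt(1 / (illegal + 0.5) + 1 / (total - illegal + 0.5))
  list(eta = eta, se = se)
}

#' Empirical PIKE for monitored sites
#'
#' PIKE = illegal / total carcasses. The linear-predictor value and SE
#' (continuity-corrected logit) are carried along for optional uncertainty
#' propagation; by default downstream Monte Carlo holds empirical PIKE
#' fixed.
#'
#' @param illegal,total amalgamated carcass counts (vectors).
#' @param site_id optional site ids.
#' @return data frame `site_id, pike, eta, eta_se, source, carcasses_total`.
#' @export
empirical_pike <- function(illegal, total, site_id = NULL) {
  if (any(total <= 0)) stop("total carcasses must be > 0")
  if (any(illegal < 0 | illegal > total)) stop("need 0 <= illegal <= total")
  l <- logit_with_se(illegal, total)
  data.frame(site_id = site_id %||% seq_along(illegal),
             pike = illegal / total, eta = l$eta, eta_se = l$se,
             source = "empirical", carcasses_total = total,
             stringsAsFactors = FALSE)
}

#' Fit and average quasi-binomial PIKE models
#'
#' Fits one quasi-binomial GLM (logit link) per candidate predictor subset
#' to the amalgamated per-site carcass counts — the `cbind(illegal,
#' total - illegal)` response weights each site by its carcass total — and
#' averages the candidates by QAICc weight. Quasi-likelihood has no true
#' AIC, so candidates are compared by QAICc computed with the binomial
#' log-likelihood scaled by the global (largest) model's dispersion, with
#' one extra parameter counted for the dispersion. The averaged model uses
#' full-model averaging: a coefficient absent from a candidate contributes
#' zero.
#'
#' @param sites data frame with `illegal`, `total` and the covariate
#'   columns.
#' @param candidates list of character vectors of covariate names; the
#'   empty vector is the intercept-only model. Default: all subsets of
#'   `covariates`.
#' @param covariates covariate names used to build the default candidate
#'   set.
#' @return object of class `pike_glm`: list with `fits`, `table`
#'   (k, qaicc, delta, weight per candidate), `dispersion`,
#'   `averaged_coefficients`, `candidates`, `training`.
#' @export
fit_pike_glm <- function(sites, candidates = NULL, covariates = NULL) {
  stopifnot(all(c("illegal", "total") %in% names(sites)))
  if (is.null(candidates)) {
    if (is.null(covariates)) stop("supply candidates or covariates")
    candidates <- unlist(lapply(0:length(covariates), function(m)
      combn(covariates, m, simplify = FALSE)), recursive = FALSE)
  }
  labels <- vapply(candidates, function(v)
    if (length(v)) paste(v, collapse = "+") else "1", character(1))
  n <- nrow(sites)
  fits <- vector("list", length(candidates))
  ok <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    rhs <- if (length(candidates[[i]])) paste(candidates[[i]], collapse = " + ") else "1"
    f <- as.formula(paste("cbind(illegal, total - illegal) ~", rhs))
    fits[[i]] <- tryCatch(
      glm(f, family = quasibinomial(), data = sites),
      error = function(e) NULL, warning = function(w) NULL)
    ok[i] <- !is.null(fits[[i]]) && fits[[i]]$converged &&
      !any(is.na(coef(fits[[i]])))
  }
  if (!any(ok)) stop("no candidate PIKE model could be fitted")
  # dispersion from the most complex successfully fitted candidate
  glob <- which(ok)[which.max(vapply(which(ok), function(i)
    length(coef(fits[[i]])), numeric(1)))]
  pr <- residuals(fits[[glob]], type = "pearson")
  c_hat <- max(sum(pr^2) / fits[[glob]]$df.residual, 1)
  loglik <- function(fit) {
    p <- fitted(fit)
    sum(dbinom(sites$illegal, sites$total, p, log = TRUE))
  }
  k <- ifelse(ok, vapply(fits, function(f)
    if (is.null(f)) NA_real_ else length(coef(f)) + 1, numeric(1)), NA)
  qa <- rep(NA_real_, length(fits))
  for (i in which(ok)) {
    if (n - k[i] - 1 <= 0) { ok[i] <- FALSE; next }
    qa[i] <- -2 * loglik(fits[[i]]) / c_hat + 2 * k[i] +
      2 * k[i] * (k[i] + 1) / (n - k[i] - 1)
  }
  if (!any(ok))
    stop("no candidate PIKE model is admissible (need n > k + 1 sites)")
  delta <- qa - min(qa[ok])
  w <- exp(-0.5 * delta); w[!ok] <- 0; w <- w / sum(w)
  all_terms <- unique(unlist(lapply(fits[ok], function(f) names(coef(f)))))
  avg <- setNames(numeric(length(all_terms)), all_terms)
  for (i in which(ok)) {
    cf <- coef(fits[[i]])
    avg[names(cf)] <- avg[names(cf)] + w[i] * cf
  }
  structure(list(
    fits = fits,
    table = data.frame(candidate = labels, k = k, qaicc = qa,
                       delta_qaicc = qa - min(qa[ok]), weight = w,
                       admissible = ok, stringsAsFactors = FALSE),
    dispersion = c_hat, averaged_coefficients = avg,
    candidates = candidates, training = sites), class = "pike_glm")
}

#' @export
print.pike_glm <- function(x, ...) {
  cat("Averaged quasi-binomial PIKE model (dispersion =",
      signif(x$dispersion, 4), ")\n")
  print(x$table[, c("candidate", "k", "qaicc", "delta_qaicc", "weight")],
        row.names = FALSE)
  cat("Averaged coefficients:\n")
  print(signif(x$averaged_coefficients, 4))
  invisible(x)
}

#' Predict PIKE for unmonitored areas
#'
#' Model-averaged prediction on the linear-predictor (logit) scale:
#' `eta = sum(w_i eta_i)` with the unconditional (model-averaging) SE
#' `eta_se = sum(w_i sqrt(se_i^2 + (eta_i - eta)^2))`, then
#' `pike = plogis(eta)`, strictly inside (0, 1).
#'
#' @param model a [fit_pike_glm()] object.
#' @param newdata data frame with the covariate columns the candidates use.
#' @param site_id optional ids for the output.
#' @return data frame `site_id, pike, eta, eta_se, source, carcasses_total`.
#' @export
predict_pike <- function(model, newdata, site_id = NULL) {
  stopifnot(inherits(model, "pike_glm"))
  used <- unique(unlist(model$candidates))
  miss <- setdiff(used, names(newdata))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  ok <- model$table$admissible
  w <- model$table$weight[ok]
  preds <- lapply(model$fits[ok], function(f)
    predict(f, newdata = newdata, type = "link", se.fit = TRUE))
  eta_mat <- vapply(preds, `[[`, numeric(nrow(newdata)), "fit")
  se_mat <- vapply(preds, `[[`, numeric(nrow(newdata)), "se.fit")
  eta_mat <- matrix(eta_mat, nrow = nrow(newdata))
  se_mat <- matrix(se_mat, nrow = nrow(newdata))
  eta <- drop(eta_mat %*% w)
  eta_se <- drop(sqrt(se_mat^2 + (eta_mat - eta)^2) %*% w)
  data.frame(site_id = site_id %||% seq_len(nrow(newdata)),
             pike = plogis(eta), eta = eta, eta_se = eta_se,
             source = "modeled", carcasses_total = NA_integer_,
             stringsAsFactors = FALSE)
}
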