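make_fitted_world <- function(seed = 14, n = 18) {
  tr <- make_training(n = n, seed = seed)$training
  fit <- fit_benchmark_gam(tr)
  areas <- tr[, c("area_id", "area_km2", "evi", "prop_12_water", "pike")]
  areas$recent_estimate <- round(0.2 * tr$stable_size)
  list(fit = fit, areas = areas, tr = tr)
}

test_that("current-PIKE predictions reproduce the in-sample fit", {
  w <- make_fitted_world()
  pred <- predict_scenario(w$fit, w$areas)
  expect_equal(pred$predicted_size, unname(fitted(w$fit$gam)),
               tolerance = 1e-8)
  expect_equal(pred$scenario, rep("current_pike", nrow(w$areas)))
  # overriding with each area's own PIKE changes nothing
  pred2 <- predict_scenario(w$fit, w$areas, pike_override = w$areas$pike,
                            scenario = "current_pike")
  expect_equal(pred2$predicted_size, pred$predicted_size)
})

test_that("benchmarks ignore current PIKE entirely", {
  w <- make_fitted_world()
  b1 <- predict_scenario(w$fit, w$areas, pike_override = 0)
  areas2 <- w$areas
  areas2$pike <- rev(areas2$pike)
  b2 <- predict_scenario(w$fit, areas2, pike_override = 0)
  expect_equal(b1$predicted_size, b2$predicted_size)
  expect_equal(b1$scenario, rep("zero_pike", nrow(w$areas)))
  expect_equal(b1$predicted_density,
               b1$predicted_size / w$areas$area_km2)
})

test_that("missing covariates and PIKE are reported by area", {
  w <- make_fitted_world()
  areas <- w$areas
  areas$pike[3] <- NA
  expect_error(predict_scenario(w$fit, areas), areas$area_id[3])
  expect_error(predict_scenario(w$fit, areas[, -2]), "area_km2")
})

test_that("deficit accounting is exact", {
  bench <- data.frame(area_id = c("a", "b"), predicted_size = c(100, 200))
  rec <- data.frame(area_id = c("a", "b"), recent_estimate = c(100, 50))
  d <- compute_deficits(bench, rec)
  expect_equal(d$records$deficit, c(0, -150))
  expect_equal(d$records$pct_of_benchmark, c(100, 25))
  expect_equal(d$totals$net_deficit, 150)
  # accounting identity
  expect_equal(d$totals$sum_recent,
               d$totals$sum_benchmark + sum(d$records$deficit))
  expect_error(compute_deficits(bench,
                                data.frame(area_id = "a",
                                           recent_estimate = 1)), "unmatched")
})

test_that("identical recent and benchmark vectors give trivial headlines", {
  w <- make_fitted_world()
  bench <- predict_scenario(w$fit, w$areas, pike_override = 0)
  areas <- w$areas
  areas$recent_estimate <- bench$predicted_size
  d <- compute_deficits(bench, areas)
  h <- summarize_headlines(d, bench, areas)
  expect_equal(h$median_pct_of_benchmark, 100)
  expect_equal(h$spearman_recent_vs_current, 1)
  expect_equal(h$ols_slope, 1, tolerance = 1e-8)
  expect_equal(h$ols_intercept, 0, tolerance = 1e-8)
  expect_equal(h$n_deficit, 0)
})

test_that("headline counts and deficit concentration add up", {
  w <- make_fitted_world(seed = 15, n = 24)
  bench <- predict_scenario(w$fit, w$areas, pike_override = 0)
  d <- compute_deficits(bench, w$areas)
  h <- summarize_headlines(d, predict_scenario(w$fit, w$areas), w$areas,
                           top_k = 5)
  expect_equal(h$n_le_5_pct, sum(d$records$pct_of_benchmark <= 5))
  expect_equal(h$n_le_10_pct, sum(d$records$pct_of_benchmark <= 10))
  shortfall <- pmax(-d$records$deficit, 0)
  expect_equal(h$top_k_deficit + h$rest_deficit, sum(shortfall))
  expect_gte(h$top_k_deficit, h$rest_deficit / (h$n_areas - 5) * 5)
})

test_that("Spearman headline is invariant under monotone transforms", {
  w <- make_fitted_world(seed = 16)
  bench <- predict_scenario(w$fit, w$areas, pike_override = 0)
  cur <- predict_scenario(w$fit, w$areas)
  d <- compute_deficits(bench, w$areas)
  h1 <- summarize_headlines(d, cur, w$areas)
  cur2 <- cur
  cur2$predicted_size <- exp(cur2$predicted_size / max(cur2$predicted_size))
  h2 <- summarize_headlines(d, cur2, w$areas)
  expect_equal(h1$spearman_recent_vs_current, h2$spearman_recent_vs_current)
})
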