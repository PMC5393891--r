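test_that("candidate trajectories evaluate to their closed forms", {
  # frozen hand evaluation: K/(1 + ((K-N0)/N0) e^(-r t)) at K=2, N0=0.2,
  # r=0.5, t=4 -> 2 / (1 + 9 exp(-2))
  expect_equal(evaluate_growth_model("logistic",
                                     list(K = 2, N0 = 0.2, r = 0.5), 4),
               2 / (1 + 9 * exp(-2)), tolerance = 1e-12)
  expect_equal(evaluate_growth_model("logistic",
                                     list(K = 2, N0 = 0.2, r = 0.5), 1e6), 2)
  expect_equal(evaluate_growth_model("gompertz",
                                     list(K = 2, N0 = 2, r = 0.3), 0:5),
               rep(2, 6))
  expect_equal(evaluate_growth_model("linear", list(a = 1, b = 0.05), 10), 1.5)
  expect_error(evaluate_growth_model("exponential", list(N0 = -1, r = 0.1), 1),
               "N0")
  expect_error(evaluate_growth_model("logistic", list(K = 2, r = 0.1), 1),
               "missing parameter")
})

test_that("AICc matches the least-squares formula and its monotonicities", {
  # frozen: 10 log(0.1) + 4 + 12/7
  expect_equal(aicc(1, 10, 2), 10 * log(0.1) + 4 + 12 / 7)
  expect_lt(aicc(0.5, 10, 2), aicc(1, 10, 2))       # smaller rss wins
  expect_lt(aicc(1, 10, 2), aicc(1, 10, 3))         # fewer params win
  expect_identical(aicc(0, 10, 2), -Inf)            # exact fit convention
  expect_true(is.na(aicc(1, 4, 3)))                 # inadmissible
})

test_that("AICc deltas agree with a likelihood-based oracle on lm fits", {
  # independent route: gaussian AIC from stats::logLik plus the small-sample
  # correction differs from the least-squares form only by a constant in n,
  # so deltas between models on the same data must agree exactly
  set.seed(42)
  for (i in 1:5) {
    n <- sample(8:20, 1)
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    f1 <- lm(y ~ 1); f2 <- lm(y ~ x)
    ours <- aicc(sum(residuals(f1)^2), n, 2) - aicc(sum(residuals(f2)^2), n, 3)
    k1 <- 2; k2 <- 3
    orc <- (AIC(f1) + 2 * k1 * (k1 + 1) / (n - k1 - 1)) -
           (AIC(f2) + 2 * k2 * (k2 + 1) / (n - k2 - 1))
    expect_equal(ours, orc, tolerance = 1e-8)
  }
})

test_that("eligibility filtering applies all four criteria", {
  good <- make_series(rep(1.5, 6), area_km2 = 1000)
  short <- make_series(rep(1.5, 4), area_id = "short")
  lowrel <- make_series(rep(1.5, 6), reliability = "C", area_id = "lowrel")
  small <- make_series(rep(0.3, 6), area_km2 = 1000, area_id = "small")
  old <- make_series(rep(1.5, 6), years = 1975:1980, area_id = "old")
  counts <- rbind(good, short, lowrel, small, old)
  out <- filter_eligible_series(counts)
  expect_setequal(names(out$eligible), "X")
  expect_equal(out$summary$reason[out$summary$area_id == "short"],
               "too_few_counts")
  expect_equal(out$summary$reason[out$summary$area_id == "lowrel"],
               "too_few_counts")
  expect_equal(out$summary$reason[out$summary$area_id == "small"],
               "population_below_minimum")
})

test_that("least-squares fits recover noiseless generating parameters", {
  tr <- make_trajectory("null")
  s <- make_series(tr$density)
  f <- fit_growth_model(s, "null")
  expect_equal(unname(f$params["K"]), 1.5)
  expect_equal(f$rss, 0)
  tr <- make_trajectory("linear")
  f <- fit_growth_model(make_series(tr$density), "linear")
  expect_equal(unname(f$params), c(1, 0.05), tolerance = 1e-8)
  tr <- make_trajectory("exponential")
  f <- fit_growth_model(make_series(tr$density), "exponential")
  expect_equal(unname(f$params["r"]), 0.08, tolerance = 1e-6)
  tr <- make_trajectory("logistic")
  f <- fit_growth_model(make_series(tr$density), "logistic")
  expect_equal(unname(f$params["K"]), 2, tolerance = 1e-4)
})

test_that("exponential rate recovery is unbiased under survey noise", {
  set.seed(9)
  rs <- replicate(150, {
    tr <- make_trajectory("exponential", n = 10)
    f <- fit_growth_model(make_series(tr$density * rnorm_mean1(10, 0.1)),
                          "exponential")
    unname(f$params["r"])
  })
  expect_lt(abs(median(rs) - 0.08), 0.01)
})

test_that("model selection prefers the parsimonious exact fit", {
  s <- make_series(rep(1.5, 8))
  sel <- select_best_model(s)
  expect_equal(sel$best_model_id, "null")
  expect_equal(sel$table$delta_aicc[sel$table$model == "null"], 0)
})

test_that("AICc ordering is invariant to shifting the time origin", {
  set.seed(31)
  dens <- 1.2 + 0.03 * (0:7) + rnorm(8, 0, 0.05)
  s1 <- make_series(dens, years = 1990:1997)
  s2 <- make_series(dens, years = 2010:2017)
  t1 <- select_best_model(s1)$table
  t2 <- select_best_model(s2)$table
  sub <- c("null", "linear", "exponential")
  expect_equal(order(t1$aicc[t1$model %in% sub]),
               order(t2$aicc[t2$model %in% sub]))
})

test_that("linear-trend test behaves at both extremes and at null rate", {
  s <- make_series(rep(2, 6))
  lt <- test_linear_trend(s)
  expect_equal(lt$slope, 0)
  expect_equal(lt$p_value, 1)
  s2 <- make_series(seq(1, 2, length.out = 10) + rnorm(10, 0, 1e-4))
  expect_lt(test_linear_trend(s2)$p_value, 1e-6)
  # type-I error near the nominal 5% on null-generated series
  set.seed(13)
  rej <- mean(replicate(600, {
    s <- make_series(2 + rnorm(8, 0, 0.2))
    test_linear_trend(s)$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("robustness assessment is degenerate without count uncertainty", {
  s <- make_series(rep(1.5, 8), se_cv = 0)
  rob <- assess_robustness(s, n_sims = 50)
  expect_equal(rob$robustness, 1)
  expect_equal(rob$stable_density, 1.5)
  expect_equal(rob$stable_density_se, 0)
})

test_that("extracted stable density tracks an independent re-simulation", {
  # the SE reported from the 200-run MC should match the SD of null-model K
  # across an independent oracle stream of simulated series
  set.seed(77)
  K <- 1.8; cv <- 0.05; n <- 8
  est <- K * 1000 * rnorm_mean1(n, cv)
  s <- make_series(est / 1000, se_cv = 0)
  s$se <- cv * s$estimate
  rob <- assess_robustness(s, n_sims = 300, seed = 5)
  oracle_K <- replicate(3000, mean(pmax(rnorm(n, s$estimate, s$se), 0)) / 1000)
  expect_equal(rob$stable_density_se, sd(oracle_K), tolerance = 0.15)
  expect_equal(rob$stable_density, mean(oracle_K), tolerance = 0.02)
  # and the extraction lands near the series' least-squares mean density
  expect_equal(rob$stable_density, mean(s$estimate) / 1000, tolerance = 0.02)
})

test_that("stable densities flow only from null-selected series", {
  set.seed(55)
  areas <- data.frame(area_id = c("up", "flat"), area_km2 = c(1000, 1000))
  up <- make_series(0.5 * exp(0.1 * (0:7)), se_cv = 0.02, area_id = "up")
  flat <- make_series(1.5 * rnorm_mean1(8, 0.02), se_cv = 0.02,
                      area_id = "flat")
  out <- extract_stable_densities(list(up = up, flat = flat), areas,
                                  n_sims = 30, seed = 2)
  expect_equal(out$selection_report$best_model[
    out$selection_report$area_id == "up"], "exponential")
  expect_true("flat" %in% out$stable_densities$area_id)
  expect_false("up" %in% out$stable_densities$area_id)
})
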