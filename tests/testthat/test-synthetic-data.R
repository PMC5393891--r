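test_that("simulation spec validates its inputs", {
  expect_s3_class(simulation_spec(), "simulation_spec")
  expect_error(simulation_spec(evi_range = c(0.5, 0.2)), "evi_range")
  expect_error(simulation_spec(water_range = c(-0.1, 1)), "water_range")
  expect_error(simulation_spec(survey_cv = -1), "survey_cv")
  expect_error(simulation_spec(nb_dispersion = 0), "nb_dispersion")
})

test_that("protected-area generation respects ranges and seeds", {
  spec <- simulation_spec(seed = 11)
  pa <- generate_protected_areas(spec)
  expect_equal(nrow(pa), 73)
  expect_true(all(pa$area_km2 >= 1020 & pa$area_km2 <= 47666))
  expect_true(all(pa$evi >= 0.05 & pa$evi <= 0.404))
  expect_true(all(pa$prop_12_water >= 0 & pa$prop_12_water <= 1))
  expect_true(all(pa$true_pike >= 0 & pa$true_pike <= 1))
  expect_identical(pa, generate_protected_areas(spec))
  spec0 <- simulation_spec(n_areas = 0)
  expect_equal(nrow(generate_protected_areas(spec0)), 0)
})

test_that("time-series generator matches its generating trajectory", {
  area <- list(area_id = "A", area_km2 = 1000)
  # zero noise: constant null series at K * A
  ts0 <- generate_time_series(area, "null", list(K = 5), 6, survey_cv = 0,
                              seed = 1)
  expect_equal(ts0$estimate, rep(5000, 6))
  expect_equal(ts0$se, rep(0, 6))
  # logistic means follow the closed form
  params <- list(K = 2, N0 = 0.1, r = 0.4)
  years <- seq(1995, by = 2, length.out = 8)
  t <- years - years[1]
  truth <- evaluate_growth_model("logistic", params, t) * 1000
  reps <- vapply(1:400, function(i)
    generate_time_series(area, "logistic", params, 8, survey_cv = 0.1,
                         years = years, seed = i)$estimate,
    numeric(8))
  mc_se <- 0.1 * truth / sqrt(400)
  expect_true(all(abs(rowMeans(reps) - truth) < 4 * mc_se))
  expect_true(all(diff(rowMeans(reps)) > 0))  # monotone mean trajectory
  # empirical CV matches the generator parameter
  cvs <- apply(reps / truth, 1, sd)
  expect_true(all(abs(cvs - 0.1) < 0.02))
  expect_error(generate_time_series(area, "null", list(K = 1), 6, -0.1),
               "survey_cv")
  expect_error(generate_time_series(area, "null", list(K = 1), 1, 0.1),
               "n_counts")
})

test_that("stable-density training tables have the advertised structure", {
  spec <- simulation_spec(seed = 3)
  tr <- generate_stable_density_training(spec)
  expect_equal(nrow(tr$training), 18)
  expect_true(all(tr$training$stable_density_se > 0))
  expect_true(is.function(tr$surface))
  expect_equal(tr$training$stable_size / exp(tr$training$log_area),
               tr$training$stable_density)
  # flat surface: mean observed density converges to the constant
  flat <- simulation_spec(n_areas = 400, seed = 4,
                          true_surface = function(e, w, p) rep(2, length(e)),
                          nb_dispersion = 50)
  trf <- generate_stable_density_training(flat, n_train = 400)$training
  expect_lt(abs(mean(trf$stable_density) - 2), 0.1)
  expect_error(generate_stable_density_training(
    simulation_spec(true_surface = function(e, w, p) -1)), "negative")
})

test_that("NB scatter approaches Poisson as dispersion grows", {
  spec <- simulation_spec(n_areas = 3000, seed = 5,
                          area_range_km2 = c(5000, 5000),
                          true_surface = function(e, w, p) rep(0.4, length(e)),
                          nb_dispersion = 1e8)
  tr <- generate_stable_density_training(spec, n_train = 3000, se_cv = 0)
  size <- tr$training$stable_size
  # Poisson limit: variance/mean ratio near 1 (NB closed form: 1 + mu/theta)
  expect_lt(abs(var(size) / mean(size) - 1), 0.1)
})

test_that("carcass records are binomial around true PIKE", {
  z <- generate_carcass_records("s1", 0, totals = 10, seed = 1)
  expect_true(all(z$illegal_carcasses == 0))
  o <- generate_carcass_records("s1", 1, totals = 10, seed = 1)
  expect_equal(o$illegal_carcasses, o$total_carcasses)
  b <- generate_carcass_records("s1", 0.3, totals = 1000,
                                totals_exact = TRUE, seed = 2)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(b$illegal_carcasses, bounds[1])
  expect_lte(b$illegal_carcasses, bounds[2])
  expect_error(generate_carcass_records("s1", 1.2, 10), "true_pike")
})

test_that("study datasets mirror the study's structure deterministically", {
  spec <- simulation_spec(seed = 21)
  ds <- generate_study_dataset(spec)
  expect_equal(nrow(ds$areas), 73)
  el <- filter_eligible_series(ds$counts)
  expect_equal(length(el$eligible), 23)
  expect_equal(sum(!is.na(ds$areas$pike_empirical)) +
                 sum(is.na(ds$areas$pike_empirical)), 73)
  expect_equal(table(ds$truth$dynamics$true_model)[["null"]], 18)
  ds2 <- generate_study_dataset(spec)
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$areas, ds2$areas)
})
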