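# Builders shared across tests. Everything is generated in code; no fixture
# files.

# a count series data frame from a density trajectory
make_series <- function(density, area_km2 = 1000, years = NULL, se_cv = 0,
                        reliability = "A", area_id = "X") {
  n <- length(density)
  if (is.null(years)) years <- seq(1995, by = 2, length.out = n)
  est <- density * area_km2
  data.frame(area_id = area_id, year = years, estimate = est,
             se = se_cv * est, reliability = reliability,
             area_km2 = area_km2, stringsAsFactors = FALSE)
}

# noiseless density trajectory for a given generating model
make_trajectory <- function(model_id, n = 12, params = NULL) {
  t <- seq(0, by = 2, length.out = n)
  params <- params %||% switch(model_id,
    null = list(K = 1.5),
    linear = list(a = 1, b = 0.05),
    exponential = list(N0 = 0.5, r = 0.08),
    logistic = list(K = 2, N0 = 0.2, r = 0.5),
    gompertz = list(K = 2, N0 = 0.2, r = 0.4))
  list(t = t, density = evaluate_growth_model(model_id, params, t),
       params = params)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# multiplicative survey noise, mean 1, floored at 0
rnorm_mean1 <- function(n, cv) pmax(rnorm(n, 1, cv), 0)

# small GAM training table from a known log-linear surface; includes both
# ecological NB scatter and density measurement error
make_training <- function(n = 18, seed = 1, theta = 3.1, se_cv = 0.1,
                          surface = default_stable_surface) {
  spec <- simulation_spec(n_areas = n, nb_dispersion = theta, seed = seed,
                          true_surface = surface)
  generate_stable_density_training(spec, n_train = n, se_cv = se_cv)
}
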