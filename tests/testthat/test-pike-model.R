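test_that("carcass amalgamation sums within the window, in any order", {
  rec <- data.frame(site_id = c("a", "a", "a"), year = c(2004, 2010, 1999),
                    illegal_carcasses = c(10, 5, 99),
                    total_carcasses = c(20, 30, 100))
  out <- amalgamate_carcasses(rec)
  expect_equal(out$illegal, 15)   # 1999 record outside the window
  expect_equal(out$total, 50)
  out2 <- amalgamate_carcasses(rec[c(3, 2, 1), ])
  expect_equal(out, out2, ignore_attr = TRUE)
  rec$illegal_carcasses[1] <- 25
  expect_error(amalgamate_carcasses(rec), "exceed")
})

test_that("amalgamation matches the generator's bookkeeping", {
  carc <- generate_carcass_records(c("s1", "s2"), c(0.2, 0.6), totals = 8,
                                   seed = 4)
  out <- amalgamate_carcasses(carc)
  for (s in c("s1", "s2")) {
    sub <- carc[carc$site_id == s & carc$year %in% 2002:2014, ]
    expect_equal(out$illegal[out$site_id == s], sum(sub$illegal_carcasses))
    expect_equal(out$total[out$site_id == s], sum(sub$total_carcasses))
  }
})

test_that("low-carcass sites are excluded at the documented boundary", {
  am <- data.frame(site_id = c("lo", "hi"), illegal = c(5, 5),
                   total = c(19, 20), n_years = c(3, 3))
  out <- filter_low_carcass_sites(am)
  expect_equal(out$site_id, "hi")
  expect_equal(attr(out, "excluded"), "lo")
  expect_warning(filter_low_carcass_sites(am, min_total = 100), "no sites")
  # idempotent
  expect_equal(filter_low_carcass_sites(out)$site_id, out$site_id)
})

test_that("empirical PIKE is the carcass ratio", {
  e <- empirical_pike(c(0, 50, 12), c(50, 50, 48))
  expect_equal(e$pike, c(0, 1, 0.25))
  expect_equal(e$source, rep("empirical", 3))
  expect_true(all(is.finite(e$eta)) && all(e$eta_se > 0))
  expect_error(empirical_pike(0, 0), "total")
})

test_that("an intercept-only candidate recovers the pooled PIKE", {
  sites <- data.frame(illegal = c(10, 30, 5, 12, 8),
                      total = c(50, 100, 40, 60, 50),
                      evi = c(0.1, 0.3, 0.2, 0.15, 0.25))
  m <- fit_pike_glm(sites, candidates = list(character(0)))
  pooled <- sum(sites$illegal) / sum(sites$total)
  expect_equal(unname(m$averaged_coefficients["(Intercept)"]),
               qlogis(pooled), tolerance = 1e-8)
  p <- predict_pike(m, data.frame(evi = 0.2))
  expect_equal(p$pike, pooled, tolerance = 1e-8)
  expect_equal(p$source, "modeled")
})

test_that("identical candidates split the weight and leave averages alone", {
  set.seed(8)
  sites <- data.frame(evi = runif(20, 0.05, 0.4))
  sites$total <- 40
  sites$illegal <- rbinom(20, 40, plogis(1 - 4 * sites$evi))
  m <- fit_pike_glm(sites, candidates = list("evi", "evi"))
  expect_equal(m$table$weight, c(0.5, 0.5))
  single <- glm(cbind(illegal, total - illegal) ~ evi,
                family = quasibinomial(), data = sites)
  expect_equal(unname(m$averaged_coefficients), unname(coef(single)),
               tolerance = 1e-10)
})

test_that("averaged predictions stay inside the candidate hull", {
  set.seed(12)
  sites <- data.frame(evi = runif(30, 0.05, 0.4),
                      prop_12_water = runif(30, 0.1, 1))
  sites$total <- rpois(30, 60) + 20
  sites$illegal <- rbinom(30, sites$total,
                          plogis(0.5 - 3 * sites$evi - sites$prop_12_water))
  m <- fit_pike_glm(sites, covariates = c("evi", "prop_12_water"))
  expect_equal(sum(m$table$weight), 1)
  nd <- data.frame(evi = runif(10, 0.05, 0.4),
                   prop_12_water = runif(10, 0.1, 1))
  avg <- predict_pike(m, nd)
  etas <- vapply(m$fits[m$table$admissible], function(f)
    predict(f, newdata = nd, type = "link"), numeric(10))
  expect_true(all(avg$eta >= apply(etas, 1, min) - 1e-10))
  expect_true(all(avg$eta <= apply(etas, 1, max) + 1e-10))
  expect_true(all(avg$pike > 0 & avg$pike < 1))
  expect_error(predict_pike(m, data.frame(evi = 0.2)), "missing covariate")
})

test_that("prediction error shrinks as PIKE training grows", {
  err <- function(n, seed) {
    set.seed(seed)
    tr <- data.frame(evi = runif(n, 0.05, 0.4))
    tr$total <- 60
    tr$illegal <- rbinom(n, 60, plogis(1 - 4 * tr$evi))
    m <- fit_pike_glm(tr, candidates = list("evi"))
    nd <- data.frame(evi = seq(0.1, 0.35, length.out = 20))
    mean(abs(predict_pike(m, nd)$pike - plogis(1 - 4 * nd$evi)))
  }
  small <- mean(vapply(1:20, function(s) err(8, s), numeric(1)))
  large <- mean(vapply(1:20, function(s) err(120, s), numeric(1)))
  expect_lt(large, small)
})
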