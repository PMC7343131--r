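# null-structure fishery: no aggregation, no season, no covariate effects
null_data <- function(seed, years = 2001:2008, sets_per_year = 400,
                      n_vessels = 12, vessel_sd = 0, ...) {
  cfg <- quick_config(seed = seed, years = years,
                      sets_per_year = sets_per_year, n_vessels = n_vessels,
                      vessel_sd = vessel_sd, ...)
  list(cfg = cfg,
       data = simulate_fishery(cfg, profiles = flat_profile(),
                               length_species = character(0)))
}

test_that("null simulations shrink smooths and track nominal annual means", {
  nd <- null_data(seed = 41, sets_per_year = 500)
  spec <- standardization_spec("catch_rate:BET")
  fit <- fit_standardization(nd$data, spec)
  edf <- summary(fit$gam)$s.table[, "edf"]
  expect_lt(edf[grep("lon", names(edf))], 1.5)
  ser <- predict_annual_series(fit, zone = "all")
  expect_true(all(ser$estimate > 0)) # back-transform to a positive rate
  expect_true(all(ser$lo95 <= ser$estimate & ser$estimate <= ser$hi95))
  nominal <- tapply(nd$data$sets$catch_BET / nd$data$sets$hooks * 1000,
                    nd$data$sets$year, mean)
  expect_gt(cor(ser$estimate, nominal), 0.95)
})

test_that("vessel random-intercept variance is recovered", {
  nd <- null_data(seed = 43, years = 2001:2005, sets_per_year = 800,
                  n_vessels = 50, vessel_sd = 0.3)
  fit <- fit_standardization(nd$data, standardization_spec("catch_rate:BET"))
  est <- vessel_sd_estimate(fit)
  expect_gt(est^2, 0.5 * 0.3^2)
  expect_lt(est^2, 1.5 * 0.3^2)
})

test_that("negative-binomial dispersion is recovered", {
  nd <- null_data(seed = 47, years = 2001:2005, sets_per_year = 2000,
                  n_vessels = 15)
  spec <- standardization_spec("catch_rate:BET",
                               likelihood = "negative_binomial")
  fit <- fit_standardization(nd$data, spec)
  theta <- fit$gam$family$getTheta(TRUE)
  expect_gt(theta, 1.5)
  expect_lt(theta, 2.7)
})

test_that("standardization removes vessel structure from annual series", {
  # a fleet whose composition drifts over time: strong vessel effects then
  # induce a spurious trend in nominal annual means that the vessel random
  # intercept should absorb
  cfg <- quick_config(seed = 54, years = 2001:2008, sets_per_year = 500,
                      n_vessels = 6, vessel_sd = 0.8)
  eff <- simulate_effort(cfg)
  yr_idx <- match(eff$year, cfg$years)
  n_yr <- length(cfg$years)
  set.seed(99)
  # early years fished by vessels 1-3, late years by 4-6
  eff$vessel_id <- vapply(yr_idx, function(t) {
    w <- if (t <= n_yr / 2) c(6, 6, 6, 1, 1, 1) else c(1, 1, 1, 6, 6, 6)
    paste0("V", sprintf("%03d", sample(6, 1, prob = w)))
  }, character(1))
  data <- simulate_catch(eff, flat_profile(), cfg,
                         length_species = character(0))
  fit <- fit_standardization(data, standardization_spec("catch_rate:BET"))
  ser <- predict_annual_series(fit)
  nominal <- tapply(data$sets$catch_BET / data$sets$hooks * 1000,
                    data$sets$year, mean)
  # the generating annual mean is constant: year-to-year variation in the
  # standardized series should be a small fraction of the nominal one
  expect_lt(sd(log(ser$estimate)), 0.25 * sd(log(nominal)))
})

test_that("contracts: minimum years, vessels and response typing", {
  nd <- null_data(seed = 59, years = 2004:2004, sets_per_year = 200)
  expect_error(fit_standardization(nd$data,
                                   standardization_spec("catch_rate:BET")),
               "2 years")
  nd2 <- null_data(seed = 61, years = 2004:2006, sets_per_year = 100,
                   n_vessels = 3)
  few <- nd2$data
  few$sets$vessel_id <- few$sets$vessel_id[1]
  expect_error(fit_standardization(few,
                                   standardization_spec("catch_rate:BET")),
               "3 vessels")
  expect_error(standardization_spec("tlc", likelihood = "negative_binomial"),
               "counts")
  expect_error(standardization_spec("biomass:BET"), "unknown response")
})

test_that("series grid is complete, flagged combinations are reported", {
  cfg <- quick_config(seed = 67, years = 2006:2012, sets_per_year = 400,
                      n_vessels = 15)
  data <- simulate_fishery(cfg, length_species = character(0))
  asg <- assign_zones(data$sets, cfg$zones)
  specs <- list(standardization_spec("catch_rate:BET", k_spatial = 15))
  ser <- build_all_series(data, asg, specs,
                          zones = c("kp110", "south", "northwest",
                                    "northeast"))
  flagged <- attr(ser, "flagged")
  got <- length(unique(paste(ser$zone, ser$metric))) + length(flagged)
  expect_equal(got, 4) # zones x metrics, fitted plus flagged
  # control zones span every simulated year
  expect_setequal(ser$year[ser$zone == "south"], 2006:2012)
})

test_that("a zone emptied by a closure still yields pre-closure years", {
  cfg <- quick_config(seed = 71, years = 2006:2012, sets_per_year = 600,
                      n_vessels = 15)
  data <- simulate_fishery(cfg, length_species = character(0))
  asg <- assign_zones(data$sets, cfg$zones)
  # the 50 nm core around Kingman/Palmyra closes in 2009: no sets after
  expect_equal(sum(asg$kp50 & data$sets$year >= 2009), 0)
  if (sum(asg$kp50) > 30 &&
      length(unique(data$sets$year[asg$kp50])) >= 2 &&
      length(unique(data$sets$vessel_id[asg$kp50])) >= 3) {
    sub <- mpaimpact:::subset_observer(data, asg$kp50)
    fit <- fit_standardization(sub, standardization_spec("catch_rate:BET",
                                                         k_spatial = 5))
    ser <- predict_annual_series(fit, zone = "kp50")
    expect_true(all(ser$year < 2009))
  }
})
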