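test_that("covariate simulation honors AR(1) structure and seeding", {
  cfg <- quick_config(seed = 5)
  # degenerate noise: every year equals the configured mean
  cfg0 <- simulation_config(
    years = 2000:2010, sets_per_year = 10,
    covariate_ar1 = list(pdo = c(mean = 0.3, ar = 0.5, sd = 0),
                         mei = c(mean = -1, ar = 0, sd = 0),
                         price_index = c(mean = 100, ar = 0.8, sd = 0)),
    seed = 5
  )
  cv <- simulate_covariates(cfg0)
  expect_true(all(cv$pdo == 0.3))
  expect_true(all(cv$mei == -1))
  expect_true(all(cv$price_index == 100))
  # determinism
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  # long-run lag-1 autocorrelation matches the configured coefficient
  cfg_long <- simulation_config(
    years = 2000:2010, sets_per_year = 10,
    covariate_ar1 = list(pdo = c(mean = 0, ar = 0.5, sd = 1)),
    seed = 42
  )
  x <- simulate_covariates(cfg_long, years = 1:10000)$pdo
  r1 <- acf(x, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1 - 0.5), 0.03)
  # non-stationary AR(1) is rejected at configuration time
  expect_error(
    simulation_config(covariate_ar1 = list(pdo = c(mean = 0, ar = 1.0,
                                                   sd = 1))),
    "non-stationary"
  )
})

test_that("effort placement respects active closures and reallocates", {
  cfg <- quick_config(seed = 9, years = 2005:2012, sets_per_year = 400)
  eff <- simulate_effort(cfg)
  z <- cfg$zones
  d <- mpaimpact:::feature_distances(eff$lat, eff$lon, z)
  post <- eff$date >= as.Date("2009-01-06")
  expect_true(all(apply(d[post, , drop = FALSE], 1, min) > 50))
  # pre-2009 the 50 nm band is fished (only the 12/3 nm cores are closed)
  expect_true(any(apply(d[!post, , drop = FALSE], 1, min) < 50))
  expect_gte(length(unique(eff$vessel_id)), 3)
  # determinism
  expect_identical(eff, simulate_effort(cfg))
})

test_that("without closures, effort density is stationary across years", {
  z_open <- zone_config(closure_schedule = data.frame(
    feature = "kingman", radius_nm = 1,
    start = as.Date("1994-01-01"), end = as.Date("1994-01-02")
  ))
  cfg <- simulation_config(years = 2005:2012, sets_per_year = 500,
                           zones = z_open, seed = 31)
  eff <- simulate_effort(cfg)
  a <- assign_zones(eff, z_open)
  tab <- table(eff$year, a$kp110)
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("catch process follows the negative-binomial log link", {
  # 100k draws at fixed covariates: empirical mean within 2% of closed form
  n <- 100000
  pl <- tibble::tibble(
    set_id = sprintf("S%06d", 1:n), vessel_id = "V001",
    date = as.Date("2003-05-10"), year = 2003, quarter = 2,
    lat = 30, lon = -150, hooks = 2000, hooks_per_float = 25,
    bait_type = "saury", hook_type = "tuna", sst = 20
  )
  cfg <- simulation_config(n_vessels = 3, years = 2003, sets_per_year = 1,
                           vessel_sd = 0, seed = 13)
  pr <- flat_profile(base_log_rate = log(5))
  covs <- tibble::tibble(year = 2003, pdo = 0, mei = 0, price_index = 100)
  out <- simulate_catch(pl, pr, cfg, covariates = covs,
                        length_species = character(0))
  d_min <- min(mpaimpact:::feature_distances(30, -150, cfg$zones))
  mu <- exp(log(5) + log(2000 / 1000) + 0 * exp(-d_min / 60))
  expect_lt(abs(mean(out$sets$catch_BET) / mu - 1), 0.02)
  # doubling hooks doubles the expected catch (log-link offset contract)
  pl2 <- pl
  pl2$hooks <- 4000
  out2 <- simulate_catch(pl2, pr, cfg, covariates = covs,
                         length_species = character(0))
  expect_lt(abs(mean(out2$sets$catch_BET) / mean(out$sets$catch_BET) - 2),
            0.06)
  # determinism
  out_b <- simulate_catch(pl, pr, cfg, covariates = covs,
                          length_species = character(0))
  expect_identical(out$sets$catch_BET, out_b$sets$catch_BET)
})

test_that("with zero aggregation the catch rate is flat in distance", {
  cfg <- quick_config(seed = 17, years = 2001:2006, sets_per_year = 5000,
                      n_vessels = 30)
  data <- simulate_fishery(cfg, profiles = flat_profile(aggregation_coef = 0),
                           length_species = character(0))
  d <- apply(mpaimpact:::feature_distances(data$sets$lat, data$sets$lon,
                                           cfg$zones), 1, min)
  lr <- log((data$sets$catch_BET + 0.5) / data$sets$hooks * 1000)
  m <- lm(lr ~ d)
  slope <- coef(summary(m))["d", ]
  expect_lt(abs(slope["Estimate"]), 2 * slope["Std. Error"])
})

test_that("aggregation of high-TL species raises TLc near features", {
  cfg <- quick_config(seed = 19, years = 2002:2005, sets_per_year = 2500,
                      n_vessels = 20)
  data <- simulate_fishery(cfg, length_species = character(0))
  tl <- trophic_table(data$profiles)
  catch_cols <- paste0("catch_", names(tl))
  cmat <- as.matrix(data$sets[, catch_cols])
  tot <- rowSums(cmat)
  tlc <- as.vector(cmat %*% tl) / tot
  d <- apply(mpaimpact:::feature_distances(data$sets$lat, data$sets$lon,
                                           cfg$zones), 1, min)
  ok <- tot > 0
  near <- ok & d <= 60
  far <- ok & d > 300
  expect_gt(sum(near), 50)
  expect_gt(mean(tlc[near]), mean(tlc[far]))
})

test_that("intervention multipliers scale treatment-zone rates as configured", {
  m_true <- 0.5
  cfg <- quick_config(
    seed = 23, years = 2004:2013, sets_per_year = 1500, n_vessels = 20,
    interventions = list(list(species = "BET", zone = "kp110",
                              multiplier = m_true, start_year = 2009,
                              path = "step"))
  )
  data <- simulate_fishery(cfg, profiles = flat_profile(aggregation_coef = 0),
                           length_species = character(0))
  asg <- assign_zones(data$sets, cfg$zones)
  s <- data$sets
  rate <- function(keep) sum(s$catch_BET[keep]) / sum(s$hooks[keep])
  post <- s$year >= 2009
  ratio_in <- rate(asg$kp110 & post) / rate(asg$kp110 & !post)
  ratio_out <- rate(!asg$kp110 & post) / rate(!asg$kp110 & !post)
  expect_lt(abs(ratio_in / ratio_out - m_true), 0.12)
  # unknown species code in an intervention is a configuration error
  bad <- quick_config(interventions = list(list(
    species = "ZZZ", zone = "kp110", multiplier = 0.5, start_year = 2009)))
  expect_error(simulate_fishery(bad), "unknown species")
})

test_that("observer CSV round trip preserves the dataset", {
  cfg <- quick_config(seed = 29, years = 2005:2007, sets_per_year = 50,
                      n_vessels = 5)
  data <- simulate_fishery(cfg)
  dir <- file.path(tempdir(), "obs_csv")
  write_observer_csv(data, dir)
  back <- read_observer_csv(dir)
  expect_equal(nrow(back$sets), nrow(data$sets))
  expect_equal(back$sets$catch_BET, data$sets$catch_BET)
  expect_equal(back$sets$date, data$sets$date)
  expect_equal(nrow(back$lengths), nrow(data$lengths))
})
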