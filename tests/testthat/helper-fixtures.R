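# Small simulation configurations and oracles shared across tests.

# a lean fishery: few vessels, modest effort, optional intervention
quick_config <- function(seed = 1L, years = 1999:2014, sets_per_year = 250,
                         n_vessels = 20, interventions = list(), ...) {
  simulation_config(
    n_vessels = n_vessels, years = years, sets_per_year = sets_per_year,
    intervention_effects = interventions, seed = seed, ...
  )
}

# single-species profile with controllable structure, zero covariate and
# seasonal effects unless stated
flat_profile <- function(code = "BET", base_log_rate = log(5),
                         aggregation_coef = 0, distance_scale = 60,
                         seasonal_amplitude = 0, coef_pdo = 0, coef_mei = 0,
                         nb_dispersion = 2, trophic_level = 4.81) {
  pr <- species_profiles()[1, ]
  pr$code <- code
  pr$trophic_level <- trophic_level
  pr$base_log_rate <- base_log_rate
  pr$aggregation_coef <- aggregation_coef
  pr$distance_scale <- distance_scale
  pr$seasonal_amplitude <- seasonal_amplitude
  pr$coef_pdo <- coef_pdo
  pr$coef_mei <- coef_mei
  pr$coef_price <- 0
  pr$nb_dispersion <- nb_dispersion
  pr
}

# dense multivariate-normal log-likelihood of the local-level model via the
# first-difference contrast: w_t = eta_{t-1} + eps_t - eps_{t-1} is MVN with
# a tridiagonal covariance. Independent of the Kalman recursion.
dense_local_level_ll <- function(y, se2, sl2) {
  n <- length(y)
  if (n < 2) return(0)
  m <- n - 1
  S <- matrix(0, m, m)
  diag(S) <- sl2 + 2 * se2
  S[abs(row(S) - col(S)) == 1] <- -se2
  w <- diff(y)
  as.numeric(-0.5 * (m * log(2 * pi) + determinant(S)$modulus +
                       t(w) %*% solve(S, w)))
}

# nominal (unstandardized) annual catch-rate series per zone: catch per
# 1000 hooks, for stage-2 inputs in recovery experiments
nominal_zone_series <- function(data, assignments, species,
                                zones = c("kp110", "south", "northwest",
                                          "northeast")) {
  col <- paste0("catch_", species)
  rows <- lapply(zones, function(z) {
    keep <- mpaimpact:::zone_index(assignments, z)
    s <- data$sets[keep, ]
    agg <- stats::aggregate(cbind(catch = s[[col]], hooks = s$hooks),
                            by = list(year = s$year), FUN = sum)
    tibble::tibble(zone = z, metric = paste0("catch_rate:", species),
                   year = agg$year,
                   estimate = agg$catch / agg$hooks * 1000)
  })
  dplyr::bind_rows(rows)
}

# one parameter-recovery / null replicate for the causal-impact module:
# simulate a small fishery, build nominal zone series, fit the
# counterfactual model for kp110 and summarize. The effort mixture leans
# toward the features so the treatment zone receives roughly the
# pre-closure effort level observed in the fishery (~60-70 sets/year
# within 110 nm of Kingman/Palmyra).
impact_replicate <- function(seed, multiplier = NULL, n_draws = 2000,
                             years = 1997:2016, sets_per_year = 600) {
  ivs <- if (is.null(multiplier)) list() else list(list(
    species = "BET", zone = "kp110", multiplier = multiplier,
    start_year = 2009, path = "step"
  ))
  cfg <- quick_config(seed = seed, years = years,
                      sets_per_year = sets_per_year, n_vessels = 20,
                      interventions = ivs,
                      effort_mixture = c(background = 0.45, core = 0.25,
                                         features = 0.30))
  # spatially homogeneous catch field: the closure's displacement of effort
  # then leaves the zone-level rate unconfounded, isolating the stage-2
  # estimator (removing spatial confounding is stage 1's job, tested
  # separately)
  data <- simulate_fishery(cfg, profiles = flat_profile(
    aggregation_coef = 0, seasonal_amplitude = 0.2,
    coef_pdo = 0.15, coef_mei = -0.05
  ), length_species = character(0))
  asg <- assign_zones(data$sets, cfg$zones)
  series <- nominal_zone_series(data, asg, "BET")
  cmx <- build_control_matrix(series, "kp110", "catch_rate:BET",
                              covariates = data$covariates,
                              intervention_year = 2009, transform = "log")
  fit <- fit_bsts(cmx, n_draws = n_draws, burn_in = 500, seed = seed + 1L)
  summarize_impact(fit)
}
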