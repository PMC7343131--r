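#' Synthetic-fishery simulation configuration
#'
#' Collects every setting of the seeded generator: fleet size, study years,
#' effort level and spatial mixture, the closure schedule (via a
#' [zone_config()]), AR(1) processes for the annual covariates, vessel
#' heterogeneity, and optional known intervention effects on treatment-zone
#' catch rates used for parameter-recovery experiments.
#'
#' @param n_vessels Number of vessels in the fleet (default 202, the fleet
#'   size the vessel random effect is meant to emulate).
#' @param years Integer vector of study years (default 1994:2018).
#' @param sets_per_year Observed sets per year (default 2500, the scale of a
#'   multi-decade observer dataset).
#' @param zones A [zone_config()] supplying features and the staged closure
#'   schedule.
#' @param covariate_ar1 Named list of `c(mean, ar, sd)` for each annual
#'   covariate (`pdo`, `mei`, `price_index`). `|ar| < 1` is required.
#' @param vessel_sd SD of vessel random intercepts on the log scale.
#' @param intervention_effects List of interventions, each a list with
#'   `species` (code), `zone` (treatment label, e.g. `"kp110"`),
#'   `multiplier` (> 0), `start_year`, and `path` (`"step"` or `"ramp"`),
#'   plus `ramp_years` (default 3). The multiplier scales the expected
#'   catch rate of that species for sets inside that zone from
#'   `start_year` onward.
#' @param effort_mixture Weights of the spatial effort mixture: uniform
#'   background over the study box, a broad kernel over the core grounds,
#'   and kernels at the shallow features.
#' @param seed Integer seed; every simulation output is a deterministic
#'   function of the configuration including this seed.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_vessels = 202,
                              years = 1994:2018,
                              sets_per_year = 2500,
                              zones = zone_config(),
                              covariate_ar1 = list(
                                pdo = c(mean = 0, ar = 0.7, sd = 0.6),
                                mei = c(mean = 0, ar = 0.6, sd = 0.8),
                                price_index = c(mean = 100, ar = 0.8, sd = 5)
                              ),
                              vessel_sd = 0.2,
                              intervention_effects = list(),
                              effort_mixture = c(background = 0.55,
                                                 core = 0.30,
                                                 features = 0.15),
                              seed = 1L) {
  stopifnot(n_vessels >= 3, sets_per_year >= 1, length(years) >= 1)
  for (nm in names(covariate_ar1)) {
    p <- covariate_ar1[[nm]]
    if (abs(p[["ar"]]) >= 1) {
      stop("non-stationary AR(1) for covariate '", nm, "' (|ar| must be < 1)",
           call. = FALSE)
    }
    if (p[["sd"]] < 0) stop("negative AR(1) sd for '", nm, "'", call. = FALSE)
  }
  for (iv in intervention_effects) {
    if (!is.numeric(iv$multiplier) || iv$multiplier <= 0) {
      stop("intervention multipliers must be > 0", call. = FALSE)
    }
  }
  structure(
    list(n_vessels = as.integer(n_vessels), years = as.integer(years),
         sets_per_year = as.integer(sets_per_year), zones = zones,
         covariate_ar1 = covariate_ar1, vessel_sd = vessel_sd,
         intervention_effects = intervention_effects,
         effort_mixture = effort_mixture, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", length(x$years), "years x", x$sets_per_year,
      "sets/year,", x$n_vessels, "vessels, seed", x$seed, "\n")
  if (length(x$intervention_effects)) {
    for (iv in x$intervention_effects) {
      cat("  intervention:", iv$species, "in", iv$zone, "x", iv$multiplier,
          "from", iv$start_year, "\n")
    }
  }
  invisible(x)
}

#' Simulate annual covariate series
#'
#' Draws each configured annual covariate (climate indices, price index) as
#' a stationary AR(1) process, initialized from its stationary
#' distribution.
#'
#' @param config A [simulation_config()].
#' @param years Optional year vector overriding `config$years` (used for
#'   long-run checks of the AR(1) moments).
#' @return Tibble with one row per year and one column per covariate.
#' @export
simulate_covariates <- function(config, years = config$years) {
  withr::local_seed(config$seed + 11L)
  n <- length(years)
  out <- tibble::tibble(year = years)
  for (nm in names(config$covariate_ar1)) {
    p <- config$covariate_ar1[[nm]]
    mu <- p[["mean"]]; ar <- p[["ar"]]; s <- p[["sd"]]
    x <- numeric(n)
    x[1] <- mu + if (s > 0) rnorm(1, 0, s / sqrt(1 - ar^2)) else 0
    if (n > 1) {
      eps <- rnorm(n - 1, 0, s)
      for (t in 2:n) x[t] <- mu + ar * (x[t - 1] - mu) + eps[t - 1]
    }
    out[[nm]] <- x
  }
  out
}

# TRUE for placements inside any closure active on their date
inside_closure <- function(lat, lon, date, zones) {
  d <- feature_distances(lat, lon, zones)
  cs <- zones$closure_schedule
  inside <- rep(FALSE, length(lat))
  for (i in seq_len(nrow(cs))) {
    active <- date >= cs$start[i] & (is.na(cs$end[i]) | date <= cs$end[i])
    inside <- inside | (active & d[, cs$feature[i]] <= cs$radius_nm[i])
  }
  inside
}

# draw n candidate positions from the spatial effort mixture
draw_positions <- function(n, config) {
  box <- config$zones$study_box
  w <- config$effort_mixture
  comp <- sample(c("background", "core", "features"), n, replace = TRUE,
                 prob = w[c("background", "core", "features")])
  lat <- numeric(n); lon <- numeric(n)
  nb <- sum(comp == "background")
  lat[comp == "background"] <- runif(nb, box$lat[1], box$lat[2])
  lon[comp == "background"] <- runif(nb, box$lon[1], box$lon[2])
  nc <- sum(comp == "core")
  # broad kernel over the core grounds north of the island chain
  lat[comp == "core"] <- rnorm(nc, 24, 5)
  lon[comp == "core"] <- rnorm(nc, -158, 7)
  nf <- sum(comp == "features")
  if (nf > 0) {
    fs <- config$zones$features
    pick <- sample(nrow(fs), nf, replace = TRUE)
    lat[comp == "features"] <- rnorm(nf, fs$lat[pick], 1.5)
    lon[comp == "features"] <- rnorm(nf, fs$lon[pick], 1.5)
  }
  lat <- pmin(pmax(lat, box$lat[1]), box$lat[2])
  lon <- pmin(pmax(lon, box$lon[1]), box$lon[2])
  list(lat = lat, lon = lon)
}

#' Simulate longline effort placements
#'
#' Places sets in space and time from a mixture of a uniform background, a
#' broad kernel over the core grounds and kernels near the shallow
#' features. Candidates falling inside a closure active on their date are
#' redrawn from the same mixture (displacement by renormalization), so no
#' set ever fishes a closed area and effort near features declines after
#' their closure.
#'
#' @param config A [simulation_config()].
#' @param zones Optional [zone_config()] overriding `config$zones`.
#' @return Tibble of placements: `set_id`, `vessel_id`, `date`, `year`,
#'   `quarter`, `lat`, `lon`, `hooks`, `hooks_per_float`, `bait_type`,
#'   `hook_type`, `sst`.
#' @export
simulate_effort <- function(config, zones = config$zones) {
  withr::local_seed(config$seed + 23L)
  n <- length(config$years) * config$sets_per_year
  year <- rep(config$years, each = config$sets_per_year)
  doy <- sample(1:365, n, replace = TRUE)
  date <- as.Date(paste0(year, "-01-01")) + (doy - 1)
  # unequal vessel activity so that some vessels dominate, as in real fleets
  vw <- rgamma(config$n_vessels, shape = 1.5)
  vessel_id <- paste0("V", sprintf("%03d", sample(config$n_vessels, n,
                                                  replace = TRUE, prob = vw)))
  pos <- draw_positions(n, config)
  lat <- pos$lat; lon <- pos$lon
  bad <- inside_closure(lat, lon, date, zones)
  tries <- 0
  while (any(bad)) {
    tries <- tries + 1
    if (tries > 100) {
      stop("infeasible effort placement: closures exclude the effort mixture",
           call. = FALSE)
    }
    repl <- draw_positions(sum(bad), config)
    lat[bad] <- repl$lat
    lon[bad] <- repl$lon
    bad[bad] <- inside_closure(lat[bad], lon[bad], date[bad], zones)
  }
  hooks <- pmin(pmax(round(rnorm(n, 2400, 250)), 1000), 3600)
  tibble::tibble(
    set_id = sprintf("S%06d", seq_len(n)),
    vessel_id = vessel_id,
    date = date,
    year = year,
    quarter = (as.integer(format(date, "%m")) - 1L) %/% 3L + 1L,
    lat = lat, lon = lon,
    hooks = hooks,
    hooks_per_float = sample(24:30, n, replace = TRUE),
    bait_type = sample(c("saury", "sardine", "mackerel"), n, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)),
    hook_type = sample(c("tuna", "circle14", "circle15"), n, replace = TRUE,
                       prob = c(0.35, 0.45, 0.20)),
    sst = 28.5 - 0.35 * (lat - 5) + rnorm(n, 0, 0.5)
  )
}

# fixed categorical log-effects used by the generator
.bait_effects <- c(saury = 0, sardine = 0.08, mackerel = -0.06)
.hook_effects <- c(tuna = 0, circle14 = -0.12, circle15 = 0.04)

# intervention multiplier path for one intervention, by calendar year
intervention_multiplier <- function(iv, year) {
  m <- rep(1, length(year))
  post <- year >= iv$start_year
  path <- if (is.null(iv$path)) "ramp" else iv$path
  ramp <- if (is.null(iv$ramp_years)) 3L else iv$ramp_years
  if (path == "step" || ramp <= 1) {
    m[post] <- iv$multiplier
  } else {
    frac <- pmin((year[post] - iv$start_year + 1) / ramp, 1)
    m[post] <- 1 + frac * (iv$multiplier - 1)
  }
  m
}

#' Simulate per-set catches and lengths
#'
#' Draws per-species catch counts for each placed set from a negative
#' binomial with log mean
#' `base_log_rate + log(hooks/1000) + alpha * exp(-d/d0) + seasonal +
#' covariate terms + vessel effect + gear effects + log(intervention
#' multiplier)`, where `d` is the distance (nm) to the nearest shallow
#' feature. Fork lengths are drawn for measured species.
#'
#' @param placements Effort table from [simulate_effort()].
#' @param profiles Species table, see [species_profiles()].
#' @param config A [simulation_config()].
#' @param covariates Annual covariate table; defaults to
#'   [simulate_covariates()] under the configured seed.
#' @param length_species Codes of species whose individuals are measured
#'   (default bigeye and yellowfin tuna, the species used in mean-length
#'   assessments).
#' @return List of class `observer_data` with `$sets` (placements plus
#'   wide `catch_<code>` columns), `$lengths` (long tibble `set_id`,
#'   `species`, `length_cm`), `$covariates` and `$profiles`.
#' @export
simulate_catch <- function(placements, profiles = species_profiles(),
                           config, covariates = NULL,
                           length_species = c("BET", "YFT")) {
  validate_profiles(profiles)
  if (is.null(covariates)) covariates <- simulate_covariates(config)
  for (iv in config$intervention_effects) {
    if (!iv$species %in% profiles$code) {
      stop("intervention references unknown species code '", iv$species, "'",
           call. = FALSE)
    }
  }
  stopifnot(all(placements$hooks >= 1))
  withr::local_seed(config$seed + 37L)

  n <- nrow(placements)
  d <- feature_distances(placements$lat, placements$lon, config$zones)
  d_min <- apply(d, 1, min)
  cov_row <- match(placements$year, covariates$year)
  pdo <- covariates$pdo[cov_row]
  mei <- covariates$mei[cov_row]
  log_price <- log(covariates$price_index[cov_row] / 100)
  doy <- as.integer(format(placements$date, "%j"))
  vessel_eff <- rnorm(config$n_vessels, 0, config$vessel_sd)
  names(vessel_eff) <- paste0("V", sprintf("%03d", seq_len(config$n_vessels)))
  v_eff <- vessel_eff[placements$vessel_id]
  gear_eff <- .bait_effects[placements$bait_type] +
    .hook_effects[placements$hook_type]
  # zone membership for interventions
  zones_needed <- unique(vapply(config$intervention_effects,
                                function(iv) tolower(iv$zone), character(1)))
  assign <- NULL
  if (length(zones_needed)) {
    assign <- assign_zones(placements, config$zones)
  }

  sets <- placements
  lengths <- list()
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    log_mu <- pr$base_log_rate +
      log(placements$hooks / 1000) +
      pr$aggregation_coef * exp(-d_min / pr$distance_scale) +
      pr$seasonal_amplitude * sin(2 * pi * doy / 365) +
      pr$coef_pdo * pdo + pr$coef_mei * mei + pr$coef_price * log_price +
      v_eff + gear_eff
    for (iv in config$intervention_effects) {
      if (iv$species != pr$code) next
      zl <- tolower(iv$zone)
      if (!zl %in% names(assign)) {
        stop("intervention zone '", iv$zone, "' is not a treatment label",
             call. = FALSE)
      }
      in_zone <- assign[[zl]]
      m <- intervention_multiplier(iv, placements$year)
      log_mu <- log_mu + ifelse(in_zone, log(m), 0)
    }
    cnt <- rnbinom(n, size = pr$nb_dispersion, mu = exp(log_mu))
    sets[[paste0("catch_", pr$code)]] <- cnt
    if (pr$code %in% length_species) {
      tot <- sum(cnt)
      if (tot > 0) {
        lengths[[pr$code]] <- tibble::tibble(
          set_id = rep(placements$set_id, cnt),
          species = pr$code,
          length_cm = pmax(rnorm(tot, pr$length_mean_cm, pr$length_sd_cm), 1)
        )
      }
    }
  }
  structure(
    list(sets = sets,
         lengths = if (length(lengths)) dplyr::bind_rows(lengths) else
           tibble::tibble(set_id = character(), species = character(),
                          length_cm = numeric()),
         covariates = covariates,
         profiles = profiles),
    class = "observer_data"
  )
}

#' @export
print.observer_data <- function(x, ...) {
  cat("<observer_data>", nrow(x$sets), "sets,",
      nrow(x$profiles), "species,", nrow(x$lengths), "measured lengths\n")
  invisible(x)
}

#' Simulate a complete observer dataset
#'
#' Convenience wrapper chaining [simulate_covariates()],
#' [simulate_effort()] and [simulate_catch()] under one configuration.
#'
#' @inheritParams simulate_catch
#' @return An `observer_data` list, see [simulate_catch()].
#' @export
simulate_fishery <- function(config, profiles = species_profiles(),
                             length_species = c("BET", "YFT")) {
  covs <- simulate_covariates(config)
  eff <- simulate_effort(config)
  simulate_catch(eff, profiles, config, covariates = covs,
                 length_species = length_species)
}

#' Write an observer dataset to CSV files
#'
#' Writes `sets.csv` (one row per set, wide `catch_<code>` columns),
#' `lengths.csv` (long format) and `covariates.csv` into a directory.
#'
#' @param data An `observer_data` object.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_observer_csv <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data$sets, file.path(dir, "sets.csv"), row.names = FALSE)
  write.csv(data$lengths, file.path(dir, "lengths.csv"), row.names = FALSE)
  write.csv(data$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read an observer dataset from CSV files
#'
#' Inverse of [write_observer_csv()].
#'
#' @param dir Directory containing `sets.csv`, `lengths.csv`,
#'   `covariates.csv`.
#' @param profiles Species profile table used downstream.
#' @return An `observer_data` list.
#' @export
read_observer_csv <- function(dir, profiles = species_profiles()) {
  sets <- tibble::as_tibble(read.csv(file.path(dir, "sets.csv")))
  sets$date <- as.Date(sets$date)
  structure(
    list(sets = sets,
         lengths = tibble::as_tibble(read.csv(file.path(dir, "lengths.csv"))),
         covariates = tibble::as_tibble(read.csv(file.path(dir,
                                                           "covariates.csv"))),
         profiles = profiles),
    class = "observer_data"
  )
}
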