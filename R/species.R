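#' Default species profiles for the synthetic fishery
#'
#' One row per species susceptible to capture in deep-set pelagic longline
#' gear: the six species used in counterfactual catch-rate assessments
#' (albacore, bigeye and yellowfin tunas, blue shark, longnose lancetfish,
#' striped marlin) plus species/groups of conservation concern (ETP:
#' endangered, threatened, protected). Fields drive the catch generator:
#'
#' * `trophic_level`: fractional trophic level (TL). Bigeye tuna 4.81,
#'   blue shark 4.95 and longnose lancetfish 4.34 are literature values;
#'   the rest are approximate defaults in the plausible pelagic range.
#' * `base_log_rate`: log expected catch per 1000 hooks in open ocean.
#' * `aggregation_coef` (alpha): log-rate boost at a shallow feature,
#'   decaying as `exp(-d / distance_scale)` with distance `d` (nm).
#'   Positive for feature-associated apex predators, negative for species
#'   relatively more abundant away from features.
#' * `coef_pdo`, `coef_mei`, `coef_price`: log-linear effects of the annual
#'   covariates (climate indices; price enters as log(price/100)).
#' * `nb_dispersion`: negative-binomial size parameter k, variance
#'   mu + mu^2/k.
#' * `length_mean_cm`, `length_sd_cm`: normal length distribution.
#'
#' Catch-rate magnitudes are chosen for numerical stability at desk scale,
#' not to reproduce any particular fishery.
#'
#' @return Tibble with one row per species.
#' @export
species_profiles <- function() {
  tibble::tribble(
    ~code, ~name, ~trophic_level, ~group, ~base_log_rate,
    ~aggregation_coef, ~distance_scale, ~seasonal_amplitude,
    ~coef_pdo, ~coef_mei, ~coef_price, ~nb_dispersion,
    ~length_mean_cm, ~length_sd_cm,
    "BET", "bigeye tuna",          4.81, "tuna",          log(6.0),  0.8, 60, 0.20,  0.15, -0.05, 0.0, 2, 120, 15,
    "YFT", "yellowfin tuna",       4.40, "tuna",          log(2.0),  0.6, 60, 0.25,  0.10,  0.10, 0.0, 2, 110, 15,
    "ALB", "albacore",             4.31, "tuna",          log(3.0),  0.2, 60, 0.30, -0.10,  0.05, 0.0, 2,  95, 10,
    "BSH", "blue shark",           4.95, "shark",         log(5.0),  0.9, 60, 0.15,  0.05, -0.10, 0.0, 2, 180, 25,
    "LAN", "longnose lancetfish",  4.34, "other_teleost", log(6.0), -0.5, 60, 0.10, -0.05,  0.05, 0.0, 2, 100, 20,
    "MLS", "striped marlin",       4.65, "other_teleost", log(0.8), -0.4, 60, 0.20,  0.10,  0.00, 0.0, 2, 170, 20,
    "OCS", "oceanic whitetip shark", 4.20, "etp",         log(0.15), 1.0, 60, 0.10,  0.00,  0.05, 0.0, 2, 160, 25,
    "FAL", "silky shark",          4.46, "etp",           log(0.10), 1.0, 60, 0.10,  0.00,  0.05, 0.0, 2, 150, 25,
    "BTH", "bigeye thresher shark", 4.50, "etp",          log(0.12), 0.0, 60, 0.10,  0.00,  0.00, 0.0, 2, 160, 25,
    "SMA", "shortfin mako shark",  4.50, "etp",           log(0.05), -0.5, 60, 0.10, 0.00,  0.00, 0.0, 2, 170, 30,
    "RID", "olive ridley turtle",  2.70, "etp",           log(0.006), 0.8, 60, 0.10, 0.00,  0.00, 0.0, 2,  65, 6,
    "ALBA", "albatrosses",         3.90, "etp",           log(0.008), -0.8, 60, 0.30, 0.00, 0.00, 0.0, 2,  80, 5,
    "ODO", "odontocetes",          4.70, "etp",           log(0.004), 0.0, 60, 0.10, 0.00,  0.00, 0.0, 2, 250, 40
  )
}

validate_profiles <- function(profiles) {
  stopifnot(
    all(profiles$trophic_level >= 2.0 & profiles$trophic_level <= 5.5),
    all(profiles$nb_dispersion > 0),
    all(profiles$distance_scale > 0),
    all(profiles$length_sd_cm > 0),
    !anyDuplicated(profiles$code)
  )
  invisible(profiles)
}

#' Trophic-level lookup table
#'
#' @param profiles Species profile table, see [species_profiles()].
#' @return Named numeric vector mapping species code to trophic level.
#' @export
trophic_table <- function(profiles = species_profiles()) {
  setNames(profiles$trophic_level, profiles$code)
}
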