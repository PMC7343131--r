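#' Compare ETP catch rates inside vs outside MPA footprints
#'
#' For each bycatch species of conservation concern with adequate sample
#' sizes, fits a negative-binomial additive mixed model to set-level catch
#' counts with an inside/outside-zone factor, year, quarter, gear
#' covariates, a log-hooks offset and a vessel random intercept, and
#' reports the expected catch per set by zone at reference covariates.
#' Rates are called significantly different when the 95% intervals are
#' disjoint; a Wald p-value for the zone coefficient is reported
#' alongside. "Inside" defaults to the future MPA footprints (50 nm of
#' Kingman/Palmyra, 200 nm of Johnston).
#'
#' @param data An `observer_data` object.
#' @param assignments Output of [assign_zones()].
#' @param species Character vector of species codes (default: the five
#'   bycatch species fitted this way — striped marlin and blue, bigeye
#'   thresher, oceanic whitetip and silky sharks).
#' @param inside Logical vector defining the inside group; defaults to
#'   `kp50 | j200`.
#' @param min_nonzero Species with fewer nonzero sets are skipped with a
#'   message (they belong in [rare_event_rates()]).
#' @return Tibble with one row per species: inside/outside expected catch
#'   per set with 95% intervals, Wald statistics and the disjoint-interval
#'   significance flag.
#' @export
compare_etp_rates <- function(data, assignments,
                              species = c("MLS", "BSH", "BTH", "OCS", "FAL"),
                              inside = NULL, min_nonzero = 30) {
  sets <- data$sets
  if (is.null(inside)) inside <- assignments$kp50 | assignments$j200
  stopifnot(length(inside) == nrow(sets))
  if (!any(inside) || all(inside)) {
    stop("both zones must contain sets", call. = FALSE)
  }
  rows <- list()
  for (sp in species) {
    cnt <- sets[[paste0("catch_", sp)]]
    if (is.null(cnt)) stop("no catch column for ", sp, call. = FALSE)
    if (sum(cnt > 0) < min_nonzero) {
      message("skipping ", sp, ": fewer than ", min_nonzero,
              " nonzero sets; use rare_event_rates()")
      next
    }
    df <- tibble::tibble(
      count = cnt,
      zone = factor(ifelse(inside, "inside", "outside"),
                    levels = c("outside", "inside")),
      year_f = factor(sets$year),
      quarter_f = factor(sets$quarter),
      bait_type = factor(sets$bait_type),
      hook_type = factor(sets$hook_type),
      hooks_per_float = sets$hooks_per_float,
      hooks = sets$hooks,
      vessel_f = factor(sets$vessel_id)
    )
    fit <- mgcv::gam(
      count ~ zone + year_f + quarter_f + bait_type + hook_type +
        hooks_per_float + s(vessel_f, bs = "re") + offset(log(hooks)),
      data = df, family = mgcv::nb(), method = "REML"
    )
    modal <- function(f) names(sort(table(f), decreasing = TRUE))[1]
    nd <- data.frame(
      zone = factor(c("inside", "outside"),
                    levels = levels(df$zone)),
      year_f = factor(modal(df$year_f), levels = levels(df$year_f)),
      quarter_f = factor(modal(df$quarter_f), levels = levels(df$quarter_f)),
      bait_type = factor(modal(df$bait_type), levels = levels(df$bait_type)),
      hook_type = factor(modal(df$hook_type), levels = levels(df$hook_type)),
      hooks_per_float = median(df$hooks_per_float),
      hooks = median(df$hooks),
      vessel_f = factor(levels(df$vessel_f)[1], levels = levels(df$vessel_f))
    )
    pr <- predict(fit, nd, type = "link", se.fit = TRUE,
                  exclude = "s(vessel_f)", newdata.guaranteed = TRUE)
    est <- unname(exp(pr$fit))
    lo <- unname(exp(pr$fit - 1.96 * pr$se.fit))
    hi <- unname(exp(pr$fit + 1.96 * pr$se.fit))
    zc <- which(names(coef(fit)) == "zoneinside")
    wald_z <- coef(fit)[zc] / sqrt(vcov(fit)[zc, zc])
    rows[[sp]] <- tibble::tibble(
      species = sp,
      inside_rate = est[1], inside_lo95 = lo[1], inside_hi95 = hi[1],
      outside_rate = est[2], outside_lo95 = lo[2], outside_hi95 = hi[2],
      log_ratio = unname(coef(fit)[zc]),
      wald_z = unname(wald_z),
      p_value = unname(2 * pnorm(-abs(wald_z))),
      significant = lo[1] > hi[2] || lo[2] > hi[1],
      criterion = "disjoint 95% intervals"
    )
  }
  dplyr::bind_rows(rows)
}

#' Compare annual trophic-level-of-the-catch trends inside vs outside
#' treatment zones
#'
#' Fits a Gaussian additive mixed model to set-specific TLc with an
#' inside/outside grouping (the 110/260 nm treatment zones by default), a
#' smooth annual trend per group, gear covariates and a vessel random
#' intercept. Returns the smoothed annual trends with 95% bands, per-year
#' band-overlap flags, and a Wald test of the overall inside-outside mean
#' difference.
#'
#' @param data An `observer_data` object.
#' @param assignments Output of [assign_zones()].
#' @param inside Logical; defaults to the treatment-zone footprint
#'   `kp110 | j260`.
#' @param min_sets Group size below which a warning is raised (estimates
#'   are still returned).
#' @return List with `trends` (tibble `group`, `year`, `estimate`, `lo95`,
#'   `hi95`, `overlap`), `difference` (estimate, se, p_value) and the
#'   fitted model.
#' @export
compare_tlc_trends <- function(data, assignments, inside = NULL,
                               min_sets = 50) {
  sets <- data$sets
  if (is.null(inside)) inside <- assignments$kp110 | assignments$j260
  spec <- standardization_spec("tlc")
  df <- std_model_frame(data, spec)
  inside <- inside[match(df$set_id, sets$set_id)]
  if (!any(inside) || all(inside)) {
    stop("TLc comparison needs sets in both groups", call. = FALSE)
  }
  if (min(sum(inside), sum(!inside)) < min_sets) {
    warning("a group has fewer than ", min_sets, " sets; estimates are weak")
  }
  df$group <- factor(ifelse(inside, "inside", "outside"),
                     levels = c("outside", "inside"))
  df$year_n <- as.numeric(as.character(df$year_f))
  if (length(unique(df$year_n[df$group == "inside"])) < 2 ||
      length(unique(df$year_n[df$group == "outside"])) < 2) {
    stop("at least 2 years are required in both groups", call. = FALSE)
  }
  k_yr <- max(3, min(8, length(unique(df$year_n)) - 1))
  fit <- mgcv::gam(
    resp ~ group + s(year_n, by = group, k = k_yr) + quarter_f +
      bait_type + hook_type + hooks_per_float + s(vessel_f, bs = "re"),
    data = df, method = "REML"
  )
  modal <- function(f) names(sort(table(f), decreasing = TRUE))[1]
  years <- sort(unique(df$year_n))
  nd <- expand.grid(year_n = years, group = levels(df$group))
  nd$quarter_f <- factor(modal(df$quarter_f), levels = levels(df$quarter_f))
  nd$bait_type <- factor(modal(df$bait_type), levels = levels(df$bait_type))
  nd$hook_type <- factor(modal(df$hook_type), levels = levels(df$hook_type))
  nd$hooks_per_float <- median(df$hooks_per_float)
  nd$vessel_f <- factor(levels(df$vessel_f)[1], levels = levels(df$vessel_f))
  pr <- predict(fit, nd, se.fit = TRUE, exclude = "s(vessel_f)",
                newdata.guaranteed = TRUE)
  trends <- tibble::tibble(
    group = nd$group, year = nd$year_n,
    estimate = as.numeric(pr$fit),
    lo95 = as.numeric(pr$fit - 1.96 * pr$se.fit),
    hi95 = as.numeric(pr$fit + 1.96 * pr$se.fit)
  )
  wide <- tidyr::pivot_wider(trends, names_from = "group",
                             values_from = c("estimate", "lo95", "hi95"))
  overlap <- !(wide$lo95_inside > wide$hi95_outside |
                 wide$lo95_outside > wide$hi95_inside)
  trends$overlap <- overlap[match(trends$year, wide$year)]
  zc <- which(names(coef(fit)) == "groupinside")
  est <- coef(fit)[zc]
  se <- sqrt(vcov(fit)[zc, zc])
  list(
    trends = trends,
    difference = list(estimate = unname(est), se = unname(se),
                      wald_z = unname(est / se),
                      p_value = unname(2 * pnorm(-abs(est / se)))),
    fit = fit
  )
}

#' Compare annual Shannon diversity among zones
#'
#' Computes effort-rarefied annual H' per zone (bootstrap CIs; the
#' rarefaction target is the smallest zone-year effort across the
#' compared strata), tests each zone's linear trend in annual H', and
#' summarizes cross-zone interval overlap.
#'
#' @param data An `observer_data` object.
#' @param assignments Output of [assign_zones()].
#' @param zones Zone labels to compare (default: combined MPA footprint
#'   `"mpa"` = kp50 | j200, and the three control zones).
#' @param n_boot Bootstrap replicates per zone-year.
#' @param seed Integer seed.
#' @return List with `annual` (tibble `zone`, `year`, `estimate`, `lo95`,
#'   `hi95`), `trend_tests` (per-zone slope, se, p_value) and
#'   `all_overlap` (logical: every pair of zone intervals overlaps in
#'   every shared year).
#' @export
compare_shannon_trends <- function(data, assignments,
                                   zones = c("mpa", "south", "northwest",
                                             "northeast"),
                                   n_boot = 200, seed = 1L) {
  sets <- data$sets
  idx <- lapply(zones, function(z) {
    if (z == "mpa") assignments$kp50 | assignments$j200
    else zone_index(assignments, z)
  })
  names(idx) <- zones
  # rarefaction target: smallest zone-year effort with at least one set
  eff <- list()
  for (z in zones) {
    s <- sets[idx[[z]], ]
    if (length(unique(s$year)) < 3) {
      stop("zone ", z, " has fewer than 3 years of data", call. = FALSE)
    }
    eff[[z]] <- tapply(s$hooks, s$year, sum)
  }
  target <- min(unlist(eff))
  rows <- list()
  for (z in zones) {
    s <- sets[idx[[z]], ]
    for (yr in sort(unique(s$year))) {
      sy <- s[s$year == yr, ]
      r <- rarefied_shannon(sy, target_effort = min(target, sum(sy$hooks)),
                            n_boot = n_boot,
                            seed = seed + yr - min(s$year))
      rows[[paste(z, yr)]] <- tibble::tibble(
        zone = z, year = yr, estimate = r$estimate,
        lo95 = r$lo95, hi95 = r$hi95
      )
    }
  }
  annual <- dplyr::bind_rows(rows)
  trend_tests <- dplyr::bind_rows(lapply(zones, function(z) {
    sub <- annual[annual$zone == z, ]
    m <- lm(estimate ~ year, data = sub)
    co <- summary(m)$coefficients
    tibble::tibble(zone = z, slope = co["year", 1], se = co["year", 2],
                   p_value = co["year", 4])
  }))
  shared <- Reduce(intersect, lapply(zones, function(z)
    annual$year[annual$zone == z]))
  all_overlap <- TRUE
  for (yr in shared) {
    sub <- annual[annual$year == yr, ]
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        if (sub$lo95[i] > sub$hi95[j] || sub$lo95[j] > sub$hi95[i]) {
          all_overlap <- FALSE
        }
      }
    }
  }
  list(annual = annual, trend_tests = trend_tests, all_overlap = all_overlap)
}
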