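#' Specification of a stage-1 standardization model
#'
#' Describes how set-level records are turned into a standardized annual
#' index: the response (`"catch_rate:<code>"`, `"mean_length:<code>"` or
#' `"tlc"`), the likelihood, and the smoother dimensions. The default
#' catch-rate model is the Gaussian spatially explicit additive mixed
#' model on `log((catch + 0.5) / hooks * 1000)` per set — the +0.5
#' continuity correction handles zero catches — with year, quarter, bait
#' type, hook type, hooks-per-float and log-hooks fixed effects, a
#' ridge-penalized vessel random intercept and a low-rank 2-D spatial
#' smooth. Counts can instead be modelled directly with a negative
#' binomial likelihood and a `log(hooks/1000)` offset.
#'
#' @param response One of `"catch_rate:<code>"`, `"mean_length:<code>"`,
#'   `"tlc"`.
#' @param likelihood `"gaussian"` (default; catch rates are modelled on the
#'   log scale) or `"negative_binomial"` (counts only).
#' @param k_spatial Basis dimension of the 2-D spatial smooth (<= 50).
#' @return Object of class `std_spec`.
#' @export
standardization_spec <- function(response,
                                 likelihood = c("gaussian",
                                                "negative_binomial"),
                                 k_spatial = 25) {
  likelihood <- match.arg(likelihood)
  parts <- strsplit(response, ":", fixed = TRUE)[[1]]
  type <- parts[1]
  if (!type %in% c("catch_rate", "mean_length", "tlc")) {
    stop("unknown response type '", type, "'", call. = FALSE)
  }
  if (likelihood == "negative_binomial" && type != "catch_rate") {
    stop("negative binomial applies to counts (catch_rate) only",
         call. = FALSE)
  }
  stopifnot(k_spatial >= 5, k_spatial <= 50)
  structure(
    list(response = response, type = type,
         species = if (length(parts) > 1) parts[2] else NA_character_,
         likelihood = likelihood, k_spatial = k_spatial),
    class = "std_spec"
  )
}

# build the model frame for one standardization response
std_model_frame <- function(data, spec, trophic = NULL) {
  sets <- data$sets
  df <- tibble::tibble(
    set_id = sets$set_id,
    year_f = factor(sets$year),
    quarter_f = factor(sets$quarter),
    bait_type = factor(sets$bait_type),
    hook_type = factor(sets$hook_type),
    hooks_per_float = sets$hooks_per_float,
    log_hooks = log(sets$hooks),
    hooks = sets$hooks,
    lon = sets$lon, lat = sets$lat,
    vessel_f = factor(sets$vessel_id)
  )
  if (spec$type == "catch_rate") {
    col <- paste0("catch_", spec$species)
    if (is.null(sets[[col]])) stop("no catch column ", col, call. = FALSE)
    df$count <- sets[[col]]
    df$resp <- log((sets[[col]] + 0.5) / sets$hooks * 1000)
  } else if (spec$type == "tlc") {
    if (is.null(trophic)) trophic <- trophic_table(data$profiles)
    catch_cols <- grep("^catch_", names(sets), value = TRUE)
    codes <- sub("^catch_", "", catch_cols)
    cmat <- as.matrix(sets[, catch_cols, drop = FALSE])
    tot <- rowSums(cmat)
    tl <- trophic[codes]
    if (anyNA(tl)) {
      stop("no trophic level for species: ",
           paste(codes[is.na(tl)], collapse = ", "), call. = FALSE)
    }
    df$resp <- as.vector(cmat %*% tl) / tot
    df <- df[tot > 0, ]
  } else { # mean_length
    len <- data$lengths[data$lengths$species == spec$species, ]
    if (nrow(len) == 0) stop("no lengths for ", spec$species, call. = FALSE)
    ml <- dplyr::summarise(dplyr::group_by(len, .data$set_id),
                           resp = mean(.data$length_cm), .groups = "drop")
    df <- dplyr::inner_join(df, ml, by = "set_id")
  }
  df
}

#' Fit a stage-1 standardization model
#'
#' Fits the penalized additive mixed model described by a
#' [standardization_spec()] to a collection of sets (typically one zone),
#' by restricted maximum likelihood via [mgcv::gam()].
#'
#' @param data An `observer_data` object (see [simulate_catch()] or
#'   [read_observer_csv()]), or a subset of one.
#' @param spec A [standardization_spec()].
#' @param trophic Optional trophic table for the `tlc` response.
#' @return Object of class `std_fit` wrapping the fitted
#'   [mgcv::gamObject] plus the model frame and spec.
#' @export
fit_standardization <- function(data, spec, trophic = NULL) {
  stopifnot(inherits(spec, "std_spec"))
  df <- std_model_frame(data, spec, trophic)
  if (nlevels(droplevels(df$year_f)) < 2) {
    stop("at least 2 years of data are required", call. = FALSE)
  }
  if (nlevels(droplevels(df$vessel_f)) < 3) {
    stop("at least 3 vessels are required", call. = FALSE)
  }
  df <- droplevels(df)
  k_sp <- min(spec$k_spatial, max(nrow(df) %/% 4, 5))
  fixed <- "year_f + quarter_f + bait_type + hook_type + hooks_per_float"
  # drop single-level factors (e.g. one quarter present) to keep full rank
  for (v in c("quarter_f", "bait_type", "hook_type")) {
    if (nlevels(df[[v]]) < 2) fixed <- sub(paste0(" \\+ ", v), "", fixed)
  }
  if (spec$likelihood == "gaussian") {
    form <- as.formula(paste(
      "resp ~", fixed, "+ log_hooks",
      "+ s(lon, lat, bs = 'ts', k =", k_sp, ") + s(vessel_f, bs = 're')"))
    fit <- mgcv::gam(form, data = df, method = "REML")
  } else {
    form <- as.formula(paste(
      "count ~", fixed,
      "+ s(lon, lat, bs = 'ts', k =", k_sp, ") + s(vessel_f, bs = 're')",
      "+ offset(log(hooks / 1000))"))
    fit <- mgcv::gam(form, data = df, family = mgcv::nb(), method = "REML")
  }
  if (anyNA(coef(fit))) {
    bad <- unique(sub("[0-9]+$", "", names(coef(fit))[is.na(coef(fit))]))
    stop("rank-deficient fit; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(gam = fit, frame = df, spec = spec), class = "std_fit")
}

#' @export
print.std_fit <- function(x, ...) {
  cat("<std_fit>", x$spec$response, "(", x$spec$likelihood, "),",
      nrow(x$frame), "sets,", nlevels(x$frame$year_f), "years,",
      nlevels(x$frame$vessel_f), "vessels\n")
  invisible(x)
}

#' Estimated vessel random-intercept standard deviation
#'
#' @param fit A [fit_standardization()] object.
#' @return Estimated SD of the vessel random intercepts.
#' @export
vessel_sd_estimate <- function(fit) {
  vc <- NULL
  invisible(utils::capture.output(
    vc <- mgcv::gam.vcomp(fit$gam, rescale = TRUE)
  ))
  unname(vc[grep("vessel", rownames(vc)), "std.dev"][1])
}

#' Predict a standardized annual series
#'
#' Predicts the annual index at reference covariates (modal gear
#' categories, median hooks-per-float and log-hooks, quarter 2 where
#' present, the effort-weighted mean position of the fitted sets) with the
#' vessel random effect excluded, and back-transforms to the response
#' scale with delta-method 95% intervals computed on the link scale.
#'
#' @param fit A [fit_standardization()] object.
#' @param zone Zone label recorded on the output.
#' @return Tibble `zone`, `metric`, `year`, `estimate`, `se`, `lo95`,
#'   `hi95`; the standard error is on the link (log for catch rates)
#'   scale.
#' @export
predict_annual_series <- function(fit, zone = NA_character_) {
  df <- fit$frame
  if (nrow(df) == 0) stop("no training sets for this zone", call. = FALSE)
  modal <- function(f) names(sort(table(f), decreasing = TRUE))[1]
  years <- sort(unique(as.character(df$year_f)))
  q_ref <- if ("2" %in% levels(df$quarter_f)) "2" else modal(df$quarter_f)
  nd <- data.frame(
    year_f = factor(years, levels = levels(df$year_f)),
    quarter_f = factor(q_ref, levels = levels(df$quarter_f)),
    bait_type = factor(modal(df$bait_type), levels = levels(df$bait_type)),
    hook_type = factor(modal(df$hook_type), levels = levels(df$hook_type)),
    hooks_per_float = median(df$hooks_per_float),
    log_hooks = median(df$log_hooks),
    hooks = exp(median(df$log_hooks)),
    lon = mean(df$lon), lat = mean(df$lat),
    vessel_f = factor(levels(df$vessel_f)[1], levels = levels(df$vessel_f))
  )
  pr <- predict(fit$gam, newdata = nd, type = "link", se.fit = TRUE,
                exclude = "s(vessel_f)", newdata.guaranteed = TRUE)
  est_link <- as.numeric(pr$fit)
  se <- as.numeric(pr$se.fit)
  lo_link <- est_link - 1.96 * se
  hi_link <- est_link + 1.96 * se
  back <- if (fit$spec$type == "catch_rate") exp else identity
  tibble::tibble(
    zone = zone,
    metric = fit$spec$response,
    year = as.integer(years),
    estimate = back(est_link),
    se = se,
    lo95 = back(lo_link),
    hi95 = back(hi_link)
  )
}

# subset an observer_data object by a logical index over sets
subset_observer <- function(data, keep) {
  sets <- data$sets[keep, , drop = FALSE]
  structure(
    list(sets = sets,
         lengths = data$lengths[data$lengths$set_id %in% sets$set_id, ,
                                drop = FALSE],
         covariates = data$covariates,
         profiles = data$profiles),
    class = "observer_data"
  )
}

# logical index of sets belonging to a zone label
zone_index <- function(assignments, zone) {
  zl <- tolower(zone)
  if (zl %in% c("kp50", "kp110", "j50", "j110", "j200", "j260")) {
    assignments[[zl]]
  } else if (zl %in% c("south", "northwest", "northeast")) {
    !is.na(assignments$control_label) & assignments$control_label == zl
  } else {
    stop("unknown zone label '", zone, "'", call. = FALSE)
  }
}

#' Build standardized annual series for every zone and metric
#'
#' Fits one standardization model per (zone, metric) combination — the
#' three treatment zones and three control zones by default — and collects
#' the predicted annual series. Combinations that cannot be fitted (no
#' sets) or yield fewer than 3 annual points are reported in the
#' `flagged` attribute rather than silently dropped; zones emptied after a
#' closure still contribute their pre-closure years.
#'
#' @param data An `observer_data` object.
#' @param assignments Output of [assign_zones()] for `data$sets`.
#' @param specs List of [standardization_spec()] objects.
#' @param zones Character vector of zone labels (treatment labels and/or
#'   control zone names).
#' @return Tibble of series rows (see [predict_annual_series()]) with a
#'   `flagged` attribute listing unusable combinations and the reason.
#' @export
build_all_series <- function(data, assignments, specs,
                             zones = c("kp110", "j110", "j260",
                                       "south", "northwest", "northeast")) {
  out <- list()
  flagged <- list()
  for (spec in specs) {
    for (z in zones) {
      keep <- zone_index(assignments, z)
      tag <- paste(z, spec$response, sep = "/")
      if (!any(keep)) {
        flagged[[tag]] <- "no sets"
        next
      }
      sub <- subset_observer(data, keep)
      res <- tryCatch(
        predict_annual_series(fit_standardization(sub, spec), zone = z),
        error = function(e) conditionMessage(e)
      )
      if (is.character(res)) {
        flagged[[tag]] <- res
        next
      }
      if (nrow(res) < 3) {
        flagged[[tag]] <- "fewer than 3 annual points; unusable for stage 2"
        next
      }
      out[[tag]] <- res
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "flagged") <- flagged
  res
}
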