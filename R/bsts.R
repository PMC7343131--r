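#' Local-level marginal log-likelihood by Kalman recursion
#'
#' Exact diffuse-filter log-likelihood of the local-level model
#' `y_t = mu_t + eps_t`, `mu_{t+1} = mu_t + eta_t` with
#' `eps ~ N(0, sigma_eps2)`, `eta ~ N(0, sigma_eta2)` and a diffuse level.
#' Under the diffuse convention the first observation carries no
#' information: its contribution is dropped, so the value equals the joint
#' log-density of the (n - 1) first differences of `y` (and is therefore
#' invariant to adding a constant to `y`). For `n = 1` the log-likelihood
#' is 0 (empty contrast).
#'
#' @param y Numeric series.
#' @param sigma_eps2 Observation variance (> 0).
#' @param sigma_eta2 Level-innovation variance (> 0).
#' @param X Optional regression matrix; with `beta`, the recursion runs on
#'   `y - X %*% beta` (regression-residual mode).
#' @param beta Coefficients for `X`.
#' @return Log-likelihood (scalar).
#' @export
kalman_loglik <- function(y, sigma_eps2, sigma_eta2, X = NULL, beta = NULL) {
  if (!all(is.finite(y))) stop("non-finite values in y", call. = FALSE)
  if (sigma_eps2 <= 0 || sigma_eta2 <= 0) {
    stop("variances must be > 0", call. = FALSE)
  }
  if (!is.null(X)) {
    if (is.null(beta)) stop("beta required with X", call. = FALSE)
    y <- y - as.vector(as.matrix(X) %*% beta)
  }
  n <- length(y)
  if (n <= 1) return(0)
  m <- y[1]
  C <- sigma_eps2 # filtered variance of the level after the first point
  ll <- 0
  for (t in 2:n) {
    R <- C + sigma_eta2
    F_ <- R + sigma_eps2
    v <- y[t] - m
    ll <- ll - 0.5 * (log(2 * pi * F_) + v * v / F_)
    K <- R / F_
    m <- m + K * v
    C <- R * (1 - K)
  }
  ll
}

#' Assemble a standardized control matrix for counterfactual modelling
#'
#' Packs the treatment-zone series `y` and the synthetic-control predictor
#' columns `X` (reference-zone series plus exogenous annual covariates)
#' onto a common year grid, standardizes predictors to mean 0 / sd 1 over
#' the full period and `y` over the pre-intervention period, and records
#' the transformation for exact back-transformation.
#'
#' @param y Treatment-zone annual series (original scale).
#' @param X Matrix or data frame of predictor series (original scale), one
#'   column per predictor.
#' @param years Year vector shared by `y` and `X`, no gaps.
#' @param intervention_year First calendar year of the post-intervention
#'   period; must lie strictly inside the year range.
#' @param transform `"identity"` or `"log"`; with `"log"` the series and
#'   predictors are log-transformed before standardization (appropriate
#'   for positive catch-rate indices) and back-transformation
#'   exponentiates.
#' @return Object of class `control_matrix`.
#' @export
control_matrix <- function(y, X, years, intervention_year,
                           transform = c("identity", "log")) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  if (length(y) != length(years) || nrow(X) != length(years)) {
    stop("y, X and years must share one year grid", call. = FALSE)
  }
  if (any(diff(years) != 1)) stop("years must be contiguous", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values are not imputed", call. = FALSE)
  k <- match(intervention_year, years)
  if (is.na(k) || k < 2 || k > length(years)) {
    stop("intervention year must lie strictly inside the series", call. = FALSE)
  }
  if (k > length(years)) stop("post-period is empty", call. = FALSE)
  n_pre <- k - 1
  if (n_pre < 3) stop("pre-period must span at least 3 years", call. = FALSE)
  y_raw <- y
  X_raw <- X
  if (transform == "log") {
    if (any(y <= 0) || any(X <= 0)) {
      stop("log transform requires strictly positive series", call. = FALSE)
    }
    y <- log(y)
    X <- log(X)
  }
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  if (any(x_sd == 0)) {
    stop("zero-variance predictor column(s): ",
         paste(colnames(X)[x_sd == 0], collapse = ", "), call. = FALSE)
  }
  y_mean <- mean(y[1:n_pre])
  y_sd <- sd(y[1:n_pre])
  if (y_sd == 0) y_sd <- 1 # constant pre-period series: center only
  structure(
    list(
      years = years,
      y = (y - y_mean) / y_sd,
      X = sweep(sweep(X, 2, x_mean), 2, x_sd, "/"),
      intervention_index = k,
      n_pre = n_pre,
      y_mean = y_mean, y_sd = y_sd,
      x_mean = x_mean, x_sd = x_sd,
      y_raw = y_raw, X_raw = X_raw,
      transform = transform
    ),
    class = "control_matrix"
  )
}

#' @export
print.control_matrix <- function(x, ...) {
  cat("<control_matrix>", length(x$years), "years (", x$n_pre, "pre +",
      length(x$years) - x$n_pre, "post ),", ncol(x$X), "predictors,",
      x$transform, "scale\n")
  invisible(x)
}

#' Back-transform a standardized series to the original scale
#'
#' @param cm A [control_matrix()].
#' @param y_std Values on the standardized scale.
#' @return Values on the original response scale.
#' @export
back_transform <- function(cm, y_std) {
  out <- y_std * cm$y_sd + cm$y_mean
  if (cm$transform == "log") out <- exp(out)
  out
}

#' Build a control matrix from stage-1 annual series
#'
#' Extracts the treatment-zone series for one metric from a stage-1 series
#' table (see [build_all_series()]), binds the three reference-zone series
#' and the annual covariates as predictor columns, and calls
#' [control_matrix()].
#'
#' @param series Tibble with columns `zone`, `metric`, `year`, `estimate`.
#' @param treatment_zone Zone label of the treated series.
#' @param metric Metric name shared by all series.
#' @param reference_zones Zone labels used as synthetic-control components.
#' @param covariates Annual covariate table (`year` plus covariate
#'   columns), or NULL for none.
#' @param intervention_year First post-intervention year.
#' @param transform Passed to [control_matrix()].
#' @return A `control_matrix`.
#' @export
build_control_matrix <- function(series, treatment_zone, metric,
                                 reference_zones = c("south", "northwest",
                                                     "northeast"),
                                 covariates = NULL,
                                 intervention_year = 2009,
                                 transform = c("identity", "log")) {
  sub <- series[series$metric == metric, ]
  tr <- sub[sub$zone == treatment_zone, ]
  tr <- tr[order(tr$year), ]
  if (nrow(tr) == 0) stop("no series for treatment zone ", treatment_zone,
                          call. = FALSE)
  years <- tr$year
  Xcols <- list()
  for (z in reference_zones) {
    rz <- sub[sub$zone == z, ]
    v <- rz$estimate[match(years, rz$year)]
    if (anyNA(v)) stop("reference zone ", z, " missing years", call. = FALSE)
    Xcols[[z]] <- v
  }
  if (!is.null(covariates)) {
    for (nm in setdiff(names(covariates), "year")) {
      v <- covariates[[nm]][match(years, covariates$year)]
      if (anyNA(v)) stop("covariate ", nm, " missing years", call. = FALSE)
      Xcols[[nm]] <- v
    }
  }
  X <- do.call(cbind, Xcols)
  transform <- match.arg(transform)
  if (transform == "log" && !is.null(covariates)) {
    # climate indices can be negative; only positive columns enter on the
    # log scale, others are left untouched by shifting them in afterwards
    X_ref <- X[, reference_zones, drop = FALSE]
    cm <- control_matrix(tr$estimate, X_ref, years, intervention_year, "log")
    extra <- X[, setdiff(colnames(X), reference_zones), drop = FALSE]
    if (ncol(extra)) {
      es <- apply(extra, 2, sd)
      if (any(es == 0)) {
        stop("zero-variance predictor column(s): ",
             paste(colnames(extra)[es == 0], collapse = ", "), call. = FALSE)
      }
      extra_std <- sweep(sweep(extra, 2, colMeans(extra)), 2, es, "/")
      cm$X <- cbind(cm$X, extra_std)
      cm$x_mean <- c(cm$x_mean, colMeans(extra))
      cm$x_sd <- c(cm$x_sd, es)
      cm$X_raw <- cbind(cm$X_raw, extra)
    }
    return(cm)
  }
  control_matrix(tr$estimate, X, years, intervention_year, transform)
}

# precompute per-model projection matrices for the spike-and-slab scan;
# models are indexed by bitmask over the p predictors
precompute_models <- function(X) {
  p <- ncol(X)
  n <- nrow(X)
  n_models <- 2^p
  M <- vector("list", n_models)
  chol_inv <- vector("list", n_models)
  idx <- vector("list", n_models)
  q <- integer(n_models)
  ok <- logical(n_models)
  for (m in seq_len(n_models)) {
    j <- which(bitwAnd(m - 1L, bitwShiftL(1L, 0:(p - 1))) > 0)
    idx[[m]] <- j
    q[m] <- length(j)
    if (q[m] == 0) {
      M[[m]] <- matrix(0, n, n)
      ok[m] <- TRUE
      next
    }
    Xg <- X[, j, drop = FALSE]
    XtX <- crossprod(Xg)
    inv <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(inv)) {
      ok[m] <- FALSE
      next
    }
    M[[m]] <- Xg %*% inv %*% t(Xg)
    chol_inv[[m]] <- chol(inv)
    ok[m] <- TRUE
  }
  list(M = M, chol_inv = chol_inv, idx = idx, q = q, ok = ok, p = p)
}

#' Fit the Bayesian structural time-series counterfactual model
#'
#' Gibbs sampler for a local-level state-space model with a spike-and-slab
#' synthetic-control regression, fitted to the pre-intervention period of
#' a [control_matrix()]:
#' `y_t = mu_t + x_t' beta + eps_t`, `mu_{t+1} = mu_t + eta_t`.
#' Each sweep alternates (i) forward-filter backward-sampling of the level
#' path, (ii) a stochastic-search Gibbs scan over the inclusion indicators
#' with a Zellner g-prior slab (g = pre-period length), (iii) a draw of the
#' included coefficients, and (iv) inverse-gamma draws of the observation
#' and level variances. Counterfactual draws are posterior-predictive
#' trajectories of `y` over the post period given the post-period
#' predictors.
#'
#' Priors are weakly informative and regularizing: inverse-gamma variance
#' priors with prior sample size `prior_ss` (default 0.01) and guesses
#' `prior_level_sd` (default 0.01, a tight level prior on the standardized
#' scale — the convention for this model family, which pushes explanatory
#' work onto the regression) and `prior_obs_sd` (default 0.5); prior
#' inclusion probability 0.5 per predictor.
#'
#' The slab is a Zellner-style g-prior whose precision is worth
#' `prior_information_weight` observations (default 0.01, i.e.
#' `g = n / 0.01`): a deliberately diffuse slab whose implied Occam factor
#' `(1 + g)^{-1/2}` per included predictor is what makes the stochastic
#' search favor a minimal or sparse synthetic control.
#'
#' @param cm A [control_matrix()].
#' @param n_draws Retained posterior draws (>= 1000; default 50000 for
#'   reporting, reduced in test settings).
#' @param burn_in Discarded warm-up sweeps (default `n_draws / 10`).
#' @param prior_level_sd,prior_obs_sd,prior_ss Prior settings, see above.
#' @param prior_inclusion Prior inclusion probability per predictor.
#' @param prior_information_weight Observations worth of prior precision in
#'   the slab (sets `g`).
#' @param seed Integer seed; fits are reproducible given the seed.
#' @return Object of class `bsts_fit`: draws of `beta`, `gamma`,
#'   `sigma_eps2`, `sigma_eta2`, the level path, counterfactual draws
#'   (standardized scale), inclusion probabilities, and settings.
#' @export
fit_bsts <- function(cm, n_draws = 50000, burn_in = ceiling(n_draws / 10),
                     prior_level_sd = 0.01, prior_obs_sd = 0.5,
                     prior_ss = 0.01, prior_inclusion = 0.5,
                     prior_information_weight = 0.01, seed = 1L) {
  stopifnot(inherits(cm, "control_matrix"))
  if (n_draws < 1000) stop("need at least 1000 draws", call. = FALSE)
  withr::local_seed(seed)

  n <- cm$n_pre
  y <- cm$y[1:n]
  X <- cm$X[1:n, , drop = FALSE]
  p <- ncol(X)
  n_post <- length(cm$years) - n
  X_post <- cm$X[(n + 1):length(cm$years), , drop = FALSE]

  g <- n / prior_information_weight
  a_eta <- prior_ss / 2
  b_eta <- prior_ss * prior_level_sd^2 / 2
  a_eps <- prior_ss / 2
  b_eps <- prior_ss * prior_obs_sd^2 / 2
  log_prior_odds <- log(prior_inclusion / (1 - prior_inclusion))
  shrink <- g / (1 + g)

  if (p > 12) stop("at most 12 predictors are supported", call. = FALSE)
  if (p > 0 && qr(X)$rank < p) {
    stop("collinear predictor columns in the pre-period", call. = FALSE)
  }
  pm <- if (p > 0) precompute_models(X) else NULL
  gamma <- rep(FALSE, p)
  beta <- rep(0, p)
  sigma_eps2 <- prior_obs_sd^2
  sigma_eta2 <- prior_level_sd^2
  mu <- y

  total <- burn_in + n_draws
  keep_beta <- matrix(0, n_draws, max(p, 1))
  keep_gamma <- matrix(FALSE, n_draws, max(p, 1))
  keep_se <- numeric(n_draws)
  keep_sl <- numeric(n_draws)
  keep_mu <- matrix(0, n_draws, n)

  m_f <- numeric(n)
  C_f <- numeric(n)

  zPz <- function(mask, z) {
    if (pm$q[mask] == 0) return(0)
    sum(z * (pm$M[[mask]] %*% z))
  }

  for (it in seq_len(total)) {
    # (i) FFBS for the level path on the regression residual
    r <- if (p > 0) y - as.vector(X %*% beta) else y
    m_f[1] <- r[1]
    C_f[1] <- sigma_eps2
    for (t in 2:n) {
      R <- C_f[t - 1] + sigma_eta2
      F_ <- R + sigma_eps2
      K <- R / F_
      m_f[t] <- m_f[t - 1] + K * (r[t] - m_f[t - 1])
      C_f[t] <- R * (1 - K)
    }
    mu[n] <- rnorm(1, m_f[n], sqrt(C_f[n]))
    for (t in (n - 1):1) {
      A <- C_f[t] / (C_f[t] + sigma_eta2)
      mu[t] <- rnorm(1, m_f[t] + A * (mu[t + 1] - m_f[t]),
                     sqrt(C_f[t] * (1 - A)))
    }
    if (!all(is.finite(mu))) {
      stop("sampler divergence (non-finite state) at iteration ", it,
           call. = FALSE)
    }

    z <- y - mu
    if (p > 0) {
      # (ii) stochastic-search scan over inclusion indicators, with both
      # the coefficients and the observation variance integrated out
      # (conjugate normal-inverse-gamma marginal): log p(z | gamma) =
      # -q/2 log(1+g) - (a + n/2) log(b + S_gamma/2) + const,
      # S_gamma = z'z - g/(1+g) z'P_gamma z
      zz <- sum(z * z)
      log_marg <- function(mask) {
        -0.5 * pm$q[mask] * log(1 + g) -
          (a_eps + n / 2) * log(b_eps + (zz - shrink * zPz(mask, z)) / 2)
      }
      mask <- 1L + sum(bitwShiftL(1L, which(gamma) - 1L))
      for (j in seq_len(p)) {
        bit <- bitwShiftL(1L, j - 1L)
        m0 <- 1L + bitwAnd(mask - 1L, bitwNot(bit))
        m1 <- m0 + bit
        if (!pm$ok[m1]) { gamma[j] <- FALSE; mask <- m0; next }
        d <- log_marg(m1) - log_marg(m0) + log_prior_odds
        gamma[j] <- runif(1) < 1 / (1 + exp(-d))
        mask <- if (gamma[j]) m1 else m0
      }
      # (iii) observation variance given the model, then coefficients
      q <- pm$q[mask]
      S_gamma <- zz - shrink * zPz(mask, z)
      sigma_eps2 <- 1 / rgamma(1, a_eps + n / 2, b_eps + S_gamma / 2)
      beta[] <- 0
      if (q > 0) {
        jdx <- pm$idx[[mask]]
        Xg <- X[, jdx, drop = FALSE]
        U <- pm$chol_inv[[mask]] # upper triangular, t(U) %*% U = (X'X)^-1
        bhat <- t(U) %*% (U %*% crossprod(Xg, z))
        mean_b <- shrink * as.vector(bhat)
        beta[jdx] <- mean_b +
          sqrt(sigma_eps2 * shrink) * as.vector(t(U) %*% rnorm(q))
      }
    } else {
      sigma_eps2 <- 1 / rgamma(1, a_eps + n / 2, b_eps + sum(z^2) / 2)
    }
    dmu <- diff(mu)
    sigma_eta2 <- 1 / rgamma(1, a_eta + (n - 1) / 2, b_eta + sum(dmu^2) / 2)

    if (it > burn_in) {
      k <- it - burn_in
      if (p > 0) {
        keep_beta[k, ] <- beta
        keep_gamma[k, ] <- gamma
      }
      keep_se[k] <- sigma_eps2
      keep_sl[k] <- sigma_eta2
      keep_mu[k, ] <- mu
    }
  }

  # posterior-predictive counterfactual over the post period (standardized)
  cf <- NULL
  if (n_post > 0) {
    cf <- matrix(0, n_draws, n_post)
    level <- keep_mu[, n]
    se <- sqrt(keep_se)
    sl <- sqrt(keep_sl)
    reg <- if (p > 0) keep_beta %*% t(X_post) else matrix(0, n_draws, n_post)
    for (h in seq_len(n_post)) {
      level <- level + rnorm(n_draws) * sl
      cf[, h] <- level + reg[, h] + rnorm(n_draws) * se
    }
  }

  structure(
    list(
      cm = cm,
      beta = keep_beta, gamma = keep_gamma,
      sigma_eps2 = keep_se, sigma_eta2 = keep_sl,
      level = keep_mu,
      counterfactual = cf,
      inclusion_probs = if (p > 0)
        setNames(colMeans(keep_gamma), colnames(X)) else numeric(0),
      n_draws = n_draws, burn_in = burn_in, seed = seed,
      prior = list(level_sd = prior_level_sd, obs_sd = prior_obs_sd,
                   ss = prior_ss, inclusion = prior_inclusion,
                   information_weight = prior_information_weight, g = g)
    ),
    class = "bsts_fit"
  )
}

#' @export
print.bsts_fit <- function(x, ...) {
  cat("<bsts_fit>", x$n_draws, "draws (burn-in", x$burn_in, "), seed",
      x$seed, "\n")
  if (length(x$inclusion_probs)) {
    cat("  inclusion probabilities:\n")
    print(round(x$inclusion_probs, 3))
  }
  invisible(x)
}

#' Summarize the causal impact of the intervention
#'
#' Compares the observed post-period series with the posterior-predictive
#' counterfactual draws on the original response scale. Reports pointwise
#' effects per post year, the cumulative effect, the relative effect
#' (`sum(actual) / sum(counterfactual) - 1`, in percent), the causal
#' effect probability (the larger of the posterior shares of positive and
#' negative cumulative effects, capped at `1 - 1/n_draws`), and predictor
#' inclusion probabilities. Draws whose counterfactual sum is not positive
#' are excluded from the relative-effect distribution; more than 5%
#' exclusions is an error.
#'
#' @param fit A [fit_bsts()] object.
#' @param actual Observed post-period values on the original scale;
#'   defaults to the post-period of the series in the control matrix.
#' @return Object of class `causal_impact_summary`.
#' @export
summarize_impact <- function(fit, actual = NULL) {
  cm <- fit$cm
  n <- cm$n_pre
  n_post <- length(cm$years) - n
  if (n_post < 1) stop("no post period to summarize", call. = FALSE)
  if (is.null(actual)) actual <- cm$y_raw[(n + 1):length(cm$years)]
  if (length(actual) != n_post) {
    stop("actual series not aligned with the post period", call. = FALSE)
  }
  cf <- back_transform(cm, fit$counterfactual) # n_draws x n_post
  cf <- matrix(cf, ncol = n_post)
  eff <- sweep(-cf, 2, actual, "+") # actual - counterfactual per draw
  cum <- rowSums(eff)
  cf_sum <- rowSums(cf)
  ok <- cf_sum > 0
  excluded <- sum(!ok)
  if (excluded > 0.05 * length(cf_sum)) {
    stop("more than 5% of counterfactual draws have non-positive sums (",
         excluded, " of ", length(cf_sum), ")", call. = FALSE)
  }
  rel <- (sum(actual) / cf_sum[ok] - 1) * 100
  q <- function(v) unname(quantile(v, c(0.025, 0.975), type = 7))
  point <- tibble::tibble(
    year = cm$years[(n + 1):length(cm$years)],
    actual = actual,
    counterfactual = colMeans(cf),
    cf_lo95 = apply(cf, 2, function(v) q(v)[1]),
    cf_hi95 = apply(cf, 2, function(v) q(v)[2]),
    effect = colMeans(eff),
    effect_lo95 = apply(eff, 2, function(v) q(v)[1]),
    effect_hi95 = apply(eff, 2, function(v) q(v)[2])
  )
  p_pos <- mean(cum > 0)
  prob <- max(p_pos, 1 - p_pos)
  prob <- min(prob, 1 - 1 / length(cum))
  structure(
    list(
      pointwise = point,
      cumulative = c(mean = mean(cum), lo95 = q(cum)[1], hi95 = q(cum)[2]),
      relative_pct = c(mean = mean(rel), lo95 = q(rel)[1], hi95 = q(rel)[2]),
      causal_effect_probability = prob,
      tail_probability = 1 - prob,
      inclusion_probs = fit$inclusion_probs,
      n_draws = length(cum),
      excluded_draws = excluded
    ),
    class = "causal_impact_summary"
  )
}

#' @export
print.causal_impact_summary <- function(x, ...) {
  pr <- x$causal_effect_probability
  cat("Causal impact summary (", nrow(x$pointwise), "post years )\n")
  cat(sprintf("  causal effect probability: %s\n",
              if (pr > 0.99) "> 0.99" else sprintf("%.3f", pr)))
  cat(sprintf("  relative effect: %.1f%% (95%% CrI %.1f%%, %.1f%%)\n",
              x$relative_pct["mean"], x$relative_pct["lo95"],
              x$relative_pct["hi95"]))
  if (length(x$inclusion_probs)) {
    imp <- sort(x$inclusion_probs, decreasing = TRUE)
    cat("  top predictors:",
        paste(sprintf("%s (%.0f%%)", names(imp)[1:min(3, length(imp))],
                      100 * imp[1:min(3, length(imp))]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Classify an impact summary as significant or not
#'
#' A causal effect is called significant when the causal effect
#' probability reaches the threshold (default 0.95, i.e. a one-sided
#' tail-area probability of at most 0.05; a summary with tail probability
#' above the threshold's complement — e.g. a Bayesian predictive p greater
#' than 0.05 — is not significant). The boundary value counts as
#' significant.
#'
#' @param summary A [summarize_impact()] object.
#' @param threshold Probability threshold (default 0.95).
#' @return List with `significant`, `causal_effect_probability`,
#'   `tail_probability` and `threshold`.
#' @export
classify_significance <- function(summary, threshold = 0.95) {
  stopifnot(inherits(summary, "causal_impact_summary"))
  pr <- summary$causal_effect_probability
  list(
    significant = pr >= threshold,
    causal_effect_probability = pr,
    tail_probability = 1 - pr,
    threshold = threshold
  )
}
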