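test_that("control matrix indexes, standardizes and round-trips", {
  years <- 1997:2016
  set.seed(1)
  y <- 10 + rnorm(20)
  X <- cbind(a = rnorm(20, 5), b = rnorm(20, 2))
  cm <- control_matrix(y, X, years, intervention_year = 2009)
  expect_equal(cm$n_pre, 12)
  expect_equal(length(cm$years) - cm$n_pre, 8)
  expect_equal(colMeans(cm$X), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(cm$X, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # round trip to the original scale
  expect_equal(back_transform(cm, cm$y), y, tolerance = 1e-12)
  cml <- control_matrix(y, X, years, 2009, transform = "log")
  expect_equal(back_transform(cml, cml$y), y, tolerance = 1e-12)
  # contracts
  expect_error(control_matrix(y, cbind(a = rep(1, 20)), years, 2009),
               "zero-variance")
  expect_error(control_matrix(c(y[-1], NA), X, years, 2009), "missing")
  expect_error(control_matrix(y, X, years, 1997), "strictly inside")
  expect_error(control_matrix(y, X, years, 1999), "at least 3")
})

test_that("Kalman log-likelihood matches the dense-Gaussian oracle", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    y <- rnorm(n, 0, 3)
    se2 <- runif(1, 0.05, 3)
    sl2 <- runif(1, 0.01, 2)
    expect_equal(kalman_loglik(y, se2, sl2),
                 dense_local_level_ll(y, se2, sl2), tolerance = 1e-9)
  }
  # base cases and diffuse shift invariance
  expect_equal(kalman_loglik(5, 1, 1), 0)
  y2 <- c(1.3, 2.9)
  expect_equal(kalman_loglik(y2, 0.4, 0.3),
               dnorm(diff(y2), 0, sqrt(0.3 + 2 * 0.4), log = TRUE))
  y <- rnorm(10)
  expect_equal(kalman_loglik(y + 1234, 0.5, 0.2),
               kalman_loglik(y, 0.5, 0.2), tolerance = 1e-9)
  # regression-residual mode
  X <- cbind(rnorm(10))
  expect_equal(kalman_loglik(y + 2 * X[, 1], 0.5, 0.2, X = X, beta = 2),
               kalman_loglik(y, 0.5, 0.2))
  expect_error(kalman_loglik(c(1, NA), 1, 1), "non-finite")
  expect_error(kalman_loglik(y, -1, 1), "variances")
})

test_that("a constant series with no predictors yields a tight counterfactual", {
  years <- 2000:2015
  y <- rep(7, 16)
  cm <- control_matrix(y, matrix(numeric(0), nrow = 16, ncol = 0),
                       years, 2010)
  fit <- fit_bsts(cm, n_draws = 2000, burn_in = 200, seed = 4)
  expect_lt(max(apply(fit$counterfactual, 2, sd)), 0.1)
  # and the summary finds nothing
  s <- summarize_impact(fit)
  expect_lt(abs(s$relative_pct["mean"]), 5)
})

test_that("the sampler is reproducible under a fixed seed", {
  set.seed(10)
  y <- cumsum(rnorm(18, 0, 0.3)) + 10
  X <- cbind(c1 = y + rnorm(18, 0, 0.5), c2 = rnorm(18, 10))
  cm <- control_matrix(y, X, 1999:2016, 2011)
  f1 <- fit_bsts(cm, n_draws = 1000, burn_in = 100, seed = 77)
  f2 <- fit_bsts(cm, n_draws = 1000, burn_in = 100, seed = 77)
  expect_identical(f1$counterfactual, f2$counterfactual)
  expect_identical(f1$inclusion_probs, f2$inclusion_probs)
})

test_that("spike-and-slab selection favors the informative control", {
  hits <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 32 # 24 pre-period years, see the selection-consistency note
    x_true <- 10 + cumsum(rnorm(n, 0, 0.5))
    y <- x_true + rnorm(n, 0, sd(x_true) * 0.3)
    X <- cbind(ctrl = x_true, matrix(rnorm(n * 5, 10, 2), n, 5,
                                     dimnames = list(NULL, paste0("n", 1:5))))
    cm <- control_matrix(y, X, 1985:2016, 2009)
    fit <- fit_bsts(cm, n_draws = 1500, burn_in = 200, seed = r)
    ip <- fit$inclusion_probs
    if (ip["ctrl"] > 0.5 && all(ip[-1] < 0.5)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

# a hand-built posterior with known counterfactual draws, for arithmetic
# checks of the impact summary
fake_fit <- function(cf_draws, y, years, intervention_year) {
  cm <- control_matrix(y, matrix(numeric(0), nrow = length(y), ncol = 0),
                       years, intervention_year)
  structure(list(cm = cm,
                 counterfactual = (cf_draws - cm$y_mean) / cm$y_sd,
                 inclusion_probs = numeric(0)),
            class = "bsts_fit")
}

test_that("impact summary arithmetic matches the ratio definition", {
  years <- 2000:2011
  y <- c(rnorm(8, 100), rep(16, 4)) # post period observed at 16
  cf <- matrix(100, nrow = 4000, ncol = 4) # every draw predicts 100
  fit <- fake_fit(cf, y, years, 2008)
  s <- summarize_impact(fit)
  expect_equal(unname(s$relative_pct["mean"]), -84)
  expect_equal(s$pointwise$effect, rep(16 - 100, 4))
  # every cumulative draw is negative: probability hits the cap
  expect_equal(s$causal_effect_probability, 1 - 1 / 4000)
  # null case: actual equals the counterfactual center with symmetric draws
  y2 <- c(rnorm(8, 100), rep(100, 4))
  cf2 <- matrix(100 + rnorm(4000 * 4), 4000, 4)
  s2 <- summarize_impact(fake_fit(cf2, y2, years, 2008))
  expect_lt(abs(s2$causal_effect_probability - 0.5), 0.05)
  expect_true(s2$relative_pct["lo95"] < 0 && s2$relative_pct["hi95"] > 0)
  # non-positive counterfactual sums beyond 5% are an error
  cf3 <- matrix(100, 4000, 4)
  cf3[1:2000, ] <- -1
  expect_error(summarize_impact(fake_fit(cf3, y2, years, 2008)), "5%")
})

test_that("significance classification applies the threshold convention", {
  years <- 2000:2011
  y <- c(rnorm(8, 100), rep(16, 4))
  fit <- fake_fit(matrix(100, 4000, 4), y, years, 2008)
  s <- summarize_impact(fit)
  expect_true(classify_significance(s)$significant)
  mk <- function(prob) {
    s$causal_effect_probability <- prob
    s
  }
  expect_true(classify_significance(mk(0.99))$significant)
  expect_false(classify_significance(mk(0.90))$significant)
  expect_equal(classify_significance(mk(0.90))$tail_probability, 0.1)
  # boundary counts as significant; threshold is configurable
  expect_true(classify_significance(mk(0.95))$significant)
  expect_false(classify_significance(mk(0.95), threshold = 0.975)$significant)
})

test_that("plot data covers the whole series with flagged post period", {
  set.seed(20)
  y <- 10 + cumsum(rnorm(16, 0, 0.2))
  X <- cbind(a = y + rnorm(16, 0, 0.3))
  cm <- control_matrix(y, X, 2000:2015, 2010)
  fit <- fit_bsts(cm, n_draws = 1000, burn_in = 100, seed = 3)
  pd <- render_counterfactual_plot_data(fit)
  expect_equal(nrow(pd), 16)
  expect_equal(sum(pd$intervention_flag), 6)
  expect_false(any(pd$intervention_flag[1:10]))
  expect_true(all(pd$lo95 <= pd$hi95))
  p <- plot_counterfactual(pd)
  expect_s3_class(p, "ggplot")
})
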