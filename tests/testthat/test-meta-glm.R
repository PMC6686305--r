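desk <- chain_config("desk")

test_that("chain presets reproduce the retained-sample arithmetic", {
  expect_equal(retained_samples(chain_config("reference")), 1998L)
  expect_equal(retained_samples(chain_config("desk")), 2000L)
  expect_equal(retained_samples(chain_config("reference_long")), 19998L)
  expect_error(chain_config("custom"), "needs iterations")
  expect_error(chain_config(iterations = 10, burn_in = 20, thinning = 1),
               "burn_in")
})

test_that("the intercept-only posterior matches the analytic log-odds", {
  d <- tibble::tibble(y = c(rep(1, 7), rep(0, 3)))
  fit <- fit_bayes_binomial(d, "y", prior_scale = 1000, chain = desk,
                            seed = 71)
  expect_lt(abs(tidy(fit)$estimate[1] - log(7 / 3)), 0.15)
})

test_that("posterior means track maximum likelihood under a near-flat prior", {
  set.seed(72)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 1.1 * x))
  d <- tibble::tibble(y = y, x = x)
  fit <- fit_bayes_binomial(d, "y", "x", prior_scale = 1000, chain = desk,
                            seed = 73)
  ml <- stats::glm(y ~ scale(x), family = binomial, data = d)
  expect_lt(max(abs(tidy(fit)$estimate - unname(coef(ml)))), 0.1)
})

test_that("complete separation stays finite under the Cauchy(0, 25) prior", {
  d <- tibble::tibble(x = 1:20, y = as.integer(1:20 > 10))
  fit <- fit_bayes_binomial(d, "y", "x", prior_scale = 25, chain = desk,
                            seed = 74)
  td <- tidy(fit)
  expect_true(all(is.finite(td$estimate)))
  expect_true(all(is.finite(c(td$conf.low, td$conf.high))))
  # the HPD is a genuine interval, not collapsed at the boundary
  expect_gt(td$conf.high[2], td$conf.low[2])
})

test_that("multinomial fits keep probabilities on the simplex and recover frequencies", {
  set.seed(75)
  d <- generate_outcome_table(300, seed = 76)
  fit0 <- fit_bayes_multinomial(d, "outcome", chain = desk, seed = 77)
  pr <- fitted_probs(fit0)
  expect_equal(sum(pr$probability), 1, tolerance = 1e-9)
  emp <- table(d$outcome) / nrow(d)
  for (cat in names(emp)) {
    expect_equal(pr$probability[pr$category == cat], unname(emp[[cat]]),
                 tolerance = 3 * sqrt(emp[[cat]] * (1 - emp[[cat]]) / 300) +
                   0.01)
  }
})

test_that("a real multinomial slope is detected at n = 300", {
  d <- generate_outcome_table(
    300, slopes = c(aggregation = 1.2, segregation = 0), seed = 78)
  fit <- fit_bayes_multinomial(d, "outcome", "plot_size_ha", chain = desk,
                               seed = 79)
  td <- tidy(fit)
  agg_slope <- td[td$term == "aggregation:plot_size_ha", ]
  expect_true(agg_slope$significant)
  expect_gt(agg_slope$conf.low, 0)
  # probabilities sum to one across a predictor grid
  pr <- fitted_probs(fit, at = c(10, 50, 120))
  sums <- tapply(pr$probability, pr$at, sum)
  expect_equal(as.vector(sums), rep(1, 3), tolerance = 1e-9)
})

test_that("the GLMM recovers random-intercept structure", {
  set.seed(80)
  G <- 19; n_per <- 24
  g <- rep(seq_len(G), each = n_per)
  u <- rnorm(G, 0, 1)
  x <- rnorm(G * n_per)
  y <- rbinom(G * n_per, 1, plogis(0.3 + 0.8 * x + u[g]))
  d <- tibble::tibble(y = y, x = x, grp = paste0("g", g))
  fit <- fit_bayes_glmm(d, "y", "x", group = "grp", chain = desk, seed = 81)
  sig <- fit$samples[, "sigma_group"]
  expect_gt(stats::median(sig), 0.5)
  expect_lt(stats::median(sig), 1.6)
  # zero-variance truth: posterior SD concentrates near zero
  y0 <- rbinom(G * n_per, 1, plogis(0.3 + 0.8 * x))
  d0 <- tibble::tibble(y = y0, x = x, grp = paste0("g", g))
  fit0 <- fit_bayes_glmm(d0, "y", "x", group = "grp", chain = desk,
                         seed = 82)
  expect_lt(stats::median(fit0$samples[, "sigma_group"]),
            stats::median(sig))
  expect_lt(stats::quantile(fit0$samples[, "sigma_group"], 0.5), 0.5)
})

test_that("with the variance pinned at zero the GLMM reduces to the GLM", {
  set.seed(83)
  d <- tibble::tibble(y = rbinom(120, 1, 0.4), x = rnorm(120),
                      grp = rep(c("a", "b", "c"), 40))
  fit_mm <- fit_bayes_glmm(d, "y", "x", group = "grp",
                           estimate_sigma = FALSE, chain = desk, seed = 84)
  fit_glm <- fit_bayes_binomial(d, "y", "x", chain = desk, seed = 84)
  expect_true(all(fit_mm$samples[, "sigma_group"] == 0))
  expect_lt(max(abs(tidy(fit_mm)$estimate[1:2] - tidy(fit_glm)$estimate)),
            0.1)
})

test_that("DIC behaves: zero against itself, positive pD, informative predictors win", {
  set.seed(85)
  x <- rnorm(250)
  y <- rbinom(250, 1, plogis(1.6 * x))
  d <- tibble::tibble(y = y, x = x)
  fit <- fit_bayes_binomial(d, "y", "x", chain = desk, seed = 86)
  fit0 <- fit_bayes_binomial(d, "y", chain = desk, seed = 87)
  expect_equal(delta_dic(fit, fit), 0)
  expect_gt(fit$p_d, 0)
  expect_gt(delta_dic(fit, fit0), 10)
  expect_true(glance(fit)$significant)
})

test_that("chain diagnostics flag autocorrelated parameters only", {
  set.seed(88)
  good <- structure(list(samples = cbind(theta = rnorm(2000))),
                    class = "bayes_glm_fit")
  expect_silent(out <- chain_diagnostics(good))
  expect_false(out$flagged)
  ar <- as.vector(stats::arima.sim(list(ar = 0.9), 2000))
  bad <- structure(list(samples = cbind(theta = ar)),
                   class = "bayes_glm_fit")
  expect_warning(out2 <- chain_diagnostics(bad), "lengthen the chain")
  expect_true(out2$flagged)
})

test_that("fits are reproducible bit-exactly given seed and chain config", {
  d <- tibble::tibble(y = rbinom(50, 1, 0.5), x = rnorm(50))
  f1 <- fit_bayes_binomial(d, "y", "x", chain = desk, seed = 90)
  f2 <- fit_bayes_binomial(d, "y", "x", chain = desk, seed = 90)
  expect_identical(f1$samples, f2$samples)
})
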