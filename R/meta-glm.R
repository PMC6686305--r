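#' MCMC chain configuration
#'
#' Presets: `"desk"` (200,000 iterations, 10,000 burn-in, thinning 95; 2,000
#' retained samples) keeps a single fit in the sub-second range and is the
#' default for interactive work and tests. `"reference"` mirrors the
#' long-chain protocol used with off-the-shelf Gibbs samplers for this kind
#' of meta-analysis: 10 million iterations, 10,000 burn-in, every 5,000th
#' sample kept, giving (10,000,000 - 10,000) / 5,000 = 1,998 retained
#' samples; `"reference_long"` stretches the chain to 100 million iterations
#' for poorly mixing fits.
#'
#' @param preset One of `"desk"`, `"reference"`, `"reference_long"`, or
#'   `"custom"` (then supply all three numbers).
#' @param iterations,burn_in,thinning Override the preset's values.
#' @return A `chain_config` list with `iterations`, `burn_in`, `thinning`.
#' @export
chain_config <- function(preset = c("desk", "reference", "reference_long",
                                    "custom"),
                         iterations = NULL, burn_in = NULL, thinning = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    desk = list(iterations = 2e5, burn_in = 1e4, thinning = 95),
    reference = list(iterations = 1e7, burn_in = 1e4, thinning = 5e3),
    reference_long = list(iterations = 1e8, burn_in = 1e4, thinning = 5e3),
    custom = list(iterations = NA, burn_in = NA, thinning = NA)
  )
  cfg$iterations <- iterations %||% cfg$iterations
  cfg$burn_in <- burn_in %||% cfg$burn_in
  cfg$thinning <- thinning %||% cfg$thinning
  if (anyNA(cfg[c("iterations", "burn_in", "thinning")])) {
    abort("custom chain_config needs iterations, burn_in, and thinning")
  }
  if (cfg$burn_in >= cfg$iterations) abort("burn_in must be < iterations")
  structure(c(cfg, list(preset = preset)), class = "chain_config")
}

#' @rdname chain_config
#' @param config A `chain_config`.
#' @return `retained_samples()`: the number of posterior samples the chain
#'   keeps, `floor((iterations - burn_in) / thinning)`.
#' @export
retained_samples <- function(config) {
  as.integer((config$iterations - config$burn_in) %/% config$thinning)
}

# ---- internal helpers ------------------------------------------------------

#' Highest posterior density interval
#'
#' Shortest interval containing `prob` of the sampled posterior mass.
#'
#' @param x Numeric vector of posterior samples.
#' @param prob Target coverage.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

lag1_autocorr <- function(x) {
  if (length(x) < 3 || sd(x) == 0) return(0)
  stats::cor(x[-1], x[-length(x)])
}

# response column -> 0/1 integer vector
code_binary_response <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("numeric response must be 0/1")
    return(as.integer(y))
  }
  f <- as.factor(y)
  if (nlevels(f) != 2) abort("response must be dichotomous")
  as.integer(f) - 1L
}

# predictor -> design matrix (intercept + standardized predictor or dummies)
build_design <- function(data, predictor) {
  if (is.null(predictor)) {
    return(list(X = matrix(1, nrow(data), 1,
                           dimnames = list(NULL, "(Intercept)")),
                center = NA_real_, scale = NA_real_, is_factor = FALSE,
                name = NULL))
  }
  x <- data[[predictor]]
  if (is.null(x)) abort(sprintf("no column '%s' in data", predictor))
  if (is.numeric(x)) {
    ctr <- mean(x)
    scl <- sd(x)
    if (scl == 0) abort(sprintf("predictor '%s' is constant", predictor))
    X <- cbind(`(Intercept)` = 1, (x - ctr) / scl)
    colnames(X)[2] <- predictor
    list(X = X, center = ctr, scale = scl, is_factor = FALSE,
         name = predictor)
  } else {
    f <- as.factor(x)
    X <- stats::model.matrix(~f)
    colnames(X) <- c("(Intercept)", paste0(predictor, levels(f)[-1]))
    list(X = X, center = NA_real_, scale = NA_real_, is_factor = TRUE,
         name = predictor, levels = levels(f))
  }
}

loglik_logit_r <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

loglik_multilogit_r <- function(beta1, beta2, y, X) {
  e1 <- drop(X %*% beta1)
  e2 <- drop(X %*% beta2)
  m <- pmax(0, e1, e2)
  lse <- m + log(exp(-m) + exp(e1 - m) + exp(e2 - m))
  num <- ifelse(y == 1, e1, ifelse(y == 2, e2, 0))
  sum(num - lse)
}

check_acceptance <- function(rates) {
  bad <- rates[!is.na(rates) & (rates < 0.1 | rates > 0.6)]
  if (length(bad)) {
    warn(sprintf(
      "MCMC acceptance rate outside [0.1, 0.6] for %d parameter(s) despite burn-in tuning; inspect chain_diagnostics()",
      length(bad)))
  }
}

new_glm_fit <- function(samples, deviance, accept_rate, family, design,
                        prior_scale, chain, dev_at_mean, extra = list()) {
  mean_dev <- mean(deviance)
  p_d <- mean_dev - dev_at_mean
  fit <- c(list(
    samples = samples, deviance = deviance, accept_rate = accept_rate,
    family = family, design = design, prior_scale = prior_scale,
    chain = chain, mean_deviance = mean_dev, p_d = p_d,
    dic = mean_dev + p_d
  ), extra)
  class(fit) <- "bayes_glm_fit"
  fit
}

# ---- fitting ---------------------------------------------------------------

#' Bayesian binomial GLM with Cauchy priors
#'
#' Logistic regression of a dichotomous null-model outcome on a single
#' data-set characteristic, fitted by adaptive random-walk Metropolis under
#' independent Cauchy(0, `prior_scale`) priors on the coefficients. The
#' weakly informative Cauchy prior keeps estimates finite under (quasi)
#' complete separation, where maximum likelihood diverges. Numeric
#' predictors are z-standardized internally; [tidy.bayes_glm_fit()] reports
#' both scales.
#'
#' @param data A data frame of outcome records.
#' @param response Column name (string) holding a logical, 0/1, or two-level
#'   factor response (for a factor, the second level is the success).
#' @param predictor Column name of the single predictor (numeric or factor),
#'   or `NULL` for the intercept-only (null) model.
#' @param prior_scale Cauchy scale of the coefficient priors (default 25).
#' @param chain A [chain_config()].
#' @param seed Optional integer seed.
#' @return A `bayes_glm_fit`: posterior samples, deviance trace, DIC
#'   ingredients, 95% HPD intervals, and a significance flag (some
#'   non-intercept HPD excludes zero). See [tidy.bayes_glm_fit()],
#'   [glance.bayes_glm_fit()], [chain_diagnostics()].
#' @export
fit_bayes_binomial <- function(data, response, predictor = NULL,
                               prior_scale = 25, chain = chain_config(),
                               seed = NULL) {
  y <- code_binary_response(data[[response]])
  des <- build_design(data, predictor)
  if (retained_samples(chain) < 1000) {
    warn("fewer than 1,000 retained samples; consider a longer chain")
  }
  run <- function() cpp_mh_logit(y, des$X, prior_scale, chain$iterations,
                                 chain$burn_in, chain$thinning)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(res$samples) <- colnames(des$X)
  if (any(!is.finite(res$samples))) abort("non-finite posterior samples")
  check_acceptance(res$accept_rate)
  bmean <- colMeans(res$samples)
  new_glm_fit(res$samples, res$deviance, res$accept_rate, "binomial", des,
              prior_scale, chain,
              dev_at_mean = -2 * loglik_logit_r(bmean, y, des$X),
              extra = list(y = y, n = length(y)))
}

#' Bayesian multinomial (baseline-category) GLM
#'
#' Trichotomous outcomes (aggregation / segregation against the `baseline`
#' category, by default `"random"`) modelled with two baseline-category
#' logits sharing the predictor; same priors and sampler as
#' [fit_bayes_binomial()].
#'
#' @inheritParams fit_bayes_binomial
#' @param baseline Reference outcome category.
#' @return A `bayes_glm_fit` with per-category coefficient samples (terms
#'   are prefixed by the non-baseline category they describe).
#' @export
fit_bayes_multinomial <- function(data, response, predictor = NULL,
                                  baseline = "random", prior_scale = 25,
                                  chain = chain_config(), seed = NULL) {
  f <- as.factor(data[[response]])
  if (nlevels(f) != 3) abort("response must have exactly 3 categories")
  if (!baseline %in% levels(f)) abort("baseline category not present")
  lev <- c(baseline, setdiff(levels(f), baseline))
  y <- as.integer(factor(f, levels = lev)) - 1L
  des <- build_design(data, predictor)
  if (retained_samples(chain) < 1000) {
    warn("fewer than 1,000 retained samples; consider a longer chain")
  }
  run <- function() cpp_mh_multilogit(y, des$X, prior_scale,
                                      chain$iterations, chain$burn_in,
                                      chain$thinning)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- ncol(des$X)
  colnames(res$samples) <- c(paste(lev[2], colnames(des$X), sep = ":"),
                             paste(lev[3], colnames(des$X), sep = ":"))
  if (any(!is.finite(res$samples))) abort("non-finite posterior samples")
  check_acceptance(res$accept_rate)
  bmean <- colMeans(res$samples)
  new_glm_fit(res$samples, res$deviance, res$accept_rate, "multinomial", des,
              prior_scale, chain,
              dev_at_mean = -2 * loglik_multilogit_r(bmean[1:p],
                                                     bmean[(p + 1):(2 * p)],
                                                     y, des$X),
              extra = list(y = y, n = length(y), categories = lev))
}

#' Bayesian binomial GLMM with a dataset random intercept
#'
#' As [fit_bayes_binomial()] plus a Gaussian random intercept per grouping
#' unit (individual data matrices in the guild-level meta-analysis), with a
#' half-Cauchy(`sigma_scale`) prior on the random-effect standard deviation.
#' The reported deviance and DIC condition on the sampled random effects.
#'
#' @inheritParams fit_bayes_binomial
#' @param group Column name of the grouping factor (e.g. `"dataset_id"`).
#' @param sigma_scale Half-Cauchy scale for the random-intercept SD.
#' @param estimate_sigma If `FALSE`, pins the random-effect variance at zero
#'   (the fit then reduces exactly to the fixed-effects model).
#' @return A `bayes_glm_fit`; random-intercept samples appear as `u.<group>`
#'   terms and the SD as `sigma_group`.
#' @export
fit_bayes_glmm <- function(data, response, predictor = NULL, group,
                           prior_scale = 25, sigma_scale = 25,
                           estimate_sigma = TRUE, chain = chain_config(),
                           seed = NULL) {
  y <- code_binary_response(data[[response]])
  des <- build_design(data, predictor)
  g <- as.factor(data[[group]])
  gi <- as.integer(g) - 1L
  G <- nlevels(g)
  if (retained_samples(chain) < 1000) {
    warn("fewer than 1,000 retained samples; consider a longer chain")
  }
  run <- function() cpp_mh_logit_mm(y, des$X, gi, G, prior_scale,
                                    sigma_scale, chain$iterations,
                                    chain$burn_in, chain$thinning,
                                    estimate_sigma)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(res$samples) <- c(colnames(des$X), paste0("u.", levels(g)),
                             "sigma_group")
  if (any(!is.finite(res$samples))) abort("non-finite posterior samples")
  check_acceptance(res$accept_rate)
  p <- ncol(des$X)
  bmean <- colMeans(res$samples)
  eta_mean <- drop(des$X %*% bmean[1:p]) + bmean[p + gi + 1]
  dev_mean <- -2 * sum(y * eta_mean - log1p(exp(eta_mean)))
  new_glm_fit(res$samples, res$deviance, res$accept_rate, "binomial_mixed",
              des, prior_scale, chain, dev_at_mean = dev_mean,
              extra = list(y = y, n = length(y), group = group,
                           group_levels = levels(g),
                           sigma_scale = sigma_scale,
                           estimate_sigma = estimate_sigma))
}

# fixed-effect (non-intercept, non-random) terms of a fit
fixed_terms <- function(fit) {
  terms <- colnames(fit$samples)
  terms <- terms[!grepl("^u\\.", terms) & terms != "sigma_group"]
  terms[!grepl("\\(Intercept\\)$", terms)]
}

#' Deviance information criterion
#'
#' `dic()` returns \eqn{DIC = \bar{D} + p_D} with
#' \eqn{p_D = \bar{D} - D(\bar{\theta})} (posterior-mean plug-in).
#' `delta_dic()` compares a model against its intercept-only null model on
#' the improvement scale: `dic(null_fit) - dic(fit)`, so positive values mean
#' the predictor improves on the null model.
#'
#' @param fit,null_fit `bayes_glm_fit` objects (the null fit is the
#'   intercept-only model for the same response).
#' @return A single number.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bayes_glm_fit"))
  fit$dic
}

#' @rdname dic
#' @export
delta_dic <- function(fit, null_fit) {
  dic(null_fit) - dic(fit)
}

#' Chain mixing diagnostics
#'
#' Lag-1 autocorrelation of every retained parameter chain; parameters at or
#' above |0.05| are flagged with advice to lengthen the chain (e.g. the
#' `"reference_long"` preset).
#'
#' @param fit A `bayes_glm_fit`.
#' @return A tibble with `parameter`, `mean`, `lag1_autocorr`, `flagged`.
#' @export
chain_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "bayes_glm_fit"))
  ac <- apply(fit$samples, 2, lag1_autocorr)
  out <- tibble::tibble(
    parameter = colnames(fit$samples),
    mean = colMeans(fit$samples),
    lag1_autocorr = unname(ac),
    flagged = abs(unname(ac)) >= 0.05
  )
  if (any(out$flagged)) {
    warn(paste0(
      "autocorrelation >= 0.05 for: ",
      paste(out$parameter[out$flagged], collapse = ", "),
      "; lengthen the chain (chain_config('reference_long'))"))
  }
  out
}

#' Tidy a Bayesian GLM fit
#'
#' One row per coefficient with the posterior mean, posterior SD, 95% HPD
#' interval, and a per-term significance flag (HPD excludes zero). With
#' `scale = "original"`, coefficients of a standardized numeric predictor
#' are back-transformed to the predictor's original units.
#'
#' @param x A `bayes_glm_fit`.
#' @param scale Report coefficients on the standardized (fitting) scale or
#'   the predictor's original scale.
#' @param prob HPD coverage.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `significant`.
#' @export
tidy.bayes_glm_fit <- function(x, scale = c("standardized", "original"),
                               prob = 0.95, ...) {
  scale <- match.arg(scale)
  samples <- x$samples
  if (scale == "original" && !x$design$is_factor &&
      !is.null(x$design$name)) {
    # back-transform each (intercept, slope) block from z-units
    ctr <- x$design$center
    scl <- x$design$scale
    slope_cols <- grep(paste0(x$design$name, "$"), colnames(samples))
    int_cols <- grep("\\(Intercept\\)$", colnames(samples))
    for (k in seq_along(slope_cols)) {
      b1 <- samples[, slope_cols[k]] / scl
      samples[, int_cols[k]] <- samples[, int_cols[k]] -
        samples[, slope_cols[k]] * ctr / scl
      samples[, slope_cols[k]] <- b1
    }
  }
  hpd <- t(apply(samples, 2, hpd_interval, prob = prob))
  tibble::tibble(
    term = colnames(samples),
    estimate = colMeans(samples),
    std.error = apply(samples, 2, sd),
    conf.low = hpd[, 1],
    conf.high = hpd[, 2],
    significant = hpd[, 1] > 0 | hpd[, 2] < 0
  )
}

#' @rdname tidy.bayes_glm_fit
#' @return `glance()`: a one-row tibble with `dic`, `p_d`, `mean_deviance`,
#'   `retained`, `n`, `significant` (any fixed-effect HPD excluding zero; NA
#'   for an intercept-only model), and the worst lag-1 autocorrelation.
#' @export
glance.bayes_glm_fit <- function(x, ...) {
  td <- tidy.bayes_glm_fit(x)
  ft <- fixed_terms(x)
  tibble::tibble(
    dic = x$dic, p_d = x$p_d, mean_deviance = x$mean_deviance,
    retained = nrow(x$samples), n = x$n,
    significant = if (length(ft)) any(td$significant[td$term %in% ft]) else NA,
    max_lag1_autocorr = max(abs(apply(x$samples, 2, lag1_autocorr)))
  )
}

#' @export
print.bayes_glm_fit <- function(x, ...) {
  cat(sprintf("<bayes_glm_fit> %s, n = %d, %d retained samples\n",
              x$family, x$n, nrow(x$samples)))
  cat(sprintf("  DIC %.2f (pD %.2f)\n", x$dic, x$p_d))
  print(tidy.bayes_glm_fit(x), n = 8)
  invisible(x)
}

#' Posterior-mean fitted outcome probabilities
#'
#' Back-transformed fitted probabilities over a grid of predictor values
#' (original units), averaged over the posterior. For multinomial fits the
#' probabilities of the three categories sum to one at every point.
#'
#' @param fit A `bayes_glm_fit` with a numeric predictor (or intercept-only).
#' @param at Predictor values (original units); defaults to the intercept
#'   (standardized 0) when the model has no predictor.
#' @return A tibble with `at`, `category`, `probability`.
#' @export
fitted_probs <- function(fit, at = NULL) {
  stopifnot(inherits(fit, "bayes_glm_fit"))
  if (fit$design$is_factor) abort("fitted_probs needs a numeric predictor")
  z <- if (is.null(fit$design$name)) 0 else {
    at <- at %||% fit$design$center
    (at - fit$design$center) / fit$design$scale
  }
  at <- at %||% NA_real_
  s <- fit$samples
  if (fit$family == "multinomial") {
    p <- ncol(fit$design$X)
    X <- cbind(1, z)[, seq_len(p), drop = FALSE]
    e1 <- exp(X %*% t(s[, 1:p, drop = FALSE]))
    e2 <- exp(X %*% t(s[, (p + 1):(2 * p), drop = FALSE]))
    denom <- 1 + e1 + e2
    tibble::tibble(
      at = rep(at, 3),
      category = rep(fit$categories, each = length(z)),
      probability = c(rowMeans(1 / denom), rowMeans(e1 / denom),
                      rowMeans(e2 / denom))
    )
  } else {
    p <- ncol(fit$design$X)
    X <- cbind(1, z)[, seq_len(p), drop = FALSE]
    eta <- X %*% t(s[, seq_len(p), drop = FALSE])
    tibble::tibble(at = at, category = "success",
                   probability = rowMeans(stats::plogis(eta)))
  }
}

#' Trace plots of a Bayesian GLM fit
#'
#' @param object A `bayes_glm_fit`.
#' @param ... Unused.
#' @return A ggplot object with one facet per parameter.
#' @export
autoplot.bayes_glm_fit <- function(object, ...) {
  keep <- colnames(object$samples)
  keep <- keep[!grepl("^u\\.", keep)]
  df <- tibble::as_tibble(object$samples[, keep, drop = FALSE]) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained sample", y = NULL) +
    ggplot2::theme_minimal()
}
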