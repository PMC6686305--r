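#' Configuration for the synthetic community generator
#'
#' Defines a species-by-year community time series with controlled dynamics.
#' Log-densities follow \eqn{\log \lambda_{it} = \mu_i + c_i b u_t +
#' \epsilon_{it}} with a shared yearly environmental driver
#' \eqn{u_t \sim N(0, env\_sd^2)} and lognormal species-year noise; observed
#' counts are Poisson around \eqn{\lambda_{it}} and are reported as densities
#' (pairs per 10 ha). The regime sets the species loadings \eqn{c_i}:
#' `"correlated"` gives every species +1 (all track the driver together),
#' `"compensatory"` balances +1/-1 within each guild (declines in some
#' species offset by gains in others), `"random"` sets all loadings to zero
#' (independent species). Tracing (rare) species are present in any year
#' independently with probability 0.3 and carry imputed density constants.
#'
#' With the defaults (S = 20, T = 30, `mean_log_density` 0.16, lognormal
#' spread 1, noise 0.4, two tracing species) random-regime matrices average
#' roughly 38% zero cells — the typical fill of long-term territory-mapping
#' matrices, whose species counts span 14-78 over 10-57 years.
#'
#' @param regime `"compensatory"`, `"correlated"`, or `"random"`.
#' @param n_species,n_years Matrix dimensions (S >= 4, T >= 10; long-term
#'   series of fewer than 10 years are not meaningful here).
#' @param mean_log_density,sd_log_density Mean and SD of the species-level
#'   log mean densities \eqn{\mu_i}.
#' @param env_sd SD of the yearly driver \eqn{u_t}.
#' @param loading Common response magnitude \eqn{b}.
#' @param noise_sd SD of the species-year lognormal noise.
#' @param obs_model Observation layer mapping expected densities to counts.
#'   `"poisson"` draws independent Poisson counts (classical sampling noise;
#'   conditional on the margins this matches the multinomial variation the
#'   IT/IA nulls assume). `"territory"` stochastically rounds the expected
#'   density (`floor(lambda)` plus a Bernoulli on the fraction), giving
#'   strongly underdispersed counts that emulate the year-to-year persistence
#'   of territory-mapping censuses; shared dynamics then stand out against
#'   the multinomial null instead of being swamped by sampling noise.
#' @param n_tracing Number of tracing (rare) species among `n_species`.
#' @param guild_scheme Named integer vector partitioning the non-tracing
#'   species into guilds; `NULL` splits them roughly 50/30/20 into foliage,
#'   ground, and trunk foragers.
#' @param plot_size_ha Census plot size recorded in the matrix.
#' @param seed Optional seed stored with the config; `generate_community()`
#'   uses it when set.
#' @return A `sim_config` list.
#' @export
sim_config <- function(regime = c("random", "correlated", "compensatory"),
                       n_species = 20, n_years = 30,
                       mean_log_density = 0.16, sd_log_density = 1,
                       env_sd = 0.5, loading = 1, noise_sd = 0.4,
                       obs_model = c("poisson", "territory"),
                       n_tracing = 2, guild_scheme = NULL,
                       plot_size_ha = 10, seed = NULL) {
  regime <- match.arg(regime)
  obs_model <- match.arg(obs_model)
  if (n_species < 4) abort("n_species must be >= 4")
  if (n_years < 10) abort("n_years must be >= 10")
  if (any(c(sd_log_density, env_sd, noise_sd) < 0)) {
    abort("standard deviations must be >= 0")
  }
  n_core <- n_species - n_tracing
  if (n_core < 2) abort("need at least 2 non-tracing species")
  if (is.null(guild_scheme)) {
    sizes <- c(floor(0.5 * n_core), floor(0.3 * n_core))
    sizes <- c(sizes, n_core - sum(sizes))
    guild_scheme <- setNames(sizes, c("foliage_forager", "ground_forager",
                                      "trunk_forager"))
    guild_scheme <- guild_scheme[guild_scheme > 0]
  }
  if (sum(guild_scheme) != n_core) {
    abort("guild_scheme must partition the non-tracing species")
  }
  if (regime == "compensatory" && any(guild_scheme < 2)) {
    abort("compensatory regime needs >= 2 species per guild to balance loadings")
  }
  structure(list(
    regime = regime, n_species = n_species, n_years = n_years,
    mean_log_density = mean_log_density, sd_log_density = sd_log_density,
    env_sd = env_sd, loading = loading, noise_sd = noise_sd,
    obs_model = obs_model,
    n_tracing = n_tracing, guild_scheme = guild_scheme,
    plot_size_ha = plot_size_ha, seed = seed
  ), class = "sim_config")
}

#' Generate a synthetic community time series
#'
#' Draws one species-by-year matrix (plus its guild table) from a
#' [sim_config()]. Non-tracing species get Poisson counts around lognormal
#' mean densities driven by a shared yearly environment according to the
#' regime; tracing species are present in each year independently with
#' probability 0.3, flagged as tracing, and filled with their size-class
#' density constant.
#'
#' @param config A [sim_config()].
#' @param dataset_id Label for the generated matrix.
#' @param seed Seed for this draw; defaults to `config$seed`. The same
#'   (config, seed) pair always reproduces the same matrix.
#' @return A list with `matrix` (an [abundance_matrix()]) and `guilds`
#'   (a tibble with `species`, `guild`, `size_class`).
#' @export
generate_community <- function(config, dataset_id = "synthetic",
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  draw <- function() {
    S <- config$n_species
    T_ <- config$n_years
    n_core <- S - config$n_tracing
    guilds_core <- rep(names(config$guild_scheme), config$guild_scheme)
    loadings <- switch(config$regime,
      correlated = rep(1, n_core),
      random = rep(0, n_core),
      compensatory = unlist(lapply(config$guild_scheme, function(k) {
        rep(c(1, -1), length.out = k)
      }), use.names = FALSE)
    )
    mu <- rnorm(n_core, config$mean_log_density, config$sd_log_density)
    u <- rnorm(T_, 0, config$env_sd)
    eps <- matrix(rnorm(n_core * T_, 0, config$noise_sd), n_core, T_)
    log_lambda <- mu + outer(loadings, u) * config$loading + eps
    lambda <- exp(log_lambda)
    counts <- if (config$obs_model == "poisson") {
      matrix(rpois(n_core * T_, lambda), n_core, T_)
    } else {
      # persistent territory counts: stochastic rounding of the expected
      # density (variance <= 0.25, far below Poisson)
      matrix(floor(lambda) + (runif(n_core * T_) < lambda %% 1), n_core, T_)
    }
    # tracing species: sporadic presences at imputed constants
    n_tr <- config$n_tracing
    tracing_cells <- matrix(FALSE, S, T_)
    values <- matrix(0, S, T_)
    values[seq_len(n_core), ] <- counts
    size_classes <- character(S)
    size_classes[seq_len(n_core)] <- NA_character_
    if (n_tr > 0) {
      tr_rows <- n_core + seq_len(n_tr)
      tr_class <- rep(names(tracing_constants), length.out = n_tr)
      present <- matrix(runif(n_tr * T_) < 0.3, n_tr, T_)
      tracing_cells[tr_rows, ] <- present
      values[tr_rows, ] <- present * tracing_constants[tr_class]
      size_classes[tr_rows] <- tr_class
    }
    sp <- sprintf("sp%02d", seq_len(S))
    guild_all <- c(guilds_core,
                   rep(c("raptor", "omnivore"), length.out = n_tr))
    dimnames(values) <- list(sp, as.character(seq_len(T_)))
    dimnames(tracing_cells) <- dimnames(values)
    list(
      matrix = abundance_matrix(values, plot_size_ha = config$plot_size_ha,
                                dataset_id = dataset_id,
                                tracing = tracing_cells),
      guilds = tibble::tibble(species = sp, guild = guild_all,
                              size_class = size_classes)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic outcome table for the meta-GLM layer
#'
#' Draws outcome records whose category probabilities follow a
#' baseline-category logit in a standardized covariate, with covariates
#' spanning the ranges typical of long-term census data sets (plot size
#' 7-150 ha, 10-57 years, 14-78 species). Used to test slope recovery and
#' HPD coverage of the Bayesian GLMs.
#'
#' @param n_datasets Number of records.
#' @param slopes Named numeric: log-odds slopes of `aggregation` and
#'   `segregation` against the `random` baseline, per SD of the predictor.
#' @param intercepts Named numeric baseline-category intercepts.
#' @param predictor Which covariate carries the effect.
#' @param seed Optional seed.
#' @return A tibble with covariates and an `outcome` factor.
#' @export
generate_outcome_table <- function(n_datasets,
                                   slopes = c(aggregation = 0,
                                              segregation = 0),
                                   intercepts = c(aggregation = 0,
                                                  segregation = 0),
                                   predictor = "plot_size_ha",
                                   seed = NULL) {
  draw <- function() {
    covs <- tibble::tibble(
      dataset_id = sprintf("ds%03d", seq_len(n_datasets)),
      plot_size_ha = runif(n_datasets, 7, 150),
      n_years = sample(10:57, n_datasets, replace = TRUE),
      n_species = sample(14:78, n_datasets, replace = TRUE),
      mean_density = exp(rnorm(n_datasets, 0, 0.7)),
      cv_density = exp(rnorm(n_datasets, 0.5, 0.3))
    )
    covs$matrix_size <- covs$n_years * covs$n_species
    covs$prop_zeros <- stats::rbeta(n_datasets, 4, 6)
    x <- covs[[predictor]]
    z <- (x - mean(x)) / sd(x)
    e_agg <- exp(intercepts[["aggregation"]] + slopes[["aggregation"]] * z)
    e_seg <- exp(intercepts[["segregation"]] + slopes[["segregation"]] * z)
    denom <- 1 + e_agg + e_seg
    u <- runif(n_datasets)
    outcome <- ifelse(u < 1 / denom, "random",
                      ifelse(u < (1 + e_agg) / denom, "aggregation",
                             "segregation"))
    covs$outcome <- factor(outcome,
                           levels = c("random", "aggregation", "segregation"))
    covs
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Paired resource-partition generator (stress test)
#'
#' A deliberately extreme two-species mechanism for stress-testing the
#' segregation detectors: species pairs share a fixed resource pool K, the
#' second species receiving `max(0, K - N1)` plus noise, which produces
#' strong negative covariance without a shared environmental driver.
#'
#' @param n_pairs Number of species pairs (matrix has `2 * n_pairs` rows).
#' @param n_years Years.
#' @param K Resource pool per pair (expected joint abundance).
#' @param noise_sd Lognormal noise on the first species' mean.
#' @param plot_size_ha,dataset_id Metadata.
#' @param seed Optional seed.
#' @return An [abundance_matrix()].
#' @export
generate_resource_partition <- function(n_pairs = 5, n_years = 30, K = 10,
                                        noise_sd = 0.4, plot_size_ha = 10,
                                        dataset_id = "partition",
                                        seed = NULL) {
  draw <- function() {
    values <- matrix(0, 2 * n_pairs, n_years)
    for (p in seq_len(n_pairs)) {
      lam1 <- K / 2 * exp(rnorm(n_years, 0, noise_sd))
      n1 <- rpois(n_years, lam1)
      n2 <- rpois(n_years, pmax(0.1, K - n1))
      values[2 * p - 1, ] <- n1
      values[2 * p, ] <- n2
    }
    rownames(values) <- sprintf("sp%02d", seq_len(2 * n_pairs))
    colnames(values) <- as.character(seq_len(n_years))
    abundance_matrix(values, plot_size_ha = plot_size_ha,
                     dataset_id = dataset_id)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
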