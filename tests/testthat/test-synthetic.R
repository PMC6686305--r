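mean_pairwise_cor <- function(m) {
  cc <- suppressWarnings(stats::cor(t(m)))
  mean(cc[upper.tri(cc)], na.rm = TRUE)
}

test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(seed = 77)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a, b)
  c2 <- generate_community(sim_config(), seed = 78)
  d <- generate_community(sim_config(), seed = 78)
  expect_identical(c2, d)
})

test_that("regimes produce their target correlation signatures", {
  set.seed(61)
  # random regime: mean pairwise correlation near zero (CLT over matrices)
  rnd <- replicate(300, {
    g <- generate_community(sim_config(n_tracing = 0))
    mean_pairwise_cor(g$matrix$values)
  })
  expect_lt(abs(mean(rnd)), 0.02)
  # correlated regime: clearly positive mean pairwise correlation (the
  # shared lognormal driver gives ~0.55 on the latent density scale;
  # Poisson observation noise at the calibrated densities attenuates the
  # count-scale value to ~0.2)
  corr <- replicate(100, {
    g <- generate_community(sim_config("correlated", n_tracing = 0))
    mean_pairwise_cor(g$matrix$values)
  })
  expect_gt(mean(corr), 0.15)
  # compensatory regime: negative mean within-guild correlation
  comp <- replicate(100, {
    g <- generate_community(sim_config("compensatory", n_tracing = 0))
    m <- g$matrix$values
    guild <- g$guilds$guild
    within <- c()
    for (gl in unique(guild)) {
      rows <- which(guild == gl)
      if (length(rows) > 1) within <- c(within, mean_pairwise_cor(m[rows, ]))
    }
    mean(within)
  })
  expect_lt(mean(comp), -0.01)
})

test_that("the calibrated default fill is close to 38% zeros", {
  set.seed(62)
  pz <- replicate(150, mean(generate_community(sim_config())$matrix$values == 0))
  expect_lt(abs(mean(pz) - 0.38), 0.04)
})

test_that("tracing species are flagged, sporadic, and carry constants", {
  set.seed(63)
  g <- generate_community(sim_config(n_species = 10, n_tracing = 3))
  x <- g$matrix
  tr_rows <- which(rowSums(x$tracing) > 0)
  expect_equal(length(tr_rows), 3)
  vals <- x$values[x$tracing]
  expect_true(all(vals %in% tracing_constants))
  expect_true(all(x$values[tr_rows, ][!x$tracing[tr_rows, ]] == 0))
  expect_false(anyNA(g$guilds$size_class[tr_rows]))
})

test_that("infeasible configurations are refused", {
  expect_error(sim_config(n_species = 3), ">= 4")
  expect_error(sim_config(n_years = 5), ">= 10")
  expect_error(sim_config("compensatory",
                          guild_scheme = c(foliage_forager = 17,
                                           raptor = 1)),
               ">= 2 species per guild")
  expect_error(sim_config(noise_sd = -1), ">= 0")
})

test_that("synthetic outcome tables follow the implied multinomial logit", {
  # zero slopes: frequencies match the intercept-implied proportions
  t0 <- generate_outcome_table(4000, seed = 64)
  freq <- table(t0$outcome) / nrow(t0)
  expect_equal(unname(freq[["random"]]), 1 / 3, tolerance = 0.08)
  expect_equal(unname(freq[["aggregation"]]), 1 / 3, tolerance = 0.08)
  # a large positive slope makes the outcome rate rise across quartiles
  t1 <- generate_outcome_table(
    4000, slopes = c(aggregation = 2, segregation = 0), seed = 65)
  q <- cut(t1$plot_size_ha, quantile(t1$plot_size_ha, 0:4 / 4),
           include.lowest = TRUE)
  rate <- tapply(t1$outcome == "aggregation", q, mean)
  expect_true(all(diff(rate) > 0))
  # determinism
  expect_identical(generate_outcome_table(50, seed = 66),
                   generate_outcome_table(50, seed = 66))
})

test_that("the resource-partition stress generator anticorrelates pairs", {
  set.seed(67)
  x <- generate_resource_partition(n_pairs = 6, n_years = 40, K = 20)
  m <- x$values
  cors <- sapply(1:6, function(p) cor(m[2 * p - 1, ], m[2 * p, ]))
  expect_lt(mean(cors), -0.2)
})
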