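test_that("outcome tabulation matches direct arithmetic", {
  rec <- fake_records(c(rep("aggregation", 2), rep("random", 5),
                        rep("segregation", 3)))
  tab <- tabulate_outcomes(rec)
  expect_equal(tab$n, c(2, 5, 3))
  expect_equal(tab$pct, c(20, 50, 30))
  expect_equal(unique(tab$n_group), 10)
  one <- tabulate_outcomes(fake_records(rep("aggregation", 4)))
  expect_equal(one$pct, c(100, 0, 0))
  # percentages always close on 100 within groups, for random record sets
  set.seed(51)
  for (rep in 1:20) {
    o <- sample(c("aggregation", "random", "segregation"),
                sample(3:40, 1), replace = TRUE)
    tab <- tabulate_outcomes(fake_records(o))
    expect_lt(abs(sum(tab$pct) - 100), 0.3)
    expect_equal(tab$n, as.vector(table(factor(o, c("aggregation", "random",
                                                    "segregation")))))
  }
})

test_that("the binary grid yields the five valid combinations", {
  set.seed(52)
  g <- generate_community(sim_config(n_species = 8, n_years = 10))
  grid <- run_binary_grid(binarize(g$matrix), n_sim = 99)
  expect_equal(nrow(grid), 5)
  expect_equal(nrow(dplyr::distinct(grid, algorithm, index)), 5)
  expect_false(any(grid$algorithm == "SIM9" & grid$index == "V_RATIO"))
  expect_setequal(grid$index[grid$algorithm == "SIM2"],
                  c("CHECKER", "C_SCORE", "V_RATIO"))
})

test_that("the quantitative grid yields all six combinations, no binary indices", {
  set.seed(53)
  g <- generate_community(sim_config(n_species = 8, n_years = 10,
                                     n_tracing = 0))
  grid <- run_quant_grid(scale_to_counts(g$matrix, 1), n_sim = 99)
  expect_equal(nrow(grid), 6)
  expect_setequal(unique(grid$index), c("CA_ST", "AA_ST", "MA"))
  expect_setequal(unique(grid$algorithm), c("IT", "IA"))
})

test_that("19 data sets produce 95 binary and 114 quantitative records", {
  set.seed(54)
  datasets <- lapply(1:19, function(i) {
    generate_community(sim_config(n_species = 8, n_years = 10,
                                  n_tracing = 0),
                       dataset_id = sprintf("ds%02d", i))$matrix
  })
  names(datasets) <- vapply(datasets, function(d) d$dataset_id, "")
  rec <- run_null_study(datasets, n_sim = 49, scale_factor = 1, seed = 99)
  expect_equal(sum(rec$model_type == "binary"), 95)
  expect_equal(sum(rec$model_type == "quantitative"), 114)
  # covariates attached to every record
  expect_true(all(c("plot_size_ha", "matrix_size", "prop_zeros",
                    "mean_density", "cv_density") %in% names(rec)))
  expect_false(anyNA(rec$prop_zeros))
})

test_that("the study runner is deterministic and order-invariant per dataset", {
  set.seed(55)
  datasets <- lapply(1:3, function(i) {
    generate_community(sim_config(n_species = 6, n_years = 10,
                                  n_tracing = 0),
                       dataset_id = paste0("d", i))$matrix
  })
  names(datasets) <- paste0("d", 1:3)
  a <- run_null_study(datasets, n_sim = 49, scale_factor = 1, seed = 7)
  b <- run_null_study(datasets, n_sim = 49, scale_factor = 1, seed = 7)
  expect_identical(a, b)
})

test_that("guild-level runs skip tiny guilds and log them", {
  set.seed(56)
  g <- generate_community(sim_config(n_species = 12, n_tracing = 2))
  # tracing species sit in raptor/omnivore guilds of size 1 -> skipped
  rec <- run_null_study(g$matrix, guilds = g$guilds, level = "guild",
                        model_type = "binary", n_sim = 49, seed = 8)
  expect_true(all(rec$level == "guild"))
  expect_false(any(is.na(rec$guild)))
  skipped <- attr(rec, "skipped")
  expect_gte(nrow(skipped), 1)
  expect_true(all(skipped$n_species < 2))
})

test_that("outcome CSVs round-trip with a provenance header", {
  rec <- fake_records(c("aggregation", "random"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcomes(rec, path, seed = 42, config = list(n_sim = 10))
  expect_match(readLines(path, n = 1), "^# temponull .*seed=42")
  back <- read_outcomes(path)
  back$guild <- as.character(back$guild)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  # identical config + seed -> byte-identical files
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_outcomes(rec, path2, seed = 42, config = list(n_sim = 10))
  expect_identical(readLines(path), readLines(path2))
})

test_that("summary plots build", {
  rec <- dplyr::bind_rows(
    fake_records(rep(c("aggregation", "random", "segregation"), 4)),
    dplyr::mutate(fake_records(rep("random", 6)), algorithm = "SIM9",
                  index = "CHECKER"))
  expect_s3_class(plot_outcome_summary(rec), "ggplot")
})
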