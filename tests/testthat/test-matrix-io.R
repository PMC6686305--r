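test_that("delimited matrices parse, with '+' cells flagged as tracing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species,1990,1991,1992,1993",
    "parus_major,2.5,3,0,1.2",
    "dendrocopos_major,+,0,+,0",
    "turdus_merula,0,0.5,0.5,0"
  ), path)
  x <- read_abundance_matrix(path, plot_size_ha = 25)
  expect_s3_class(x, "abundance_matrix")
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(years(x), 1990:1993)
  expect_equal(unname(x$values["parus_major", ]), c(2.5, 3, 0, 1.2))
  expect_equal(unname(x$tracing["dendrocopos_major", ]),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(x$values["dendrocopos_major", ]), rep(0, 4))
  expect_equal(x$plot_size_ha, 25)
})

test_that("parse errors name the offending cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,1,2", "a,1,-1", "b,0,1"), path)
  expect_error(read_abundance_matrix(path), "negative.*'a'.*'2'")
  writeLines(c("species,1,2", "a,1,x", "b,0,1"), path)
  expect_error(read_abundance_matrix(path), "cannot parse.*'a'")
  writeLines(c("species,1,2", "a,1,1", "a,0,1"), path)
  expect_error(read_abundance_matrix(path), "duplicate")
})

test_that("write -> read round trip reproduces random matrices bit-exactly", {
  set.seed(41)
  for (rep in 1:20) {
    v <- matrix(round(rexp(30), 3), 5, 6)
    tr <- matrix(runif(30) < 0.1, 5, 6)
    v[tr] <- 0
    dimnames(v) <- list(paste0("sp", 1:5), as.character(2000:2005))
    dimnames(tr) <- dimnames(v)
    x <- abundance_matrix(v, plot_size_ha = 12, dataset_id = "rt",
                          tracing = tr)
    path <- withr::local_tempfile(fileext = ".csv")
    write_abundance_matrix(x, path)
    y <- read_abundance_matrix(path, plot_size_ha = 12, dataset_id = "rt")
    expect_identical(y$values, x$values)
    expect_identical(y$tracing, x$tracing)
  }
})

test_that("tracing imputation fills flagged cells with size-class constants", {
  v <- matrix(0, 3, 4, dimnames = list(c("wp", "corvid", "eagle"), 1:4))
  tr <- v > 0
  tr["wp", c(2, 3)] <- TRUE
  tr["corvid", 1] <- TRUE
  tr["eagle", 4] <- TRUE
  x <- abundance_matrix(v, tracing = tr)
  sc <- c(wp = "small", corvid = "medium_raptor_corvid",
          eagle = "large_raptor")
  y <- impute_tracing(x, sc)
  expect_equal(unname(y$values["wp", ]), c(0, 0.1, 0.1, 0))
  expect_equal(unname(y$values["corvid", 1]), 0.05)
  expect_equal(unname(y$values["eagle", 4]), 0.004)
  # non-tracing cells untouched, flags retained
  expect_true(all(y$values[!y$tracing] == 0))
  expect_identical(y$tracing, x$tracing)
  # missing size class errors; no tracing flags is the identity
  expect_error(impute_tracing(x, sc[-1]), "without a size class")
  plain <- abundance_matrix(matrix(1, 2, 4))
  expect_identical(impute_tracing(plain, character()), plain)
})

test_that("binarize thresholds at zero and is idempotent", {
  x <- abundance_matrix(matrix(c(0.1, 2.3, 0, 0.004), 2, 2))
  b <- binarize(x)
  expect_equal(unname(b$values), matrix(c(1L, 1L, 0L, 1L), 2, 2))
  expect_identical(binarize(b), b)
  # all-zero rows are retained in storage
  x2 <- abundance_matrix(rbind(a = c(1, 0), b = c(0, 0)))
  expect_equal(unname(binarize(x2)$values[2, ]), c(0L, 0L))
})

test_that("characteristics match direct arithmetic and a brute-force oracle", {
  x <- abundance_matrix(matrix(c(1, 0, 0, 1), 2, 2), plot_size_ha = 10)
  ch <- characteristics(x)
  expect_equal(ch$prop_zeros, 0.5)
  expect_equal(ch$matrix_size, 4)
  expect_equal(ch$n_species, 2)
  expect_equal(ch$n_years, 2)
  expect_equal(ch$mean_density, 0.5)

  ch2 <- characteristics(abundance_matrix(matrix(2, 2, 2)))
  expect_equal(ch2$prop_zeros, 0)
  expect_equal(ch2$cv_density, 0)

  expect_error(characteristics(abundance_matrix(matrix(0, 2, 2))),
               "undefined")

  set.seed(7)
  for (rep in 1:100) {
    v <- matrix(rpois(48, 1.5) * round(runif(48), 2), 6, 8)
    if (mean(v) == 0) next
    ch <- characteristics(abundance_matrix(v))
    expect_equal(ch$prop_zeros, sum(v == 0) / 48)
    expect_equal(ch$mean_density, mean(v))
    expect_equal(ch$cv_density, sd(as.vector(v)) / mean(v))
    expect_equal(ch$matrix_size, 48)
  }
})

test_that("guild splitting partitions rows exactly and flags singletons", {
  v <- matrix(1, 5, 3, dimnames = list(paste0("s", 1:5), 1:3))
  x <- abundance_matrix(v)
  g <- tibble::tibble(
    species = paste0("s", 1:5),
    guild = c("trunk_forager", "trunk_forager", "ground_forager",
              "ground_forager", "raptor"))
  parts <- split_by_guild(x, g)
  expect_equal(nrow(parts), 3)
  expect_equal(sort(unname(parts$n_species)), c(1L, 2L, 2L))
  expect_equal(parts$analyzable, parts$n_species >= 2)
  # exact partition: union of rows equals input, no duplicates
  all_rows <- unlist(lapply(parts$matrix, species))
  expect_setequal(all_rows, species(x))
  expect_equal(length(all_rows), 5)

  # all species in one guild: identity submatrix
  g1 <- tibble::tibble(species = paste0("s", 1:5), guild = "omnivore")
  one <- split_by_guild(x, g1)
  expect_identical(one$matrix[[1]]$values, x$values)

  expect_error(split_by_guild(x, g[1:3, ]), "not in guild table")

  # property: random guild assignments always partition exactly
  set.seed(11)
  for (rep in 1:25) {
    gl <- sample(guild_categories, 5, replace = TRUE)
    parts <- split_by_guild(x, tibble::tibble(species = paste0("s", 1:5),
                                              guild = gl))
    rows <- unlist(lapply(parts$matrix, species))
    expect_setequal(rows, species(x))
    expect_equal(length(rows), 5)
  }
})

test_that("excluding rare species drops tracing rows and raises fill", {
  set.seed(13)
  g <- generate_community(sim_config(n_species = 10, n_tracing = 2))
  x <- g$matrix
  red <- exclude_rare(x)
  expect_equal(nrow(red$values), 8)
  expect_false(any(red$tracing))
  no_tr <- generate_community(sim_config(n_tracing = 0))$matrix
  expect_identical(exclude_rare(no_tr), no_tr)
  # fill increases monotonically after exclusion on generated data
  for (rep in 1:10) {
    m <- generate_community(sim_config(n_species = 12, n_tracing = 3))$matrix
    expect_gte(mean(exclude_rare(m)$values > 0), mean(m$values > 0))
  }
  # fewer than 2 species left -> error
  tiny <- generate_community(sim_config(n_species = 4, n_tracing = 2))$matrix
  tiny$tracing[1:3, 1] <- TRUE
  expect_error(exclude_rare(tiny), "fewer than 2")
})

test_that("guild tables validate categories and size classes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,guild,size_class", "a,raptor,large_raptor",
               "b,omnivore,"), path)
  g <- read_guild_table(path)
  expect_equal(g$guild, c("raptor", "omnivore"))
  writeLines(c("species,guild", "a,seabird"), path)
  expect_error(read_guild_table(path), "unknown guild")
})
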