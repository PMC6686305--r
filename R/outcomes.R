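#' The standard index-by-algorithm grids
#'
#' `run_binary_grid()` runs the five valid binary combinations on one matrix:
#' SIM2 with CHECKER, C-score and V-ratio, and SIM9 with CHECKER and C-score
#' (SIM9 cannot be paired with the V-ratio). `run_quant_grid()` runs all six
#' quantitative combinations: IT and IA each with CA_ST, AA_ST and MA.
#' Within an algorithm the same null matrices are reused across indices.
#'
#' @param x An [abundance_matrix()] / `binary_matrix` (binary grid) or a
#'   `count_matrix` (quantitative grid).
#' @param n_sim,alpha Simulation protocol (defaults follow the reference
#'   protocol: 10,000 replicates at the 5% level).
#' @param burn_in,thin SIM9 chain controls.
#' @param max_restarts IT refill budget.
#' @param seed Optional integer seed.
#' @param level,guild Labels carried into the outcome records.
#' @return A tibble of outcome records, one row per (algorithm, index): 5
#'   rows for the binary grid, 6 for the quantitative grid.
#' @export
run_binary_grid <- function(x, n_sim = 10000, alpha = 0.05, burn_in = 30000,
                            thin = NULL, seed = NULL, level = "assemblage",
                            guild = NA_character_) {
  run <- function() {
    res <- c(
      binary_null_core(x, c("CHECKER", "C_SCORE", "V_RATIO"), "SIM2",
                       n_sim, alpha, burn_in, thin, level, guild),
      binary_null_core(x, c("CHECKER", "C_SCORE"), "SIM9",
                       n_sim, alpha, burn_in, thin, level, guild)
    )
    dplyr::bind_rows(lapply(res, tidy))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @rdname run_binary_grid
#' @export
run_quant_grid <- function(x, n_sim = 10000, alpha = 0.05,
                           max_restarts = 1000, seed = NULL,
                           level = "assemblage", guild = NA_character_) {
  run <- function() {
    res <- c(
      quant_null_core(x, c("CA_ST", "AA_ST", "MA"), "IT", n_sim, alpha,
                      max_restarts, level, guild),
      quant_null_core(x, c("CA_ST", "AA_ST", "MA"), "IA", n_sim, alpha,
                      max_restarts, level, guild)
    )
    dplyr::bind_rows(lapply(res, tidy))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Tabulate null-model outcomes
#'
#' Counts and percentages of the three outcome categories (aggregation,
#' random, segregation) within groups. Percentages within a group sum to 100
#' up to rounding; groups with no records are omitted.
#'
#' @param records A tibble of outcome records (rows from
#'   [tidy.null_result()], [run_binary_grid()], or [run_null_study()]).
#' @param ... Grouping columns (tidy-select), e.g. `model_type, algorithm,
#'   index`. Empty means one overall group.
#' @param digits Rounding applied to the percentage column.
#' @return A tibble with grouping columns, `outcome`, `n`, `n_group`, and
#'   `pct`.
#' @export
tabulate_outcomes <- function(records, ..., digits = 1) {
  if (nrow(records) == 0) abort("no outcome records to tabulate")
  levels <- c("aggregation", "random", "segregation")
  bad <- setdiff(unique(records$outcome), levels)
  if (length(bad)) {
    abort(paste0("unknown outcome value(s): ", paste(bad, collapse = ", ")))
  }
  records |>
    dplyr::mutate(outcome = factor(.data$outcome, levels = levels)) |>
    dplyr::group_by(..., .data$outcome, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(n_group = sum(.data$n),
                  pct = round(100 * .data$n / .data$n_group, digits)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_group > 0) |>
    dplyr::mutate(outcome = as.character(.data$outcome))
}

#' Summary bar chart of outcome frequencies
#'
#' Stacked percentage bars of the three outcome categories per
#' index-by-algorithm combination, optionally faceted by another grouping
#' column.
#'
#' @param records A tibble of outcome records.
#' @param facet Optional column name (string) to facet by, e.g. `"level"`.
#' @return A ggplot object.
#' @export
plot_outcome_summary <- function(records, facet = NULL) {
  groups <- c("model_type", "algorithm", "index", facet)
  tab <- tabulate_outcomes(records, dplyr::across(dplyr::all_of(groups)))
  tab$combo <- paste(tab$algorithm, tab$index, sep = "\n")
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$combo, y = .data$pct,
                                         fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(aggregation = "#2166ac",
                                          random = "grey75",
                                          segregation = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "% of simulations", fill = "outcome") +
    ggplot2::theme_minimal()
  if (!is.null(facet)) p <- p + ggplot2::facet_wrap(facet)
  p
}

#' Run the full null-model study over a set of data sets
#'
#' Applies the binary and/or quantitative grids to each assemblage matrix
#' and, optionally, to its foraging-guild submatrices, and binds all outcome
#' records with the per-dataset characteristics attached as covariates. Each
#' dataset receives its own child RNG seed derived deterministically from
#' `seed`, so results are reproducible and independent of dataset order.
#' Guild submatrices with fewer than two species (or, after imputation,
#' fewer than two non-empty rows/years) are skipped with a log attribute.
#'
#' @param datasets A named list of [abundance_matrix()] objects (names are
#'   dataset ids) or a single matrix.
#' @param guilds Optional guild table covering all species; required for
#'   `level = "guild"` records.
#' @param level Which levels to run: any of `"assemblage"`, `"guild"`.
#' @param model_type Which model families: any of `"binary"`,
#'   `"quantitative"`.
#' @param n_sim,alpha Simulation protocol.
#' @param scale_factor Density-to-count factor for the quantitative grid.
#' @param exclude_rare Drop tracing species before analysis (the
#'   reduced-matrix variant).
#' @param seed Master seed; per-dataset child seeds are derived from it.
#' @return A tibble of outcome records with covariate columns
#'   (`plot_size_ha`, `matrix_size`, `n_years`, `n_species`, `prop_zeros`,
#'   `mean_density`, `cv_density`). Skipped guild units are recorded in the
#'   `"skipped"` attribute.
#' @export
run_null_study <- function(datasets, guilds = NULL, level = "assemblage",
                           model_type = c("binary", "quantitative"),
                           n_sim = 10000, alpha = 0.05, scale_factor = 250,
                           exclude_rare = FALSE, seed = 1) {
  if (inherits(datasets, "abundance_matrix")) {
    datasets <- setNames(list(datasets), datasets$dataset_id)
  }
  level <- match.arg(level, c("assemblage", "guild"), several.ok = TRUE)
  model_type <- match.arg(model_type, several.ok = TRUE)
  if ("guild" %in% level && is.null(guilds)) {
    abort("guild-level analysis needs a guild table")
  }
  child_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(datasets)))
  skipped <- list()
  run_grids <- function(x, lvl, guild) {
    out <- list()
    if ("binary" %in% model_type) {
      out$bin <- run_binary_grid(x, n_sim = n_sim, alpha = alpha,
                                 level = lvl, guild = guild)
    }
    if ("quantitative" %in% model_type) {
      cm <- scale_to_counts(x, scale_factor)
      out$quant <- run_quant_grid(cm, n_sim = n_sim, alpha = alpha,
                                  level = lvl, guild = guild)
    }
    dplyr::bind_rows(out)
  }
  records <- purrr::imap(datasets, function(x, id) {
    withr::with_seed(child_seeds[[match(id, names(datasets))]], {
      if (exclude_rare) x <- exclude_rare(x)
      covs <- characteristics(x)
      recs <- list()
      if ("assemblage" %in% level) {
        recs$assemblage <- run_grids(x, "assemblage", NA_character_)
      }
      if ("guild" %in% level) {
        parts <- split_by_guild(x, guilds)
        for (i in seq_len(nrow(parts))) {
          g <- parts$guild[i]
          gm <- parts$matrix[[i]]
          ok <- parts$analyzable[i] &&
            sum(rowSums(gm$values) > 0) >= 2 &&
            sum(colSums(gm$values) > 0) >= 2
          if (!ok) {
            skipped[[length(skipped) + 1]] <<-
              tibble::tibble(dataset_id = id, guild = g,
                             n_species = parts$n_species[i])
            next
          }
          recs[[paste0("guild_", g)]] <- run_grids(gm, "guild", g)
        }
      }
      dplyr::bind_rows(recs) |>
        dplyr::left_join(covs, by = "dataset_id")
    })
  })
  out <- dplyr::bind_rows(records)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Write / read outcome records
#'
#' CSV serialization of outcome records with a provenance header (package
#' version, seed, and configuration hash) written as `#`-prefixed comment
#' lines.
#'
#' @param records Outcome records tibble.
#' @param path File path.
#' @param seed,config Provenance recorded in the header: the master seed and
#'   any list describing the run configuration (hashed).
#' @return `path` (write) or the records tibble (read).
#' @export
write_outcomes <- function(records, path, seed = NA, config = list()) {
  header <- sprintf(
    "# temponull %s | seed=%s | config_hash=%s",
    as.character(utils::packageVersion("temponull")), as.character(seed),
    rlang::hash(config))
  writeLines(header, path)
  readr::write_csv(records, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
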