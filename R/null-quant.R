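#' Individual-based matrix randomizations
#'
#' `it_randomize()` places individuals one at a time into cells with
#' probability proportional to the product of the observed row and column
#' totals, restricted to rows and columns that are not yet saturated, until
#' both marginals are reproduced exactly. `ia_randomize()` drops all N
#' individuals independently with cell probability
#' \eqn{R_i C_j / N^2}; only the grand total is constrained.
#'
#' @param row_totals,col_totals Non-negative integer marginal totals; for IT
#'   their sums must be equal.
#' @param max_restarts Full-refill budget should a fill ever dead-end (with
#'   product-form admissibility this cannot happen; the guard is defensive).
#' @return An integer matrix with the requested marginal structure.
#' @export
it_randomize <- function(row_totals, col_totals, max_restarts = 1000) {
  row_totals <- as.integer(row_totals)
  col_totals <- as.integer(col_totals)
  if (any(row_totals < 0) || any(col_totals < 0)) {
    abort("marginal totals must be non-negative")
  }
  if (sum(row_totals) != sum(col_totals)) {
    abort("row and column totals must have equal sums")
  }
  cpp_it(row_totals, col_totals, max_restarts)
}

#' @rdname it_randomize
#' @export
ia_randomize <- function(row_totals, col_totals) {
  row_totals <- as.integer(row_totals)
  col_totals <- as.integer(col_totals)
  if (any(row_totals < 0) || any(col_totals < 0)) {
    abort("marginal totals must be non-negative")
  }
  if (sum(row_totals) == 0) abort("grand total must be positive")
  cpp_ia(row_totals, col_totals)
}

# Tail pointing to segregation for each quantitative index: CA_ST high means
# opposing abundance shifts; AA_ST high means concordant shifts (so its low
# tail is the segregation side); MA low means dissimilar year compositions.
quant_seg_tail <- c(CA_ST = "high", AA_ST = "low", MA = "low")

quant_index_fun <- list(
  CA_ST = function(m) cpp_ca_aa(m)[1],
  AA_ST = function(m) cpp_ca_aa(m)[2],
  MA = function(m) cpp_ma(m)
)

quant_null_core <- function(x, indices, algorithm, n_sim, alpha,
                            max_restarts = 1000, level = "assemblage",
                            guild = NA_character_) {
  if (!inherits(x, "count_matrix")) {
    abort("x must be a count_matrix; see scale_to_counts()")
  }
  m <- x$values
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn(sprintf("dropping %d empty row(s) and %d empty column(s) from '%s'",
                 sum(!keep_r), sum(!keep_c), x$dataset_id))
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("need at least 2 non-empty species rows and 2 non-empty years")
  }
  all_idx <- c("CA_ST", "AA_ST", "MA")
  want <- all_idx %in% indices
  nulls <- cpp_quant_null(m, algorithm, want, n_sim, max_restarts)
  mm <- m
  storage.mode(mm) <- "double"
  lapply(setNames(indices, indices), function(idx) {
    new_null_result(
      observed = unname(quant_index_fun[[idx]](mm)),
      null_values = nulls[, match(idx, all_idx)],
      alpha = alpha, tails = "one", seg_tail = quant_seg_tail[[idx]],
      index = idx, algorithm = algorithm, model_type = "quantitative",
      dataset_id = x$dataset_id, level = level, guild = guild
    )
  })
}

#' Run a quantitative null-model test
#'
#' Computes the observed abundance-based index, simulates its null
#' distribution under the IT or IA individual-reassignment algorithm, and
#' classifies the outcome with one-tailed tests in each direction (add-one
#' Monte-Carlo convention): the outcome is segregation when the
#' segregation-side tail falls below `alpha`, aggregation when the
#' aggregation-side tail does, random otherwise. High CA_ST and low MA signal
#' segregation; high AA_ST signals aggregation. Empty rows/columns are
#' stripped with a warning before simulation.
#'
#' @param x A `count_matrix` (see [scale_to_counts()]).
#' @param index One of `"CA_ST"`, `"AA_ST"`, `"MA"`.
#' @param algorithm `"IT"` (both marginals reproduced) or `"IA"` (grand total
#'   only).
#' @param n_sim Number of null matrices.
#' @param alpha Significance level per one-tailed test.
#' @param max_restarts IT refill budget.
#' @param seed Optional integer seed.
#' @param level,guild Labels carried into the outcome record.
#' @return A `null_result`; see [tidy.null_result()].
#' @export
run_quant_null <- function(x, index = c("CA_ST", "AA_ST", "MA"),
                           algorithm = c("IT", "IA"), n_sim = 10000,
                           alpha = 0.05, max_restarts = 1000, seed = NULL,
                           level = "assemblage", guild = NA_character_) {
  index <- match.arg(index)
  algorithm <- match.arg(algorithm)
  run <- function() {
    quant_null_core(x, index, algorithm, n_sim, alpha, max_restarts,
                    level, guild)[[index]]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
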