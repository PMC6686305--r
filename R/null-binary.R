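#' Binary matrix randomizations
#'
#' `sim2_randomize()` draws one matrix with row sums fixed and columns
#' equiprobable: each species keeps its number of occupied years, placed in a
#' uniform random subset of years. `sim9_randomize()` runs the sequential
#' swap Markov chain with both marginals fixed: each step draws a random
#' (row pair, column pair) and swaps the 2x2 submatrix when it is a
#' checkerboard. Because that proposal is symmetric, the chain samples the
#' fixed-marginal ensemble uniformly; samples are emitted every `thin`
#' attempted swaps after `burn_in` attempts.
#'
#' @param x A `binary_matrix` (or 0/1 matrix).
#' @param n_samples Number of matrices to emit from the swap chain.
#' @param burn_in Attempted swaps discarded before sampling.
#' @param thin Attempted swaps between emitted samples; default
#'   `10 * max(S, T)`.
#' @return `sim2_randomize()`: one 0/1 matrix. `sim9_randomize()`: a list of
#'   `n_samples` 0/1 matrices.
#' @export
sim2_randomize <- function(x) {
  m <- coerce_binary(x)
  cpp_sim2(m)
}

#' @rdname sim2_randomize
#' @export
sim9_randomize <- function(x, n_samples = 1, burn_in = 30000, thin = NULL) {
  m <- coerce_binary(x)
  thin <- thin %||% (10L * max(dim(m)))
  if (!cpp_has_checkerboard(m)) {
    warn("no swappable checkerboard submatrix: SIM9 chain is frozen")
  }
  cpp_sim9_matrices(m, burn_in, thin, n_samples)
}

binary_index_fun <- list(
  CHECKER = function(m) cpp_checker(m),
  C_SCORE = function(m) cpp_cscore(m),
  V_RATIO = function(m) cpp_vratio(m)
)

# Tail pointing to segregation for each binary index: CHECKER and C-score
# high above the null means exclusion; V-ratio low means negative covariance.
binary_seg_tail <- c(CHECKER = "high", C_SCORE = "high", V_RATIO = "low")

# Monte-Carlo tail probabilities with the add-one convention, ties counted
# as "equal or more extreme" in both tails.
mc_tails <- function(observed, null_values) {
  n <- length(null_values)
  list(
    p_low = (1 + sum(null_values <= observed)) / (n + 1),
    p_high = (1 + sum(null_values >= observed)) / (n + 1)
  )
}

new_null_result <- function(observed, null_values, alpha, tails, seg_tail,
                            index, algorithm, model_type, dataset_id,
                            level = "assemblage", guild = NA_character_) {
  pt <- mc_tails(observed, null_values)
  p_two <- min(1, 2 * min(pt$p_low, pt$p_high))
  if (tails == "two") {
    if (p_two < alpha) {
      side <- if (pt$p_high <= pt$p_low) "high" else "low"
      outcome <- if (side == seg_tail) "segregation" else "aggregation"
    } else {
      outcome <- "random"
    }
  } else {
    seg_p <- if (seg_tail == "high") pt$p_high else pt$p_low
    agg_p <- if (seg_tail == "high") pt$p_low else pt$p_high
    stopifnot(!(seg_p < alpha && agg_p < alpha))
    outcome <- if (seg_p < alpha) "segregation"
               else if (agg_p < alpha) "aggregation" else "random"
  }
  structure(
    list(observed = observed, null_values = null_values,
         p_low = pt$p_low, p_high = pt$p_high, p_two = p_two,
         alpha = alpha, tails = tails, outcome = outcome, index = index,
         algorithm = algorithm, model_type = model_type,
         dataset_id = dataset_id, level = level, guild = guild,
         n_sim = length(null_values)),
    class = "null_result"
  )
}

# Shared driver: one pass of null simulation for several binary indices at
# once (SIM9 samples and SIM2 draws are reused across indices).
binary_null_core <- function(x, indices, algorithm, n_sim, alpha, burn_in,
                             thin, level = "assemblage",
                             guild = NA_character_) {
  xb <- binarize(drop_empty(x, "both"))
  m <- xb$values
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("need at least 2 non-empty species rows and 2 non-empty years")
  }
  thin <- thin %||% (10L * max(dim(m)))
  if (algorithm == "SIM9" && "V_RATIO" %in% indices) {
    abort("SIM9 is not applicable with the V-ratio index")
  }
  if (algorithm == "SIM9" && !cpp_has_checkerboard(m)) {
    warn("no swappable checkerboard submatrix: SIM9 chain is frozen")
  }
  all_idx <- c("CHECKER", "C_SCORE", "V_RATIO")
  want <- all_idx %in% indices
  nulls <- cpp_binary_null(m, algorithm, want, n_sim, burn_in, thin)
  lapply(setNames(indices, indices), function(idx) {
    obs <- binary_index_fun[[idx]](m)
    if (idx == "V_RATIO" && is.na(obs)) {
      abort("v_ratio undefined: every species row is constant")
    }
    new_null_result(
      observed = obs, null_values = nulls[, match(idx, all_idx)],
      alpha = alpha, tails = "two", seg_tail = binary_seg_tail[[idx]],
      index = idx, algorithm = algorithm, model_type = "binary",
      dataset_id = xb$dataset_id, level = level, guild = guild
    )
  })
}

#' Run a binary null-model test
#'
#' Computes the observed index, simulates its null distribution under the
#' chosen randomization (fresh draws for SIM2; one long sequential swap chain
#' for SIM9), and classifies the outcome. Tail probabilities use the add-one
#' Monte-Carlo convention, ties counted as equally extreme in both tails; the
#' two-tailed p doubles the smaller tail (capped at 1). Observed CHECKER or
#' C-score above the null signals segregation; observed V-ratio below the
#' null signals segregation. All-zero species rows and year columns are
#' stripped (with a warning) before simulation, since fixed marginals of zero
#' admit only zero rows.
#'
#' @param x An [abundance_matrix()] (binarized automatically) or
#'   `binary_matrix`.
#' @param index One of `"CHECKER"`, `"C_SCORE"`, `"V_RATIO"`.
#' @param algorithm `"SIM2"` (row sums fixed, columns equiprobable) or
#'   `"SIM9"` (both marginals fixed; not applicable with V-ratio).
#' @param n_sim Number of null matrices (10,000 reproduces the reference
#'   protocol).
#' @param alpha Significance level of the two-tailed test.
#' @param burn_in,thin SIM9 chain controls (attempted swaps); `thin` defaults
#'   to `10 * max(S, T)`.
#' @param seed Optional integer seed for a self-contained reproducible run.
#' @param level,guild Labels carried into the outcome record.
#' @return A `null_result`; see [tidy.null_result()].
#' @export
run_binary_null <- function(x, index = c("C_SCORE", "CHECKER", "V_RATIO"),
                            algorithm = c("SIM2", "SIM9"), n_sim = 10000,
                            alpha = 0.05, burn_in = 30000, thin = NULL,
                            seed = NULL, level = "assemblage",
                            guild = NA_character_) {
  index <- match.arg(index)
  algorithm <- match.arg(algorithm)
  run <- function() {
    binary_null_core(x, index, algorithm, n_sim, alpha, burn_in, thin,
                     level, guild)[[index]]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
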