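coerce_binary <- function(x) {
  if (inherits(x, "binary_matrix")) return(x$values)
  if (inherits(x, "abundance_matrix")) return(binarize(x)$values)
  m <- as.matrix(x)
  if (!all(m %in% c(0, 1))) abort("matrix must be binary (0/1)")
  storage.mode(m) <- "integer"
  m
}

coerce_numeric <- function(x) {
  if (inherits(x, "abundance_matrix")) return(x$values)
  as.matrix(x)
}

#' Binary co-occurrence indices
#'
#' `checker()` counts the species pairs that never co-occur in any year
#' (perfect checkerboard pairs). `c_score()` is the mean number of
#' checkerboard units per unordered species pair,
#' \eqn{CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})} with \eqn{r} the row totals
#' and \eqn{S_{ij}} the number of shared years. `v_ratio()` is the variance
#' ratio: the variance of the yearly species totals divided by the sum of the
#' per-species occurrence variances (population variances); values below 1
#' indicate negative covariance among species.
#'
#' @param x A `binary_matrix` (an `abundance_matrix` is binarized first) or a
#'   plain 0/1 matrix, species in rows, years in columns.
#' @return A single number (`checker()` returns an integer count).
#' @seealso [run_binary_null()]
#' @export
checker <- function(x) {
  m <- coerce_binary(x)
  if (nrow(m) < 2) abort("need at least 2 species")
  cpp_checker(m)
}

#' @rdname checker
#' @export
c_score <- function(x) {
  m <- coerce_binary(x)
  if (nrow(m) < 2) abort("need at least 2 species")
  cpp_cscore(m)
}

#' @rdname checker
#' @export
v_ratio <- function(x) {
  m <- coerce_binary(x)
  out <- cpp_vratio(m)
  if (is.na(out)) {
    abort("v_ratio undefined: every species row is constant")
  }
  out
}

#' Scale a density matrix to integer counts
#'
#' The individual-based IT and IA randomizations place discrete individuals,
#' so fractional densities are multiplied by `scale_factor` and rounded. The
#' default factor 250 maps the smallest tracing constant (0.004 pairs/10 ha)
#' to exactly one individual. Any positive density that would round to zero
#' is an error (information would be silently lost); increase the factor.
#'
#' @param x An [abundance_matrix()] (or plain matrix).
#' @param scale_factor Positive multiplier applied before rounding.
#' @return A `count_matrix`: the integer matrix plus the scale factor.
#' @export
scale_to_counts <- function(x, scale_factor = 250) {
  if (scale_factor <= 0) abort("scale_factor must be positive")
  v <- coerce_numeric(x)
  counts <- round(v * scale_factor)
  lost <- v > 0 & counts == 0
  if (any(lost)) {
    idx <- which(lost, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "density %.6g at row %d, column %d rounds to 0 at scale_factor %.6g; use a larger factor",
      v[idx[1], idx[2]], idx[1], idx[2], scale_factor))
  }
  storage.mode(counts) <- "integer"
  structure(
    list(values = counts, scale_factor = scale_factor,
         plot_size_ha = if (inherits(x, "abundance_matrix")) x$plot_size_ha else NA_real_,
         dataset_id = if (inherits(x, "abundance_matrix")) x$dataset_id else "matrix"),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix '%s'> %d species x %d years, %d individuals (scale %.6g)\n",
              x$dataset_id, nrow(x$values), ncol(x$values), sum(x$values),
              x$scale_factor))
  print(head(x$values, 6))
  invisible(x)
}

coerce_counts <- function(x) {
  if (inherits(x, "count_matrix")) return(x$values)
  m <- coerce_numeric(x)
  if (any(m != round(m))) {
    abort("matrix must contain integer counts; see scale_to_counts()")
  }
  storage.mode(m) <- "integer"
  m
}

#' Quantitative association indices
#'
#' `ca_aa_scores()` scans all 2x2 species-by-year submatrices: a submatrix is
#' an abundance checkerboard when the two species' abundance differences
#' across the year pair have opposite signs, an aggregation when they have
#' the same sign; ties (either difference zero) count to neither. The
#' standardized scores CA_ST and AA_ST divide the counts by the number of
#' submatrices, so both lie in \[0, 1\] and CA_ST + AA_ST <= 1.
#'
#' `ma_index()` is the multi-community extension of the Morisita-Horn
#' similarity across the year columns: with \eqn{p_{ik}} the relative
#' abundance of species i in year k,
#' \deqn{MA = \sum_i [(\sum_k p_{ik})^2 - \sum_k p_{ik}^2] /
#'       [(T-1) \sum_{ik} p_{ik}^2].}
#' It equals 1 when all years share the same relative composition, 0 when
#' years are completely dissimilar, and reduces to the classical two-sample
#' Morisita-Horn index at T = 2.
#'
#' @param x A `count_matrix`, [abundance_matrix()], or plain non-negative
#'   matrix (ma_index accepts fractional densities).
#' @return `ca_aa_scores()`: a named numeric vector `c(CA_ST, AA_ST)`;
#'   `ma_index()`: a single number.
#' @seealso [run_quant_null()]
#' @export
ca_aa_scores <- function(x) {
  m <- coerce_numeric(if (inherits(x, "count_matrix")) x$values else x)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 species and 2 years")
  out <- cpp_ca_aa(m)
  c(CA_ST = out[1], AA_ST = out[2])
}

#' @rdname ca_aa_scores
#' @export
ma_index <- function(x) {
  m <- coerce_numeric(if (inherits(x, "count_matrix")) x$values else x)
  if (ncol(m) < 2) abort("need at least 2 years")
  if (any(colSums(m) == 0)) abort("every year column must have a positive total")
  cpp_ma(m)
}
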