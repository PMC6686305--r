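#' Construct a species-by-year abundance matrix
#'
#' The basic container for a community time series: a non-negative
#' species-by-year matrix of breeding densities (pairs per 10 ha), a parallel
#' logical matrix flagging cells recorded only as tracing ("+") occurrences,
#' the census plot size, and a dataset label.
#'
#' @param values Numeric matrix, species in rows, years in columns. Row names
#'   are species labels; column names are year labels (coercible to integer,
#'   strictly increasing).
#' @param plot_size_ha Positive census plot size in hectares.
#' @param dataset_id Dataset label.
#' @param tracing Logical matrix of the same dimension marking tracing cells;
#'   defaults to no tracing.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, plot_size_ha = 10, dataset_id = "dataset",
                             tracing = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sp", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- as.character(seq_len(ncol(values)))
  }
  if (is.null(tracing)) {
    tracing <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  x <- structure(
    list(values = values, tracing = tracing,
         plot_size_ha = plot_size_ha, dataset_id = dataset_id),
    class = "abundance_matrix"
  )
  validate_abundance_matrix(x)
}

validate_abundance_matrix <- function(x) {
  v <- x$values
  if (!is.numeric(v)) abort("matrix values must be numeric")
  if (anyNA(v)) abort("matrix values must not contain NA")
  if (any(v < 0)) abort("matrix values must be non-negative")
  if (!identical(dim(x$tracing), dim(v))) {
    abort("tracing flags must match the matrix dimensions")
  }
  if (anyDuplicated(rownames(v))) {
    abort(paste0("duplicate species labels: ",
                 paste(unique(rownames(v)[duplicated(rownames(v))]),
                       collapse = ", ")))
  }
  yrs <- suppressWarnings(as.integer(colnames(v)))
  if (anyNA(yrs)) abort("year labels must be integers")
  if (ncol(v) > 1 && any(diff(yrs) <= 0)) {
    abort("year labels must be strictly increasing")
  }
  if (!is.numeric(x$plot_size_ha) || x$plot_size_ha <= 0) {
    abort("plot_size_ha must be a positive number")
  }
  x
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "<abundance_matrix '%s'> %d species x %d years, plot %.7g ha, %d tracing cells\n",
    x$dataset_id, nrow(x$values), ncol(x$values), x$plot_size_ha,
    sum(x$tracing)))
  print(head(x$values, 6))
  if (nrow(x$values) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Species and year labels of a community matrix
#'
#' @param x An `abundance_matrix` or `binary_matrix`.
#' @return Character vector of species labels, or integer years.
#' @export
species <- function(x) rownames(x$values)

#' @rdname species
#' @export
years <- function(x) as.integer(colnames(x$values))

#' @importFrom tibble as_tibble
#' @export
as_tibble.abundance_matrix <- function(x, ...) {
  tibble::tibble(
    dataset_id = x$dataset_id,
    species = rep(rownames(x$values), times = ncol(x$values)),
    year = rep(years(x), each = nrow(x$values)),
    density = as.vector(x$values),
    tracing = as.vector(x$tracing)
  )
}

#' Convert an abundance matrix to presence/absence
#'
#' A cell becomes 1 exactly when the density is positive. Applying
#' `binarize()` to an already binary matrix is a no-op.
#'
#' @param x An `abundance_matrix` or `binary_matrix`.
#' @return A `binary_matrix` with the same labels and metadata.
#' @export
binarize <- function(x) {
  if (inherits(x, "binary_matrix")) return(x)
  stopifnot(inherits(x, "abundance_matrix"))
  b <- x
  b$values <- matrix(as.integer(x$values > 0), nrow(x$values), ncol(x$values),
                     dimnames = dimnames(x$values))
  class(b) <- c("binary_matrix", "abundance_matrix")
  b
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("<binary_matrix '%s'> %d species x %d years, fill %.2f\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              mean(x$values > 0)))
  print(head(x$values, 6))
  if (nrow(x$values) > 6) cat("...\n")
  invisible(x)
}

# Strip all-zero rows (and columns) before a null-model run; degenerate
# marginals of zero admit only zero rows under fixed-marginal algorithms.
drop_empty <- function(x, what = c("rows", "both")) {
  what <- match.arg(what)
  keep_r <- rowSums(x$values) > 0
  if (!all(keep_r)) {
    warn(sprintf("dropping %d all-zero species row(s) from '%s'",
                 sum(!keep_r), x$dataset_id))
    x$values <- x$values[keep_r, , drop = FALSE]
    x$tracing <- x$tracing[keep_r, , drop = FALSE]
  }
  if (what == "both") {
    keep_c <- colSums(x$values) > 0
    if (!all(keep_c)) {
      warn(sprintf("dropping %d all-zero year column(s) from '%s'",
                   sum(!keep_c), x$dataset_id))
      x$values <- x$values[, keep_c, drop = FALSE]
      x$tracing <- x$tracing[, keep_c, drop = FALSE]
    }
  }
  x
}
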