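#' Read a species-by-year matrix from delimited text
#'
#' Expects a header row of year labels, a first column of species labels, and
#' cells that are either non-negative numbers or the literal `"+"` marking a
#' tracing occurrence (a species breeding at a density too low to census).
#' `"+"` cells are flagged and carry value 0 until [impute_tracing()] assigns
#' them a density constant. The delimiter (comma, semicolon, or tab) is
#' autodetected from the header line.
#'
#' @param path Path to a CSV/TSV file.
#' @param plot_size_ha Census plot size in hectares.
#' @param dataset_id Dataset label; defaults to the file name.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, plot_size_ha = 10,
                                  dataset_id = NULL) {
  dataset_id <- dataset_id %||% sub("\\.[^.]*$", "", basename(path))
  header <- readLines(path, n = 1L)
  delim <- detect_delim(header)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  if (ncol(raw) < 3) abort("need at least a species column and two years")
  sp <- as.character(raw[[1]])
  if (anyDuplicated(sp)) {
    abort(paste0("duplicate species label(s): ",
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  tracing <- cells == "+"
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  values[tracing] <- 0
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("cannot parse cell at species '%s', year '%s': '%s'",
                  sp[bad[1, 1]], colnames(raw)[-1][bad[1, 2]],
                  cells[bad[1, 1], bad[1, 2]]))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(sprintf("negative density at species '%s', year '%s'",
                  sp[neg[1, 1]], colnames(raw)[-1][neg[1, 2]]))
  }
  dimnames(values) <- list(sp, colnames(raw)[-1])
  dimnames(tracing) <- dimnames(values)
  abundance_matrix(values, plot_size_ha = plot_size_ha,
                   dataset_id = dataset_id, tracing = tracing)
}

detect_delim <- function(line) {
  counts <- c(`,` = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              `;` = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))),
              `\t` = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))))
  names(counts)[which.max(counts)]
}

#' Write a species-by-year matrix as CSV
#'
#' Tracing-flagged cells are written back as `"+"` so a write/read round trip
#' preserves the tracing record; numeric cells are written at full precision.
#'
#' @param x An [abundance_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  cells <- matrix(format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                  nrow(x$values), ncol(x$values))
  cells[x$tracing] <- "+"
  df <- data.frame(species = rownames(x$values), cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("species", colnames(x$values))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a guild classification table
#'
#' A CSV with columns `species`, `guild`, and optionally `size_class` (body
#' size class used for tracing-density imputation). Guild values must come
#' from the nine recognized categories ([guild_categories]).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per species.
#' @export
read_guild_table <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_guild_table(g)
}

validate_guild_table <- function(g) {
  if (!all(c("species", "guild") %in% names(g))) {
    abort("guild table needs 'species' and 'guild' columns")
  }
  bad <- setdiff(unique(g$guild), guild_categories)
  if (length(bad)) {
    abort(paste0("unknown guild categor(ies): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(g$species)) {
    abort("each species must have exactly one guild")
  }
  if ("size_class" %in% names(g)) {
    bad_sc <- setdiff(unique(stats::na.omit(g$size_class)),
                      names(tracing_constants))
    if (length(bad_sc)) {
      abort(paste0("unknown size class(es): ", paste(bad_sc, collapse = ", ")))
    }
  }
  tibble::as_tibble(g)
}

#' Impute tracing densities
#'
#' Replaces tracing-flagged cells by the assumed density constant for the
#' species' body size class: 0.1 pairs/10 ha for woodpeckers and smaller
#' passerines (`small`), 0.05 for smaller raptors and corvids
#' (`medium_raptor_corvid`), and 0.004 for large raptors (`large_raptor`).
#' Non-tracing cells are never altered.
#'
#' @param x An [abundance_matrix()].
#' @param size_class Either a named character vector (species -> size class)
#'   or a data frame with `species` and `size_class` columns (e.g. a guild
#'   table).
#' @return The matrix with tracing cells filled in (flags are retained so the
#'   tracing record survives, e.g. for [exclude_rare()]).
#' @export
impute_tracing <- function(x, size_class) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (!any(x$tracing)) return(x)
  if (is.data.frame(size_class)) {
    size_class <- setNames(as.character(size_class$size_class),
                           size_class$species)
  }
  need <- rownames(x$values)[rowSums(x$tracing) > 0]
  missing <- setdiff(need, names(size_class)[!is.na(size_class)])
  if (length(missing)) {
    abort(paste0("tracing species without a size class: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(size_class[need]), names(tracing_constants))
  if (length(bad)) {
    abort(paste0("unknown size class(es): ", paste(bad, collapse = ", ")))
  }
  for (sp in need) {
    cells <- x$tracing[sp, ]
    x$values[sp, cells] <- tracing_constants[[size_class[[sp]]]]
  }
  x
}

#' Per-dataset matrix characteristics
#'
#' The seven descriptors used as meta-analysis covariates: plot size, matrix
#' size (rows x columns), number of years, number of species, proportion of
#' zero cells, mean cell density, and coefficient of variation of cell
#' density (sample SD / mean over all cells, zeros included).
#'
#' @param x An [abundance_matrix()].
#' @return A one-row tibble.
#' @export
characteristics <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  v <- x$values
  m <- mean(v)
  if (m == 0) abort("all-zero matrix: CV of density is undefined")
  tibble::tibble(
    dataset_id = x$dataset_id,
    plot_size_ha = x$plot_size_ha,
    n_species = nrow(v),
    n_years = ncol(v),
    matrix_size = nrow(v) * ncol(v),
    prop_zeros = mean(v == 0),
    mean_density = m,
    cv_density = sd(as.vector(v)) / m
  )
}

#' Split an assemblage matrix by foraging guild
#'
#' Partitions the species rows by guild. Guild submatrices with fewer than
#' two species cannot enter a null-model analysis and are flagged.
#'
#' @param x An [abundance_matrix()].
#' @param guilds Guild table (data frame with `species`, `guild`).
#' @return A tibble with one row per guild present: `guild`, `n_species`,
#'   `analyzable`, and a `matrix` list-column of guild submatrices.
#' @export
split_by_guild <- function(x, guilds) {
  stopifnot(inherits(x, "abundance_matrix"))
  guilds <- validate_guild_table(guilds)
  map <- setNames(guilds$guild, guilds$species)
  unmapped <- setdiff(rownames(x$values), names(map))
  if (length(unmapped)) {
    abort(paste0("species not in guild table: ",
                 paste(unmapped, collapse = ", ")))
  }
  gl <- map[rownames(x$values)]
  out <- lapply(split(rownames(x$values), gl), function(sp) {
    sub <- x
    sub$values <- x$values[sp, , drop = FALSE]
    sub$tracing <- x$tracing[sp, , drop = FALSE]
    sub
  })
  tibble::tibble(
    guild = names(out),
    n_species = vapply(out, function(m) nrow(m$values), integer(1)),
    analyzable = vapply(out, function(m) nrow(m$values) >= 2, logical(1)),
    matrix = unname(out)
  )
}

#' Exclude rare (tracing) species
#'
#' Drops every species row that contains any tracing-imputed value, leaving
#' the subset with measurable abundances. Excluding rare species raises the
#' fill of the matrix.
#'
#' @param x An [abundance_matrix()].
#' @return The reduced matrix; errors if fewer than two species remain.
#' @export
exclude_rare <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  keep <- rowSums(x$tracing) == 0
  if (sum(keep) < 2) {
    abort("fewer than 2 species left after excluding tracing species")
  }
  x$values <- x$values[keep, , drop = FALSE]
  x$tracing <- x$tracing[keep, , drop = FALSE]
  x
}
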