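# Validate a long-format phenotype table: genotype + numeric value columns,
# optional nesting columns; canonicalizes genotype labels.
validate_phenotype_table <- function(data, universe, nesting = NULL) {
  universe <- as_universe(universe)
  if (!is.data.frame(data)) stop("data must be a data frame", call. = FALSE)
  need <- c("genotype", "value", nesting)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("data lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(data)) stop("data contain no observations", call. = FALSE)
  if (!is.numeric(data$value) || anyNA(data$value)) {
    stop("the value column must be numeric without NAs", call. = FALSE)
  }
  data$genotype <- vapply(seq_len(nrow(data)), function(i) {
    tryCatch(canonical_genotype(data$genotype[i], universe),
             error = function(e) {
               stop(sprintf("row %d: %s", i, conditionMessage(e)),
                    call. = FALSE)
             })
  }, character(1))
  data
}

#' Read a long-format phenotype table
#'
#' Reads delimited text (TSV by default; the delimiter is sniffed from the
#' header when `sep = NULL`) with one row per observation. Required columns
#' are `genotype` (either notation; `"-"` for the fully mutant genotype) and
#' a numeric `value`; a `treatment` column and nesting columns such as
#' `replicate`, `flat`, `pot` pass through after validation. Genotype
#' labels are canonicalized to the omission dialect.
#'
#' @param path Path to the delimited file.
#' @param universe A gene universe.
#' @param dialect Genotype notation: `"auto"` (default), `"full"` or
#'   `"omission"`.
#' @param sep Field separator; `NULL` (default) tries tab, then comma.
#' @return A validated phenotype data frame.
#' @export
read_phenotype_table <- function(path, universe,
                                 dialect = c("auto", "full", "omission"),
                                 sep = NULL) {
  universe <- as_universe(universe)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    if (!length(header)) stop("empty file: ", path, call. = FALSE)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("genotype", "value") %in% names(raw))) {
    stop("file must have 'genotype' and 'value' columns", call. = FALSE)
  }
  if (!is.numeric(raw$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$value))))
    stop("non-numeric value(s) at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  raw$genotype <- vapply(seq_len(nrow(raw)), function(i) {
    tryCatch(canonical_genotype(raw$genotype[i], universe, dialect = dialect),
             error = function(e) {
               stop(sprintf("%s, data row %d: %s", basename(path), i,
                            conditionMessage(e)), call. = FALSE)
             })
  }, character(1))
  raw
}

#' Write a coefficient table
#'
#' Writes fitted or solved coefficients as delimited text with a
#' deterministic row order (intercept first, then terms by order and
#' lexicographic position). Multi-gene term labels carry the family's
#' interaction operator (`";"` averaging, `":"` additive/NR).
#'
#' @param table An `"avg_coef"` / `"avg_coef_table"` data frame.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(table, path, sep = "\t") {
  stopifnot(is.data.frame(table))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a written coefficient table
#'
#' @param path Path written by [write_coefficient_table()].
#' @param sep Field separator (tab by default).
#' @return A data frame with the stored columns.
#' @export
read_coefficient_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a stability-study summary
#'
#' @param summary An `"avg_study"` data frame from [run_uniform_study()].
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, sep = "\t") {
  stopifnot(is.data.frame(summary))
  utils::write.table(as.data.frame(summary), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mean table
#'
#' Two-column delimited text (`genotype`, `mean`) in canonical genotype
#' order, the input format of the `solve` command-line subcommand.
#'
#' @param means A complete named mean vector.
#' @param universe A gene universe.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_mean_table <- function(means, universe, path, sep = "\t") {
  y <- align_means(means, universe)
  utils::write.table(data.frame(genotype = names(y), mean = unname(y)),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mean table
#'
#' @param path Two-column delimited file (`genotype`, `mean`).
#' @param universe A gene universe.
#' @param sep Field separator; `NULL` sniffs tab vs comma.
#' @return Named numeric vector over the canonical genotypes.
#' @export
read_mean_table <- function(path, universe, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("genotype", "mean") %in% names(raw))) {
    stop("mean table must have 'genotype' and 'mean' columns", call. = FALSE)
  }
  y <- raw$mean
  names(y) <- raw$genotype
  align_means(y, universe)
}
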