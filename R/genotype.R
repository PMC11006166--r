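#' Define a gene universe
#'
#' A gene universe is an ordered set of single-letter gene labels. Each gene
#' has two allele states: active (wild type, written upper case) and inactive
#' (null mutant, written lower case). A genotype is the subset of genes
#' carrying the active allele.
#'
#' @param genes Either a single string of unique upper-case letters
#'   (e.g. `"JEPS"`) or a character vector of single letters.
#' @return A character vector of upper-case gene labels with class
#'   `"avg_universe"`.
#' @examples
#' gene_universe("ABC")
#' gene_universe(c("J", "E", "P", "S"))
#' @export
gene_universe <- function(genes) {
  if (length(genes) == 1L && nchar(genes) > 1L) {
    genes <- strsplit(genes, "")[[1]]
  }
  genes <- as.character(genes)
  if (length(genes) < 1L || length(genes) > 16L) {
    stop("a gene universe must contain between 1 and 16 genes", call. = FALSE)
  }
  if (any(nchar(genes) != 1L) || any(!grepl("^[A-Za-z]$", genes))) {
    stop("gene labels must be single alphabetical characters", call. = FALSE)
  }
  genes <- toupper(genes)
  if (anyDuplicated(genes)) {
    stop("gene labels must be unique (case-insensitively)", call. = FALSE)
  }
  structure(genes, class = "avg_universe")
}

# Coerce to a validated universe; accepts a string, vector or avg_universe.
as_universe <- function(universe) {
  if (inherits(universe, "avg_universe")) return(universe)
  gene_universe(universe)
}

#' @export
print.avg_universe <- function(x, ...) {
  cat("Gene universe:", paste(unclass(x), collapse = ""),
      sprintf("(%d genes, %d genotypes)\n", length(x), 2L^length(x)))
  invisible(x)
}

#' Parse genotype strings
#'
#' Two notations are supported. In the full dialect every gene is written,
#' with case encoding the allele state: `"ABc"` is the genotype with genes A
#' and B active and C mutant. In the omission dialect only the active genes
#' are written (`"AB"`), with `"-"` (or the empty string) denoting the
#' fully mutant genotype. By default the dialect is detected per token: a
#' string is read as full dialect if and only if its length equals the number
#' of genes and its letters match the universe order case-insensitively.
#'
#' @param text Character vector of genotype strings.
#' @param universe A gene universe (see [gene_universe()]).
#' @param dialect `"auto"` (default), `"full"` or `"omission"` to force a
#'   notation.
#' @return A list with one character vector per input token, each holding the
#'   active gene labels in universe order. For a single token the list is
#'   dropped to a plain character vector.
#' @examples
#' u <- gene_universe("ABC")
#' parse_genotype("ABc", u)   # full dialect: A, B active
#' parse_genotype("AB", u)    # omission dialect: same genotype
#' parse_genotype("-", u)     # fully mutant
#' @export
parse_genotype <- function(text, universe, dialect = c("auto", "full", "omission")) {
  universe <- as_universe(universe)
  dialect <- match.arg(dialect)
  out <- lapply(as.character(text), parse_one_genotype,
                universe = universe, dialect = dialect)
  if (length(out) == 1L) out[[1]] else out
}

parse_one_genotype <- function(token, universe, dialect) {
  n <- length(universe)
  if (is.na(token)) stop("genotype string is NA", call. = FALSE)
  if (dialect == "auto") {
    chars <- strsplit(token, "")[[1]]
    full <- nchar(token) == n && all(toupper(chars) == unclass(universe))
    dialect <- if (full) "full" else "omission"
  }
  if (dialect == "full") {
    chars <- strsplit(token, "")[[1]]
    if (length(chars) != n) {
      stop(sprintf("full-dialect genotype '%s' must have one character per gene (%d)",
                   token, n), call. = FALSE)
    }
    if (!all(toupper(chars) == unclass(universe))) {
      stop(sprintf("full-dialect genotype '%s' does not follow universe order %s",
                   token, paste(unclass(universe), collapse = "")), call. = FALSE)
    }
    return(unclass(universe)[chars == unclass(universe)])
  }
  # omission dialect
  if (token == "-" || token == "") return(character(0))
  chars <- strsplit(token, "")[[1]]
  if (any(!chars %in% unclass(universe))) {
    bad <- setdiff(chars, unclass(universe))
    stop(sprintf("genotype '%s' contains gene(s) not in universe %s: %s",
                 token, paste(unclass(universe), collapse = ""),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(chars)) {
    stop(sprintf("genotype '%s' lists a gene more than once", token), call. = FALSE)
  }
  unclass(universe)[unclass(universe) %in% chars]
}

#' Format a genotype as text
#'
#' Inverse of [parse_genotype()]. The canonical form used throughout the
#' package is the omission dialect with genes in universe order and `"-"`
#' for the fully mutant genotype.
#'
#' @param active Character vector of active gene labels (or a list of them).
#' @param universe A gene universe.
#' @param dialect `"omission"` (default) or `"full"`.
#' @return Character vector of genotype strings.
#' @export
format_genotype <- function(active, universe, dialect = c("omission", "full")) {
  universe <- as_universe(universe)
  dialect <- match.arg(dialect)
  if (!is.list(active)) active <- list(active)
  vapply(active, function(a) {
    a <- unclass(universe)[unclass(universe) %in% a]
    if (dialect == "full") {
      chars <- ifelse(unclass(universe) %in% a,
                      unclass(universe), tolower(unclass(universe)))
      paste(chars, collapse = "")
    } else if (length(a) == 0L) "-" else paste(a, collapse = "")
  }, character(1))
}

# Canonicalize a vector of genotype strings to omission-dialect labels.
canonical_genotype <- function(text, universe, dialect = "auto") {
  universe <- as_universe(universe)
  sets <- lapply(as.character(text), parse_one_genotype,
                 universe = universe, dialect = dialect)
  format_genotype(sets, universe)
}

#' Enumerate all combinatorial genotypes
#'
#' Lists the 2^n exhaustively combinatorial genotypes of an n-gene system in
#' canonical order: by number of active genes, then lexicographically by gene
#' position within the universe. The first genotype is the fully mutant
#' (most disrupted) state and the last is the all-wild-type state.
#'
#' @param universe A gene universe.
#' @return Character vector of 2^n canonical genotype labels.
#' @examples
#' enumerate_genotypes(gene_universe("ABC"))
#' @export
enumerate_genotypes <- function(universe) {
  universe <- as_universe(universe)
  format_genotype(enumerate_subsets(universe, length(universe), include_empty = TRUE),
                  universe)
}

# All subsets of the universe with 0 (optionally) < |S| <= max_order, in
# canonical (order, lexicographic) order. Returns a list of character vectors.
enumerate_subsets <- function(universe, max_order, include_empty = FALSE) {
  genes <- unclass(as_universe(universe))
  out <- if (include_empty) list(character(0)) else list()
  for (k in seq_len(max_order)) {
    combos <- utils::combn(genes, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}
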