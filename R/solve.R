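#' Exact coefficient solving on a complete genotype lattice
#'
#' Converts the 2^n genotype phenotype means of a full model into the unique
#' coefficient vector of the chosen family, by forward substitution on the
#' lower-triangular model matrix. The intercept is the phenotype of the
#' fully mutant (most disrupted) genotype, the reference state of all three
#' families in wild-type-allele coding.
#'
#' @param spec A full model spec (`max_order = n`).
#' @param means A mean table: named numeric vector with one genotype label
#'   per name (any dialect), covering every genotype exactly once.
#' @return A data frame of class `"avg_coef"` with columns `term`, `order`
#'   (0 for the intercept) and `estimate`.
#' @seealso [predict_means()] for the inverse, [averaging_coef_direct()] and
#'   [mobius_additive_oracle()] for single-term closed forms.
#' @examples
#' u <- gene_universe("AB")
#' means <- c("-" = 2, "A" = 3, "B" = 5, "AB" = 9)
#' solve_means(model_spec("additive", u), means)
#' @export
solve_means <- function(spec, means) {
  stopifnot(inherits(spec, "avg_model_spec"))
  n <- length(spec$universe)
  if (spec$max_order != n) {
    stop("solve_means requires the full model (max_order = n); ",
         "fit reduced models with fit_fixed()", call. = FALSE)
  }
  y <- align_means(means, spec$universe)
  M <- build_model_matrix(spec)
  est <- forwardsolve(M, y)
  new_coef(spec, est)
}

# Validate and order a named mean vector along the canonical genotype
# enumeration; errors on missing or duplicated genotypes.
align_means <- function(means, universe) {
  if (is.null(names(means))) {
    stop("means must be a named vector (names = genotype labels)", call. = FALSE)
  }
  labs <- canonical_genotype(names(means), universe)
  if (anyDuplicated(labs)) {
    stop("duplicated genotype(s) in mean table: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  want <- enumerate_genotypes(universe)
  missing <- setdiff(want, labs)
  if (length(missing)) {
    stop("mean table is incomplete; missing genotype(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(means)[match(want, labs)]
  names(y) <- want
  y
}

new_coef <- function(spec, estimate, extra = NULL) {
  labels <- term_labels(spec)
  out <- data.frame(
    term = c("(Intercept)", labels),
    order = c(0L, lengths(enumerate_subsets(spec$universe, spec$max_order))),
    estimate = as.numeric(estimate),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) out <- cbind(out, extra)
  attr(out, "spec") <- spec
  class(out) <- c("avg_coef", "data.frame")
  out
}

#' @export
print.avg_coef <- function(x, digits = 4, ...) {
  spec <- attr(x, "spec")
  if (!is.null(spec)) {
    cat(sprintf("%s-model coefficients (genes %s, up to order %d)\n",
                spec$family, paste(unclass(spec$universe), collapse = ""),
                spec$max_order))
  }
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Predict genotype means from coefficients
#'
#' Inverse of [solve_means()]: the matrix-vector product of the model matrix
#' with a coefficient vector, giving the modeled phenotype of every
#' genotype.
#'
#' @param spec A model spec.
#' @param coefficients An `"avg_coef"` data frame, or a named numeric vector
#'   whose names are `"(Intercept)"` and the spec's term labels.
#' @return Named numeric vector of 2^n genotype means in canonical order.
#' @export
predict_means <- function(spec, coefficients) {
  stopifnot(inherits(spec, "avg_model_spec"))
  if (inherits(coefficients, "avg_coef") || is.data.frame(coefficients)) {
    est <- coefficients$estimate
    names(est) <- coefficients$term
    coefficients <- est
  }
  want <- c("(Intercept)", term_labels(spec))
  if (!setequal(names(coefficients), want) ||
      length(coefficients) != length(want)) {
    stop("coefficient names do not match the model's term list", call. = FALSE)
  }
  M <- build_model_matrix(spec)
  drop(M %*% coefficients[want])
}

#' Averaging coefficient from its defining deviation
#'
#' The averaging coefficient of a gene set S is defined directly on observed
#' means: the phenotype of the genotype with exactly S active, minus the
#' average phenotype of the |S| genotypes obtained by inactivating one gene
#' of S (mutant background fixed). For a single gene this is the difference
#' from the fully mutant state. It equals the corresponding entry of
#' `solve_means()` for the averaging family.
#'
#' @param subset Character vector of gene labels (nonempty).
#' @param means A mean table covering at least the genotypes of orders
#'   `|S|` and `|S| - 1` within S.
#' @param universe A gene universe.
#' @return The averaging coefficient (numeric scalar).
#' @examples
#' u <- gene_universe("AB")
#' means <- c("-" = 2, "A" = 3, "B" = 5, "AB" = 9)
#' averaging_coef_direct(c("A", "B"), means, u)  # 9 - (3 + 5) / 2
#' @export
averaging_coef_direct <- function(subset, means, universe) {
  universe <- as_universe(universe)
  subset <- unclass(universe)[unclass(universe) %in% subset]
  if (length(subset) < 1L) stop("subset must be nonempty", call. = FALSE)
  labs <- canonical_genotype(names(means), universe)
  val <- function(set) {
    lab <- format_genotype(set, universe)
    i <- match(lab, labs)
    if (is.na(i)) stop("mean table lacks genotype ", lab, call. = FALSE)
    as.numeric(means)[i]
  }
  parents <- lapply(seq_along(subset), function(i) subset[-i])
  val(subset) - mean(vapply(parents, val, numeric(1)))
}

#' Additive coefficient by Moebius inversion
#'
#' Independent closed form for the additive (ANOVA-with-interaction)
#' coefficient of a gene set S in wild-type-allele coding:
#' inclusion-exclusion over the subset lattice,
#' `coef(S) = sum over T subsets of S of (-1)^(|S| - |T|) mean(T)`.
#' Used as a cross-check of the triangular solve.
#'
#' @inheritParams averaging_coef_direct
#' @return The additive coefficient (numeric scalar).
#' @export
mobius_additive_oracle <- function(subset, means, universe) {
  universe <- as_universe(universe)
  subset <- unclass(universe)[unclass(universe) %in% subset]
  labs <- canonical_genotype(names(means), universe)
  vals <- as.numeric(means)
  total <- 0
  for (k in 0:length(subset)) {
    subs <- if (k == 0L) list(character(0)) else
      utils::combn(subset, k, simplify = FALSE)
    sign <- (-1)^(length(subset) - k)
    for (s in subs) {
      i <- match(format_genotype(s, universe), labs)
      if (is.na(i)) stop("mean table lacks genotype ",
                         format_genotype(s, universe), call. = FALSE)
      total <- total + sign * vals[i]
    }
  }
  total
}

#' Recode a mean table to mutant-allele reference
#'
#' Relabels every genotype by its complement, so that "active" comes to mean
#' "carries the mutant allele" and the reference (empty) genotype becomes
#' the all-wild-type state. Solving the additive model on the recoded table
#' yields the classical mutant-allele effects (a, b, c, ...) contrasted
#' against the wild type. The operation is an involution.
#'
#' @param means A complete mean table.
#' @param universe A gene universe.
#' @return A mean table with complemented genotype labels, in canonical
#'   order of the recoded labels.
#' @export
recode_to_mutant <- function(means, universe) {
  universe <- as_universe(universe)
  y <- align_means(means, universe)
  sets <- lapply(names(y), parse_one_genotype, universe = universe,
                 dialect = "omission")
  comp <- lapply(sets, function(s) setdiff(unclass(universe), s))
  names(y) <- format_genotype(comp, universe)
  align_means(y, universe)
}
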