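#' Specify a model family over a gene universe
#'
#' The three families are reparameterizations of the genotype cell-means
#' model and differ only in how a genotype's fitted value is decomposed into
#' gene effects and interactions:
#'
#' * `additive` -- classical ANOVA with interaction: a genotype's mean is the
#'   unweighted sum of the effects and interactions of all subsets of its
#'   active genes.
#' * `nr` -- network reconstitution model: interaction terms of each order
#'   >= 2 are averaged within the order, while 1-gene effects are summed.
#' * `averaging` -- the averaging principle applied at every order: terms of
#'   order k enter a genotype of m active genes with weight 1/choose(m, k).
#'   Equivalently, each coefficient is the deviation of its genotype from the
#'   average of the genotypes with one fewer active gene.
#'
#' @param family `"additive"`, `"nr"` or `"averaging"`.
#' @param universe A gene universe (see [gene_universe()]).
#' @param max_order Highest interaction order retained; defaults to the full
#'   model (`max_order = n`). Reduced models (`max_order < n`) are fit by
#'   least squares rather than solved exactly.
#' @return An object of class `"avg_model_spec"`.
#' @examples
#' model_spec("averaging", "JEPS")
#' model_spec("additive", "ABC", max_order = 2)
#' @export
model_spec <- function(family = c("averaging", "additive", "nr"),
                       universe, max_order = NULL) {
  family <- match.arg(family)
  universe <- as_universe(universe)
  n <- length(universe)
  if (is.null(max_order)) max_order <- n
  max_order <- as.integer(max_order)
  if (max_order < 1L || max_order > n) {
    stop(sprintf("max_order must be in [1, %d]", n), call. = FALSE)
  }
  structure(list(family = family, universe = universe, max_order = max_order),
            class = "avg_model_spec")
}

#' @export
print.avg_model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s family, genes %s, interactions up to order %d%s\n",
              x$family, paste(unclass(x$universe), collapse = ""), x$max_order,
              if (x$max_order == length(x$universe)) " (full model)" else ""))
  invisible(x)
}

# Interaction operator per family: ";" marks averaging interactions, ":"
# additive/NR interactions.
term_sep <- function(family) if (family == "averaging") ";" else ":"

#' Model term labels
#'
#' Terms are the nonempty subsets of the universe with size up to
#' `max_order`, in canonical (order, lexicographic) order. Multi-gene terms
#' are joined with `";"` for the averaging family and `":"` otherwise; the
#' intercept is not a term.
#'
#' @param spec A model spec.
#' @return Character vector of term labels.
#' @examples
#' term_labels(model_spec("averaging", "ABC"))
#' @export
term_labels <- function(spec) {
  stopifnot(inherits(spec, "avg_model_spec"))
  subsets <- enumerate_subsets(spec$universe, spec$max_order)
  vapply(subsets, paste, character(1), collapse = term_sep(spec$family))
}

# Split a term label back into its gene subset.
term_genes <- function(label, family) {
  strsplit(label, term_sep(family), fixed = TRUE)
}

#' Model weight of a term within a genotype
#'
#' The weight with which a term of order `k` contributes to the fitted value
#' of a genotype with `m` active genes (for terms that are subsets of the
#' genotype's active set; other terms contribute 0):
#'
#' * additive: 1;
#' * averaging: 1 / choose(m, k);
#' * NR: 1 for 1-gene effects, 1 / choose(m, k) for interactions.
#'
#' The averaging weight is the closed form of the recursion
#' w(m, m) = 1, w(k, m) = ((m - k) / m) w(k, m - 1), which encodes each
#' coefficient as a deviation from the average of the genotypes with one
#' fewer active gene.
#'
#' @param family `"additive"`, `"nr"` or `"averaging"`.
#' @param k Term order (subset size), `1 <= k <= m`. Vectorized.
#' @param m Genotype order (number of active genes). Vectorized.
#' @return Numeric vector of weights.
#' @examples
#' model_weight("averaging", 1, 3)  # 1/3
#' model_weight("nr", 2, 3)         # 1/3
#' model_weight("additive", 3, 7)   # 1
#' @export
model_weight <- function(family = c("averaging", "additive", "nr"), k, m) {
  family <- match.arg(family)
  k <- as.integer(k); m <- as.integer(m)
  if (any(k < 1L)) stop("term order k must be >= 1", call. = FALSE)
  if (any(k > m)) stop("term order k cannot exceed genotype order m", call. = FALSE)
  switch(family,
    additive  = rep(1, length(pmax(k, m))),
    averaging = 1 / choose(m, k),
    nr        = ifelse(k == 1L, 1, 1 / choose(m, k))
  )
}

#' Build the model matrix of a family
#'
#' Rows are the 2^n genotypes in canonical order; columns are the intercept
#' followed by the model terms. The entry for genotype G and term T is
#' `model_weight(family, |T|, |active(G)|)` when T is a subset of G's active
#' genes and 0 otherwise. For the full model (`max_order = n`) the matrix is
#' lower triangular with unit diagonal under the canonical ordering, hence
#' invertible.
#'
#' @param spec A model spec (see [model_spec()]).
#' @return Numeric matrix with genotype row names and
#'   `c("(Intercept)", term_labels(spec))` column names.
#' @examples
#' build_model_matrix(model_spec("averaging", "AB"))
#' @export
build_model_matrix <- function(spec) {
  stopifnot(inherits(spec, "avg_model_spec"))
  n <- length(spec$universe)
  if (n > 12L) {
    stop("dense model matrices are limited to 12 genes (4096 genotypes)",
         call. = FALSE)
  }
  genosets <- enumerate_subsets(spec$universe, n, include_empty = TRUE)
  termsets <- enumerate_subsets(spec$universe, spec$max_order)
  labels <- term_labels(spec)
  M <- matrix(0, nrow = length(genosets), ncol = 1L + length(termsets),
              dimnames = list(format_genotype(genosets, spec$universe),
                              c("(Intercept)", labels)))
  M[, 1L] <- 1
  m_order <- lengths(genosets)
  for (j in seq_along(termsets)) {
    term <- termsets[[j]]
    k <- length(term)
    hit <- vapply(genosets, function(g) all(term %in% g), logical(1))
    M[hit, j + 1L] <- model_weight(spec$family, k, m_order[hit])
  }
  M
}
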