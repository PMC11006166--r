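#' Screen genes for inclusion in the model
#'
#' A gene belongs in the analysis only if it measurably moves the phenotype
#' in at least one genotype context. For each gene g and every background
#' B (a subset of the remaining genes), the screen t-tests the difference of
#' cell means between the genotype with g active on that background and the
#' background itself -- 2^(n-1) contrasts per gene, e.g. for gene C in a
#' 3-gene system: ABC-AB, AC-A, BC-B and C-(fully mutant). Contrast
#' estimates and standard errors come from a one-mean-per-genotype
#' cell-means fit (with nested random intercepts when `nesting` is given).
#' p-values are Benjamini-Hochberg adjusted and a gene is dropped when none
#' of its adjusted p-values fall below `alpha`.
#'
#' @param data A phenotype table over a complete genotype lattice.
#' @param universe A gene universe.
#' @param alpha Significance level for the keep/drop decision (default 0.05).
#' @param nesting Optional nesting columns for a mixed cell-means fit.
#' @param bh_scope Family over which BH adjusts: `"gene"` (default; each
#'   gene's 2^(n-1) contrasts form one family) or `"dataset"` (all
#'   contrasts of all genes together).
#' @return An object of class `"avg_screen"`: a data frame of contrasts
#'   (`gene`, `background`, `with_gene`, `estimate`, `se`, `t`, `p`,
#'   `p_bh`), with the per-gene keep/drop decisions in attribute
#'   `"decision"` (named logical, `TRUE` = keep).
#' @examples
#' spec <- model_spec("averaging", "ABC")
#' truth <- solve_means(spec, network_means(six_node_network()))
#' dat <- generate_replicated_data(synth_config(spec, truth), seed = 1)
#' scr <- screen_genes(dat, "ABC")
#' kept_genes(scr)
#' @export
screen_genes <- function(data, universe, alpha = 0.05, nesting = NULL,
                         bh_scope = c("gene", "dataset")) {
  universe <- as_universe(universe)
  bh_scope <- match.arg(bh_scope)
  data <- validate_phenotype_table(data, universe, nesting = nesting)
  labs <- check_lattice(model_spec("additive", universe), data$genotype)
  all_geno <- enumerate_genotypes(universe)
  cm <- cellmeans_fit(data, labs, all_geno, nesting)

  genes <- unclass(universe)
  others <- lapply(genes, function(g) setdiff(genes, g))
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    oth <- others[[i]]
    backs <- list(character(0))
    for (k in seq_along(oth)) {
      backs <- c(backs, utils::combn(oth, k, simplify = FALSE))
    }
    for (B in backs) {
      lab_with <- format_genotype(sort_genes(c(B, g), universe), universe)
      lab_wo <- format_genotype(B, universe)
      iw <- match(lab_with, all_geno); io <- match(lab_wo, all_geno)
      est <- cm$mu[iw] - cm$mu[io]
      se <- sqrt(cm$vc[iw, iw] + cm$vc[io, io] - 2 * cm$vc[iw, io])
      tval <- est / se
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, background = lab_wo, with_gene = lab_with,
        estimate = est, se = se, t = tval,
        p = 2 * stats::pt(abs(tval), cm$df, lower.tail = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (bh_scope == "dataset") {
    res$p_bh <- bh_adjust(res$p)
  } else {
    res$p_bh <- stats::ave(res$p, res$gene, FUN = bh_adjust)
  }
  decision <- tapply(res$p_bh < alpha, res$gene, any)[genes]
  attr(res, "decision") <- decision
  attr(res, "alpha") <- alpha
  attr(res, "universe") <- universe
  class(res) <- c("avg_screen", "data.frame")
  res
}

sort_genes <- function(x, universe) unclass(universe)[unclass(universe) %in% x]

# One-mean-per-genotype fit returning cell means, their covariance and the
# residual df; mixed (lme) when nesting columns are supplied.
cellmeans_fit <- function(data, labs, all_geno, nesting) {
  geno <- factor(labs, levels = all_geno)
  if (is.null(nesting)) {
    fit <- stats::lm(data$value ~ 0 + geno)
    mu <- unname(stats::coef(fit))
    vc <- stats::vcov(fit)
    df <- fit$df.residual
  } else {
    dd <- data.frame(.value = data$value, geno = geno)
    for (g in nesting) dd[[g]] <- factor(data[[g]])
    random <- stats::as.formula(paste("~ 1 |", paste(nesting, collapse = "/")))
    fit <- nlme::lme(.value ~ 0 + geno, random = random, data = dd,
                     method = "REML")
    mu <- unname(nlme::fixef(fit))
    vc <- as.matrix(stats::vcov(fit))
    df <- nrow(dd) - length(mu)
  }
  list(mu = mu, vc = vc, df = df)
}

#' Genes kept by a screen
#'
#' @param screen An `"avg_screen"` result.
#' @return Character vector of gene labels whose keep decision was `TRUE`.
#' @export
kept_genes <- function(screen) {
  stopifnot(inherits(screen, "avg_screen"))
  d <- attr(screen, "decision")
  names(d)[d]
}

#' @export
print.avg_screen <- function(x, digits = 4, ...) {
  d <- attr(x, "decision")
  cat("Gene-inclusion screen (alpha =", attr(x, "alpha"), ")\n")
  cat("  keep:", paste(names(d)[d], collapse = ", "), "\n")
  if (any(!d)) cat("  drop:", paste(names(d)[!d], collapse = ", "), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Bundle observations over an insignificant gene
#'
#' Collapses the genotype lattice over one gene by relabeling every
#' observation's genotype without it, treating the gene's two allele states
#' as equivalent: observations of the genotype with the gene active become
#' part of the corresponding genotype without it. No observations are
#' discarded. The operation is lossy (the removed gene's allele state is
#' forgotten) and therefore irreversible.
#'
#' @param data A phenotype table.
#' @param gene Single gene label to remove.
#' @param universe The gene universe of `data`.
#' @return The phenotype table with `genotype` relabeled over the reduced
#'   universe; attach the reduced universe as attribute `"universe"`.
#' @examples
#' dat <- data.frame(genotype = c("JEPS", "EPS", "J", "-"), value = 1:4)
#' bundle_gene(dat, "J", "JEPS")$genotype  # "EPS" "EPS" "-" "-"
#' @export
bundle_gene <- function(data, gene, universe) {
  universe <- as_universe(universe)
  if (length(gene) != 1L || !gene %in% unclass(universe)) {
    stop("gene must be one label of the universe", call. = FALSE)
  }
  data <- validate_phenotype_table(data, universe)
  reduced <- gene_universe(setdiff(unclass(universe), gene))
  sets <- lapply(data$genotype, parse_one_genotype, universe = universe,
                 dialect = "auto")
  sets <- lapply(sets, setdiff, y = gene)
  data$genotype <- format_genotype(sets, reduced)
  attr(data, "universe") <- reduced
  data
}

#' Holm and Benjamini-Hochberg p-value adjustment
#'
#' Thin validated wrappers around [stats::p.adjust()]: `holm_adjust()` is
#' the step-down family-wise correction applied to the term p-values of one
#' fit; `bh_adjust()` is the step-up false-discovery-rate correction applied
#' to the contrast p-values of a gene screen.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, capped at 1, in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
holm_adjust <- function(p) {
  check_p(p)
  stats::p.adjust(p, method = "holm")
}

#' @rdname holm_adjust
#' @export
bh_adjust <- function(p) {
  check_p(p)
  stats::p.adjust(p, method = "BH")
}

check_p <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Within-genotype treatment contrasts
#'
#' Reduces a two-level treatment design to the quantity of interest: for
#' each genotype (within each nesting cell, when nesting columns are
#' present) the difference `treated - control` of the cell means. The
#' result is a phenotype table whose `value` column holds the contrasts, so
#' downstream fitting models the genotype-specific treatment response;
#' genotype baseline levels and shared group intercepts cancel in the
#' differencing.
#'
#' @param data A phenotype table with a two-level `treatment` column in
#'   which every genotype (and nesting cell) is observed under both levels.
#' @param control Label of the reference level; the other observed level is
#'   taken as treated.
#' @param nesting Optional nesting columns preserved through the pairing.
#' @return A phenotype table of contrasts (one row per genotype x nesting
#'   cell). Without a `treatment` column the data are returned unchanged.
#' @export
treatment_contrast <- function(data, control, nesting = NULL) {
  if (!"treatment" %in% names(data)) return(data)
  levels_seen <- unique(data$treatment)
  if (length(levels_seen) != 2L) {
    stop("treatment must have exactly two levels; found: ",
         paste(levels_seen, collapse = ", "), call. = FALSE)
  }
  if (!control %in% levels_seen) {
    stop("control level '", control, "' not present", call. = FALSE)
  }
  treated <- setdiff(levels_seen, control)
  key_cols <- c("genotype", nesting)
  key <- interaction(data[key_cols], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(data, key), function(cell) {
    a <- cell$value[cell$treatment == treated]
    b <- cell$value[cell$treatment == control]
    if (!length(a) || !length(b)) {
      stop("genotype ", cell$genotype[1L],
           " lacks one treatment level in a cell", call. = FALSE)
    }
    res <- cell[1L, key_cols, drop = FALSE]
    res$value <- mean(a) - mean(b)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("genotype", "value", nesting), drop = FALSE]
}
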