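#' Coefficient-stability study under random phenotypes
#'
#' Repeatedly draws an independent phenotype mean for every combinatorial
#' genotype from a uniform distribution, solves each requested full model,
#' and summarizes the distribution of every non-intercept coefficient across
#' repeats. With a bounded phenotype range the additive model grossly
#' inflates high-order interaction estimates, while the averaging model's
#' coefficient distributions stay homogeneous across orders; this study
#' quantifies that contrast.
#'
#' The same drawn means are solved under every family, so quantities whose
#' formulas coincide across families (all 1-gene effects) have identical --
#' not merely identically distributed -- samples.
#'
#' @param n_genes Number of genes (default 7, i.e. 128 genotypes).
#' @param reps Number of Monte-Carlo repeats (default 10000).
#' @param low,high Bounds of the uniform phenotype distribution (defaults 1
#'   and 10).
#' @param families Model families to solve (default all three).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame of class `"avg_study"` with one row per family and
#'   term: columns `family`, `term`, `order`, `q25`, `q50`, `q75`, `iqr`,
#'   `whisker_low`, `whisker_high` (1.5 IQR convention). The study settings
#'   are kept in attributes.
#' @examples
#' s <- run_uniform_study(n_genes = 3, reps = 200, seed = 1)
#' iqr_ratio(s, "additive", 3, 1)
#' @export
run_uniform_study <- function(n_genes = 7, reps = 10000, low = 1, high = 10,
                              families = c("additive", "nr", "averaging"),
                              seed = NULL) {
  stopifnot(n_genes >= 1, reps >= 1, low <= high)
  families <- match.arg(families, c("additive", "nr", "averaging"),
                        several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  universe <- gene_universe(paste(LETTERS[seq_len(n_genes)], collapse = ""))
  n_geno <- 2L^n_genes
  # column = repeat; within a column, draws follow the canonical genotype order
  Y <- matrix(stats::runif(n_geno * reps, low, high), nrow = n_geno)
  out <- list()
  for (fam in families) {
    spec <- model_spec(fam, universe)
    M <- build_model_matrix(spec)
    coefs <- forwardsolve(M, Y)   # terms x reps, intercept in row 1
    coefs <- coefs[-1L, , drop = FALSE]
    q <- apply(coefs, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
               names = FALSE)
    iqr <- q[3L, ] - q[1L, ]
    out[[fam]] <- data.frame(
      family = fam,
      term = term_labels(spec),
      order = lengths(enumerate_subsets(universe, n_genes)),
      q25 = q[1L, ], q50 = q[2L, ], q75 = q[3L, ], iqr = iqr,
      whisker_low = q[1L, ] - 1.5 * iqr,
      whisker_high = q[3L, ] + 1.5 * iqr,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "study") <- list(n_genes = n_genes, reps = reps,
                             low = low, high = high, seed = seed)
  class(res) <- c("avg_study", "data.frame")
  res
}

#' Interquartile-range ratios from a stability study
#'
#' Compares the spread of coefficient estimates across interaction orders:
#' the mean IQR of the terms of `numerator_order` divided by the mean IQR of
#' the terms of `denominator_order`. With `denominator = "range"` the
#' denominator is instead the phenotype range (`high - low`) of the study.
#'
#' @param summary An `"avg_study"` result.
#' @param family Model family to extract.
#' @param numerator_order,denominator_order Interaction orders to compare.
#' @param denominator `"order"` (default) or `"range"`.
#' @return Numeric ratio.
#' @export
iqr_ratio <- function(summary, family, numerator_order,
                      denominator_order = 1, denominator = c("order", "range")) {
  stopifnot(inherits(summary, "avg_study"))
  denominator <- match.arg(denominator)
  rows <- summary[summary$family == family, , drop = FALSE]
  if (!nrow(rows)) stop("family '", family, "' not in summary", call. = FALSE)
  pick <- function(ord) {
    x <- rows$iqr[rows$order == ord]
    if (!length(x)) stop("no terms of order ", ord, " in summary", call. = FALSE)
    mean(x)
  }
  num <- pick(numerator_order)
  den <- if (denominator == "range") {
    st <- attr(summary, "study")
    st$high - st$low
  } else pick(denominator_order)
  num / den
}

#' Configure a synthetic replicated-data generator
#'
#' Describes a data-generating process emulating a replicated combinatorial
#' mutant experiment: true genotype means come from a known coefficient
#' vector, observations add nested Gaussian random intercepts (e.g.
#' experimental replicate / flat / pot) and Gaussian residual noise, and an
#' optional two-level treatment shifts each genotype by a genotype-specific
#' effect.
#'
#' The nested design mirrors a plant-pathology bacterial-growth experiment:
#' `n_rep` top-level replicates each contain every genotype; within a
#' replicate, pots are grouped into flats of `flat_size` pots; each
#' genotype-by-replicate combination occupies one pot holding
#' `plants_per_pot` independently measured plants.
#'
#' @param spec A model spec.
#' @param coef True coefficients: an `"avg_coef"` data frame or named vector
#'   matching the spec's term list.
#' @param sd_resid Residual (within-pot) standard deviation, phenotype
#'   units. Default 0.5, a typical spread for log10 bacterial counts.
#' @param n_rep Number of top-level replicates (default 3).
#' @param plants_per_pot Observations per pot (default 2).
#' @param flat_size Pots per flat (default 8).
#' @param sd_nested Named numeric vector of random-intercept standard
#'   deviations for levels `replicate`, `flat`, `pot` (default
#'   `c(replicate = 0.25, flat = 0.15, pot = 0.1)`). Use zeros for a purely
#'   fixed-effects process.
#' @param treatment_coef Optional coefficient vector for genotype-specific
#'   treatment effects; when given, every plant is measured under both a
#'   control and a treated condition sharing its pot's random intercepts.
#' @param control,treated Labels of the two treatment levels.
#' @return An object of class `"avg_synth_config"`.
#' @export
synth_config <- function(spec, coef, sd_resid = 0.5, n_rep = 3,
                         plants_per_pot = 2, flat_size = 8,
                         sd_nested = c(replicate = 0.25, flat = 0.15, pot = 0.1),
                         treatment_coef = NULL,
                         control = "mock", treated = "induced") {
  stopifnot(inherits(spec, "avg_model_spec"), n_rep >= 1, plants_per_pot >= 1,
            flat_size >= 1, sd_resid >= 0, all(sd_nested >= 0))
  if (!all(c("replicate", "flat", "pot") %in% names(sd_nested))) {
    stop("sd_nested must name levels replicate, flat and pot", call. = FALSE)
  }
  structure(list(spec = spec, coef = coef, sd_resid = sd_resid, n_rep = n_rep,
                 plants_per_pot = plants_per_pot, flat_size = flat_size,
                 sd_nested = sd_nested, treatment_coef = treatment_coef,
                 control = control, treated = treated),
            class = "avg_synth_config")
}

#' Generate a synthetic replicated phenotype table
#'
#' Draws one dataset from the process described by a [synth_config()]:
#' `value = true genotype mean (+ treatment effect) + replicate intercept +
#' flat intercept + pot intercept + residual`, with genotypes enumerated in
#' canonical order within each replicate.
#'
#' @param cfg An `"avg_synth_config"`.
#' @param seed Optional integer seed.
#' @return A long-format data frame with columns `genotype`, `value`,
#'   nesting columns `replicate`, `flat`, `pot`, and `treatment` when the
#'   config defines treatment effects. The true genotype means are attached
#'   as attribute `"truth"`.
#' @examples
#' spec <- model_spec("averaging", "ABC")
#' truth <- solve_means(spec, network_means(six_node_network()))
#' dat <- generate_replicated_data(synth_config(spec, truth), seed = 1)
#' head(dat)
#' @export
generate_replicated_data <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "avg_synth_config"))
  if (!is.null(seed)) set.seed(seed)
  spec <- cfg$spec
  mu <- predict_means(spec, cfg$coef)
  genos <- names(mu)
  n_geno <- length(genos)
  has_trt <- !is.null(cfg$treatment_coef)
  delta <- if (has_trt) predict_means(spec, cfg$treatment_coef) else NULL

  rows <- list()
  for (r in seq_len(cfg$n_rep)) {
    rep_id <- sprintf("R%d", r)
    rep_eff <- stats::rnorm(1, 0, cfg$sd_nested[["replicate"]])
    flat_of_pot <- ceiling(seq_len(n_geno) / cfg$flat_size)
    flat_eff <- stats::rnorm(max(flat_of_pot), 0, cfg$sd_nested[["flat"]])
    for (g in seq_len(n_geno)) {
      pot_id <- sprintf("%s.P%d", rep_id, g)
      flat_id <- sprintf("%s.F%d", rep_id, flat_of_pot[g])
      pot_eff <- stats::rnorm(1, 0, cfg$sd_nested[["pot"]])
      base <- mu[g] + rep_eff + flat_eff[flat_of_pot[g]] + pot_eff
      for (p in seq_len(cfg$plants_per_pot)) {
        if (has_trt) {
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = genos[g],
            value = base + c(0, delta[g]) + stats::rnorm(2, 0, cfg$sd_resid),
            treatment = c(cfg$control, cfg$treated),
            replicate = rep_id, flat = flat_id, pot = pot_id,
            stringsAsFactors = FALSE
          )
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = genos[g],
            value = base + stats::rnorm(1, 0, cfg$sd_resid),
            replicate = rep_id, flat = flat_id, pot = pot_id,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- mu
  attr(out, "universe") <- spec$universe
  out
}
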