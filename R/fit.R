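# Observation-level design matrix: one model-matrix row per observation,
# looked up by the observation's genotype.
observation_design <- function(spec, genotype) {
  M <- build_model_matrix(spec)
  labs <- canonical_genotype(genotype, spec$universe)
  idx <- match(labs, rownames(M))
  if (anyNA(idx)) {
    stop("genotype(s) outside the model's universe: ",
         paste(unique(genotype[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  M[idx, , drop = FALSE]
}

check_lattice <- function(spec, genotype, full_required = TRUE) {
  labs <- canonical_genotype(genotype, spec$universe)
  missing <- setdiff(enumerate_genotypes(spec$universe), labs)
  if (length(missing) && full_required) {
    stop("data are missing genotype(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing)) {
    warning("data are missing genotype(s): ", paste(missing, collapse = ", "),
            "; the reduced design must retain full column rank", call. = FALSE)
  }
  invisible(labs)
}

coef_inference <- function(spec, est, vc, df, sigma2 = NULL) {
  se <- sqrt(pmax(diag(vc), 0))
  if (df > 0) {
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    ci <- stats::qt(0.975, df) * se
    p_holm <- rep(NA_real_, length(p))
    p_holm[-1L] <- holm_adjust(p[-1L])   # family: all non-intercept terms
    extra <- data.frame(se = se, df = df, ci_low = est - ci, ci_high = est + ci,
                        p = p, p_holm = p_holm)
  } else {
    extra <- data.frame(se = NA_real_, df = 0, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, p_holm = NA_real_)
  }
  out <- new_coef(spec, est, extra = extra)
  class(out) <- c("avg_coef_table", class(out))
  out
}

#' Fit a model to replicated data by least squares
#'
#' Ordinary least squares of the observed phenotypes on the
#' observation-expanded model matrix. All three families are
#' reparameterizations of the one-mean-per-genotype cell-means model, so for
#' the full model their fitted values and residuals are identical; only the
#' decomposition into effects and interactions differs. Standard errors come
#' from the coefficient covariance, with `df = N - p` residual degrees of
#' freedom; 95% confidence intervals use the t quantile and p-values are
#' Holm-adjusted over all non-intercept terms of the fit.
#'
#' @param spec A model spec. A full model requires every genotype observed;
#'   a reduced model (`max_order < n`) tolerates missing genotypes as long
#'   as the design keeps full column rank.
#' @param data A phenotype table: data frame with columns `genotype` and
#'   `value` (see [read_phenotype_table()]).
#' @return An `"avg_coef_table"` data frame: `term`, `order`, `estimate`,
#'   `se`, `df`, `ci_low`, `ci_high`, `p`, `p_holm`. With zero residual
#'   degrees of freedom (e.g. one observation per genotype in a full model)
#'   the estimates are returned and the inference columns are `NA`. Fitted
#'   values and residuals are attached as attributes.
#' @examples
#' spec <- model_spec("averaging", "ABC")
#' means <- network_means(six_node_network())
#' dat <- data.frame(genotype = rep(names(means), 2), value = rep(means, 2))
#' fit_fixed(spec, dat)
#' @export
fit_fixed <- function(spec, data) {
  stopifnot(inherits(spec, "avg_model_spec"))
  data <- validate_phenotype_table(data, spec$universe)
  check_lattice(spec, data$genotype,
                full_required = spec$max_order == length(spec$universe))
  X <- observation_design(spec, data$genotype)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("rank-deficient design: the observed genotypes cannot identify all ",
         "terms up to order ", spec$max_order, call. = FALSE)
  }
  est <- qr.coef(qr_x, data$value)
  fitted <- drop(X %*% est)
  resid <- data$value - fitted
  df <- length(data$value) - ncol(X)
  if (df > 0) {
    sigma2 <- sum(resid^2) / df
    vc <- sigma2 * chol2inv(qr.R(qr_x))
  } else {
    sigma2 <- NA_real_
    vc <- matrix(NA_real_, ncol(X), ncol(X))
    diag(vc) <- 0   # keeps se = 0-path out; handled by df = 0 branch
  }
  out <- coef_inference(spec, est, vc, df)
  attr(out, "fitted") <- fitted
  attr(out, "residuals") <- resid
  attr(out, "sigma") <- sqrt(sigma2)
  out
}

#' Fit a model with nested random effects
#'
#' Linear mixed-effects fit (REML, via [nlme::lme()]): the fixed effects are
#' the intercept and model terms through the observation-expanded model
#' matrix, and the random effects are nested intercepts, e.g.
#' `~ 1 | replicate/flat/pot`. This is the appropriate fit when the
#' experimental design has grouping factors and unequal replicate numbers.
#' Confidence intervals and t-tests use `df = N - p` residual degrees of
#' freedom, an approximation of the containment degrees of freedom.
#'
#' @inheritParams fit_fixed
#' @param nesting Character vector of grouping column names, outermost
#'   first, e.g. `c("replicate", "flat", "pot")`.
#' @param fallback_fixed If `TRUE`, a mixed fit that fails to converge is
#'   replaced by [fit_fixed()] with a warning; by default non-convergence is
#'   an error carrying the optimizer's message.
#' @return An `"avg_coef_table"`; the random-effect standard deviations
#'   (one per nesting level, plus the residual) are attached as attribute
#'   `"ranef_sd"`.
#' @examples
#' spec <- model_spec("averaging", "ABC")
#' truth <- solve_means(spec, network_means(six_node_network()))
#' dat <- generate_replicated_data(synth_config(spec, truth), seed = 1)
#' fit_mixed(spec, dat, nesting = c("replicate", "flat", "pot"))
#' @export
fit_mixed <- function(spec, data, nesting, fallback_fixed = FALSE) {
  stopifnot(inherits(spec, "avg_model_spec"), length(nesting) >= 1)
  data <- validate_phenotype_table(data, spec$universe, nesting = nesting)
  check_lattice(spec, data$genotype,
                full_required = spec$max_order == length(spec$universe))
  if (length(unique(data[[nesting[1L]]])) < 2L) {
    stop("mixed fits need at least 2 groups at the top nesting level",
         call. = FALSE)
  }
  X <- observation_design(spec, data$genotype)
  p <- ncol(X)
  bnames <- sprintf("b%03d", seq_len(p))
  dd <- data.frame(.value = data$value, X, check.names = FALSE)
  colnames(dd) <- c(".value", bnames)
  for (g in nesting) dd[[g]] <- factor(data[[g]])
  fixed <- stats::as.formula(paste(".value ~ 0 +", paste(bnames, collapse = " + ")))
  random <- stats::as.formula(paste("~ 1 |", paste(nesting, collapse = "/")))
  fit <- tryCatch(
    nlme::lme(fixed = fixed, random = random, data = dd, method = "REML"),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    if (fallback_fixed) {
      warning("mixed fit failed (", conditionMessage(fit),
              "); falling back to fit_fixed()", call. = FALSE)
      return(fit_fixed(spec, data))
    }
    stop("mixed fit failed to converge: ", conditionMessage(fit), call. = FALSE)
  }
  est <- nlme::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  df <- nrow(dd) - p
  out <- coef_inference(spec, unname(est), vc, df)
  vcr <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vcr[, "StdDev"]))
  sds <- sds[!is.na(sds)]
  # VarCorr lists levels outermost-in, then the residual
  if (length(sds) == length(nesting) + 1L) names(sds) <- c(nesting, "residual")
  attr(out, "ranef_sd") <- sds
  attr(out, "lme") <- fit
  out
}

#' Truncate a model at a lower interaction order
#'
#' Model reduction: refitting after omitting all interactions above a chosen
#' order. The reduced model is no longer square in the genotype means and is
#' estimated by least squares ([fit_fixed()] / [fit_mixed()]). Under the
#' additive family, reduction substantially shifts the surviving lower-order
#' estimates when high-order interactions carried weight; under the
#' averaging family the surviving estimates are nearly unaffected.
#'
#' @param spec A model spec.
#' @param new_max_order New maximum interaction order,
#'   `1 <= new_max_order <= max_order`.
#' @return A model spec with the truncated term list.
#' @export
reduce_model <- function(spec, new_max_order) {
  stopifnot(inherits(spec, "avg_model_spec"))
  new_max_order <- as.integer(new_max_order)
  if (new_max_order < 1L || new_max_order > spec$max_order) {
    stop("new_max_order must be in [1, ", spec$max_order, "]", call. = FALSE)
  }
  model_spec(spec$family, spec$universe, new_max_order)
}
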