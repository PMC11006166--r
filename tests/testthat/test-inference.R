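make_replicated <- function(spec, means, reps = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  labs <- rep(names(means), each = reps)
  data.frame(genotype = labs,
             value = rep(unname(means), each = reps) +
               stats::rnorm(length(labs), 0, noise_sd),
             stringsAsFactors = FALSE)
}

test_that("full-model fits are reparameterizations of the cell means", {
  set.seed(31)
  u <- universe_of_size(3)
  means <- random_means(u)
  dat <- make_replicated(model_spec("additive", u), means, reps = 3,
                         noise_sd = 0.7)
  fits <- lapply(c("additive", "nr", "averaging"), function(fam) {
    fit_fixed(model_spec(fam, u), dat)
  })
  f0 <- attr(fits[[1]], "fitted")
  for (f in fits[-1]) {
    expect_lt(max(abs(attr(f, "fitted") - f0)), 1e-8)
    expect_lt(max(abs(attr(f, "residuals") - attr(fits[[1]], "residuals"))),
              1e-8)
  }
  # balanced data: fitted genotype means equal observed genotype means
  obs <- tapply(dat$value, dat$genotype, mean)
  expect_equal(unname(c(obs[dat$genotype])), unname(f0), tolerance = 1e-10)
})

test_that("fits without residual degrees of freedom flag inference as absent", {
  u <- gene_universe("AB")
  means <- c("-" = 1, "A" = 2, "B" = 3, "AB" = 7)
  fit <- fit_fixed(model_spec("averaging", u), make_replicated(
    model_spec("averaging", u), means, reps = 1))
  expect_equal(fit$df, rep(0, 4))
  expect_true(all(is.na(fit$se)))
  expect_true(all(is.na(fit$p)))
  # estimates still equal the exact solution
  exact <- solve_means(model_spec("averaging", u), means)
  expect_equal(fit$estimate, exact$estimate, tolerance = 1e-10)
})

test_that("missing genotypes are fatal for full fits, tolerated when reduced", {
  u <- gene_universe("ABC")
  means <- example_means()
  dat <- make_replicated(model_spec("additive", u), means, reps = 2)
  dat <- dat[dat$genotype != "ABC", ]
  expect_error(fit_fixed(model_spec("additive", u), dat), "missing genotype")
  expect_warning(fit2 <- fit_fixed(model_spec("additive", u, max_order = 2), dat),
                 "missing genotype")
  expect_equal(nrow(fit2), 7)
})

test_that("reduced models refit by least squares", {
  u <- universe_of_size(3)
  spec2 <- model_spec("additive", u, max_order = 2)
  # order-2 additive mechanism: reduction to order 2 fits perfectly
  coefs <- zero_coef(spec2)
  coefs[c("(Intercept)", "A", "B", "A:B", "B:C")] <- c(1, 2, -1, 0.5, 1.5)
  means <- predict_means(spec2, coefs)
  dat <- make_replicated(spec2, means, reps = 1)
  fit <- fit_fixed(spec2, dat)
  expect_lt(max(abs(attr(fit, "residuals"))), 1e-10)
  expect_equal(stats::setNames(fit$estimate, fit$term), coefs,
               tolerance = 1e-10)
  # reduction to the current order is the identity
  expect_equal(reduce_model(spec2, 2), spec2)
  expect_error(reduce_model(spec2, 3), "new_max_order")
})

test_that("model reduction perturbs additive 1-gene estimates more than averaging", {
  set.seed(61)
  u <- universe_of_size(4)
  shift <- function(fam, m) {
    spec <- model_spec(fam, u)
    full <- solve_means(spec, m)
    red <- fit_fixed(reduce_model(spec, 3),
                     data.frame(genotype = names(m), value = unname(m)))
    mean(abs(full$estimate[full$order == 1] - red$estimate[red$order == 1]))
  }
  deltas <- replicate(50, {
    m <- random_means(u)
    shift("additive", m) - shift("averaging", m)
  })
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.9)
})

test_that("zero-variance groups reduce the mixed fit to the fixed fit", {
  spec <- model_spec("averaging", "ABC")
  truth <- solve_means(spec, example_means())
  cfg <- synth_config(spec, truth, sd_resid = 0.4,
                      sd_nested = c(replicate = 0, flat = 0, pot = 0))
  dat <- generate_replicated_data(cfg, seed = 13)
  ff <- fit_fixed(spec, dat)
  fm <- fit_mixed(spec, dat, nesting = c("replicate", "flat", "pot"))
  expect_equal(fm$estimate, ff$estimate, tolerance = 1e-6)
  # with no true group variance the upper-level components collapse
  expect_lt(max(attr(fm, "ranef_sd")[c("replicate", "flat")]), 0.2)
})

test_that("mixed fits recover variance components and stay unbiased when unbalanced", {
  spec <- model_spec("averaging", "AB")
  coefs <- zero_coef(spec)
  coefs[] <- c(5, 1.5, -1, 2)
  sds <- c(replicate = 0.5, flat = 0.4, pot = 0.3)
  cfg <- synth_config(spec, coefs, sd_resid = 0.3, n_rep = 6,
                      plants_per_pot = 3, flat_size = 2, sd_nested = sds)
  set.seed(71)
  nsim <- 60
  var_hat <- matrix(NA_real_, nsim, 3)
  est_a <- numeric(nsim)
  for (i in seq_len(nsim)) {
    dat <- generate_replicated_data(cfg)
    # unbalanced: drop a random 20% of observations
    dat <- dat[-sample(nrow(dat), round(0.2 * nrow(dat))), ]
    fm <- fit_mixed(spec, dat, nesting = c("replicate", "flat", "pot"))
    var_hat[i, ] <- attr(fm, "ranef_sd")[c("replicate", "flat", "pot")]^2
    est_a[i] <- fm$estimate[fm$term == "A"]
  }
  # REML variance components: simulation mean within 3 MC SEs of truth
  for (j in 1:3) {
    mc_se <- stats::sd(var_hat[, j]) / sqrt(nsim)
    expect_lt(abs(mean(var_hat[, j]) - sds[j]^2), 3 * mc_se + 1e-8)
  }
  # fixed effects unbiased despite the unbalance
  mc_se <- stats::sd(est_a) / sqrt(nsim)
  expect_lt(abs(mean(est_a) - coefs[["A"]]), 3 * mc_se)
})

test_that("the gene screen forms the documented contrasts", {
  spec <- model_spec("averaging", "ABC")
  truth <- solve_means(spec, example_means())
  dat <- generate_replicated_data(synth_config(spec, truth), seed = 17)
  scr <- screen_genes(dat, "ABC")
  cc <- scr[scr$gene == "C", ]
  expect_equal(nrow(cc), 4)  # ABC-AB, AC-A, BC-B, C-(fully mutant)
  expect_setequal(paste(cc$with_gene, cc$background, sep = "-"),
                  c("ABC-AB", "AC-A", "BC-B", "C--"))
  expect_equal(nrow(scr), 3 * 4)
  expect_true(all(scr$p_bh >= scr$p - 1e-12))
  # strong own activity of C: kept; decision accessors agree
  expect_true("C" %in% kept_genes(scr))
})

test_that("bundling collapses a gene's allele states and is lossy", {
  set.seed(19)
  u <- gene_universe("JEPS")
  labs <- enumerate_genotypes(u)
  dat <- data.frame(genotype = rep(labs, 2), value = stats::rnorm(32))
  out <- bundle_gene(dat, "J", u)
  expect_equal(nrow(out), nrow(dat))          # every observation retained
  expect_length(unique(out$genotype), 8)      # 16 labels collapse to 8
  expect_false(any(grepl("J", out$genotype)))
  expect_equal(attr(out, "universe"), gene_universe("EPS"))
  # screening the reduced universe never references the removed gene
  scr <- screen_genes(out, attr(out, "universe"))
  expect_false("J" %in% scr$gene)
  expect_error(bundle_gene(dat, "X", u), "one label")
})

test_that("Holm and BH adjustments match hand-executed step procedures", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotonicity: uniformly larger p never yields smaller adjusted values
  set.seed(23)
  for (r in 1:20) {
    p <- stats::runif(8)
    q <- pmin(p + stats::runif(8, 0, 0.2), 1)
    expect_true(all(holm_adjust(q) >= holm_adjust(p)))
    expect_true(all(bh_adjust(q) >= bh_adjust(p)))
  }
})

test_that("treatment contrasts isolate the genotype-specific response", {
  spec <- model_spec("averaging", "ABC")
  base <- zero_coef(spec); base["(Intercept)"] <- 5; base["A"] <- 1
  trt <- solve_means(spec, example_means())  # treatment effect structure
  cfg <- synth_config(spec, base, sd_resid = 0,
                      sd_nested = c(replicate = 0.4, flat = 0.2, pot = 0.3),
                      treatment_coef = trt)
  dat <- generate_replicated_data(cfg, seed = 29)
  ctr <- treatment_contrast(dat, control = "mock",
                            nesting = c("replicate", "flat", "pot"))
  expect_false("treatment" %in% names(ctr))
  # noiseless: shared pot intercepts cancel, contrasts equal the true effects
  fit <- fit_fixed(spec, ctr)
  expect_equal(fit$estimate, trt$estimate, tolerance = 1e-8)
  # identical values under both levels make every contrast zero
  dat0 <- dat; dat0$value <- 3
  ctr0 <- treatment_contrast(dat0, control = "mock",
                             nesting = c("replicate", "flat", "pot"))
  expect_true(all(ctr0$value == 0))
  # data without a treatment column pass through untouched
  plain <- data.frame(genotype = "A", value = 1)
  expect_identical(treatment_contrast(plain, control = "mock"), plain)
  # a missing level is an error
  bad <- dat[!(dat$genotype == "ABC" & dat$treatment == "mock"), ]
  expect_error(treatment_contrast(bad, control = "mock"), "treatment level")
})
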