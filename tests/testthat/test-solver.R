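test_that("the worked example solves to the published mechanism", {
  m <- example_means()
  add <- solve_means(model_spec("additive", "ABC"), m)
  est <- stats::setNames(add$estimate, add$term)
  expect_equal(est[["(Intercept)"]], 2)
  expect_equal(est[["C"]], 4)
  expect_equal(est[["A:C"]], 5)
  expect_equal(est[["B:C"]], -3)
  expect_equal(unname(est[c("A", "B", "A:B", "A:B:C")]), rep(0, 4))
})

test_that("mutant-allele recoding recovers the wild-type-referenced effects", {
  m <- example_means()
  rec <- recode_to_mutant(m, "ABC")
  add <- solve_means(model_spec("additive", "ABC"), rec)
  est <- stats::setNames(add$estimate, add$term)
  expect_equal(est[["(Intercept)"]], 8)  # all-wild-type phenotype
  expect_equal(est[["A"]], -5)           # a = aBC - ABC = 3 - 8
  expect_equal(est[["B"]], 3)
  expect_equal(est[["C"]], -6)
  expect_equal(est[["B:C"]], -3)
  # recoding is an involution
  expect_equal(recode_to_mutant(rec, "ABC")[names(m)], m)
})

test_that("averaging coefficients equal their direct-deviation definition", {
  m <- example_means()
  u <- gene_universe("ABC")
  # A;B;C = ABC - (AB + AC + BC)/3 = 8 - 16/3
  expect_equal(averaging_coef_direct(c("A", "B", "C"), m, u), 8 - 16 / 3)
  expect_equal(averaging_coef_direct("C", m, u), 4)
  expect_equal(averaging_coef_direct(c("A", "C"), m, u), 7)
  avg <- solve_means(model_spec("averaging", u), m)
  for (i in 2:nrow(avg)) {
    genes <- strsplit(avg$term[i], ";", fixed = TRUE)[[1]]
    expect_equal(avg$estimate[i], averaging_coef_direct(genes, m, u),
                 tolerance = 1e-12)
  }
  # equal means everywhere give zero for every subset
  flat <- stats::setNames(rep(3.7, 8), names(m))
  for (i in 2:nrow(avg)) {
    genes <- strsplit(avg$term[i], ";", fixed = TRUE)[[1]]
    expect_equal(averaging_coef_direct(genes, flat, u), 0)
  }
})

test_that("averaging coefficient is the mean of last-gene differences", {
  set.seed(11)
  u <- universe_of_size(4)
  m <- random_means(u)
  subsets <- list(c("A", "B"), c("A", "C", "D"), c("A", "B", "C", "D"))
  for (S in subsets) {
    diffs <- vapply(seq_along(S), function(i) {
      m[[format_genotype(S, u)]] - m[[format_genotype(S[-i], u)]]
    }, numeric(1))
    expect_equal(averaging_coef_direct(S, m, u), mean(diffs), tolerance = 1e-12)
  }
})

test_that("solvers agree with independent closed forms on random tables", {
  set.seed(101)
  for (n in 2:5) {
    u <- universe_of_size(n)
    for (r in 1:10) {
      m <- random_means(u)
      add <- solve_means(model_spec("additive", u), m)
      avg <- solve_means(model_spec("averaging", u), m)
      for (i in seq_len(nrow(add))[-1]) {
        genes <- strsplit(add$term[i], ":", fixed = TRUE)[[1]]
        expect_equal(add$estimate[i], mobius_additive_oracle(genes, m, u),
                     tolerance = 1e-9)
        expect_equal(avg$estimate[i], averaging_coef_direct(genes, m, u),
                     tolerance = 1e-9)
      }
      # 1-gene coefficients identical across the three families
      nr <- solve_means(model_spec("nr", u), m)
      expect_equal(add$estimate[add$order == 1], avg$estimate[avg$order == 1],
                   tolerance = 1e-10)
      expect_equal(add$estimate[add$order == 1], nr$estimate[nr$order == 1],
                   tolerance = 1e-10)
    }
  }
})

test_that("predict and solve are exact inverses", {
  set.seed(5)
  for (fam in c("additive", "nr", "averaging")) {
    spec <- model_spec(fam, universe_of_size(4))
    coefs <- zero_coef(spec)
    coefs[] <- stats::rnorm(length(coefs))
    m <- predict_means(spec, coefs)
    back <- solve_means(spec, m)
    expect_equal(stats::setNames(back$estimate, back$term), coefs,
                 tolerance = 1e-10)
  }
  # zero coefficients with intercept 5 predict a constant phenotype
  spec <- model_spec("averaging", "ABC")
  coefs <- zero_coef(spec)
  coefs["(Intercept)"] <- 5
  expect_equal(unname(predict_means(spec, coefs)), rep(5, 8))
  # the worked example's coefficients recover its means, ABC = 8 included
  add <- solve_means(model_spec("additive", "ABC"), example_means())
  pred <- predict_means(model_spec("additive", "ABC"), add)
  expect_equal(pred, example_means()[names(pred)])
  expect_equal(pred[["ABC"]], 8)
})

test_that("additive mechanisms of order r have no coefficients above r", {
  set.seed(21)
  for (n in 3:5) {
    u <- universe_of_size(n)
    r <- n - 1L
    gen <- model_spec("additive", u, max_order = n)
    coefs <- zero_coef(gen)
    low <- c(0L, lengths(enumerate_subsets(u, n))) <= r
    coefs[low] <- stats::runif(sum(low), -2, 2)
    m <- predict_means(gen, coefs)
    out <- solve_means(model_spec("additive", u), m)
    expect_true(all(abs(out$estimate[out$order > r]) < 1e-9))
  }
})

test_that("incomplete or malformed mean tables are rejected", {
  u <- gene_universe("AB")
  expect_error(solve_means(model_spec("additive", u), c("-" = 1, "A" = 2)),
               "missing genotype")
  expect_error(solve_means(model_spec("additive", u),
                           c("-" = 1, "A" = 2, "B" = 3, "AB" = 4, "Ab" = 9)),
               "duplicated")
  expect_error(solve_means(model_spec("additive", u, max_order = 1),
                           c("-" = 1, "A" = 2, "B" = 3, "AB" = 4)),
               "full model")
})
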