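# Shared fixtures and independent oracles for the test suite.

# Phenotypes of the six-node worked-example network, frozen by hand from the
# node rules: nZ = (nA + nB + nX) + nY with mutant nodes forced to 0.
example_means <- function() {
  c("-" = 2, "A" = 2, "B" = 2, "C" = 6, "AB" = 2, "AC" = 11, "BC" = 3,
    "ABC" = 8)
}

# Random complete mean table over an n-gene universe.
random_means <- function(universe, low = 1, high = 10) {
  labs <- enumerate_genotypes(universe)
  stats::setNames(stats::runif(length(labs), low, high), labs)
}

# Named coefficient vector of zeros for a spec, ready for assignment.
zero_coef <- function(spec) {
  labs <- c("(Intercept)", term_labels(spec))
  stats::setNames(numeric(length(labs)), labs)
}

# Independent oracle: the averaging weight defined by its recursion,
# w(m, m) = 1; w(k, m) = ((m - k) / m) * w(k, m - 1).
recursive_averaging_weight <- function(k, m) {
  if (k == m) return(1)
  (m - k) / m * recursive_averaging_weight(k, m - 1)
}

universe_of_size <- function(n) {
  gene_universe(paste(LETTERS[seq_len(n)], collapse = ""))
}
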