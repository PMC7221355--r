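# Fixtures are generated in code; nothing is read from disk.

# Valid random connectome: sample correlation of seeded Gaussian series.
random_connectome <- function(n = 12, t = 80, seed = 1) {
  set.seed(seed)
  pearson_connectome(matrix(rnorm(t * n), t, n))
}

# Community-structured connectome from the generator's population model.
structured_connectome <- function(seed = 1, n_nodes = 30, k = 3) {
  spec <- cohort_spec(n_case = 2, n_control = 2, n_nodes = n_nodes, k = k,
                      seed = seed)
  simulate_cohort(spec)$connectomes[[1]]
}

# Small cohort for inference tests: quick to simulate, large enough to fit
# the six-term logistic model.
small_cohort <- function(seed = 1, effect_between = 0.03, n_case = 30,
                         n_control = 30, n_nodes = 30, k = 3, ...) {
  simulate_cohort(cohort_spec(n_case = n_case, n_control = n_control,
                              n_nodes = n_nodes, k = k,
                              effect_between = effect_between,
                              seed = seed, ...))
}

# Hand-written Pearson correlation, the brute-force oracle.
cor_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

expect_symmetric_unit_diag <- function(m) {
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(1, nrow(m)))
}
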