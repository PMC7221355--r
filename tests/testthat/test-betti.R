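toy_curve <- function() {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.5
  d[2, 3] <- d[3, 2] <- 0.9
  b0_curve(d)
}

test_that("hand-worked single linkage on three nodes", {
  cv <- toy_curve()
  expect_equal(cv$merge_values, c(0.2, 0.5))
  expect_equal(b0_at(cv, 0), 3)
  expect_equal(b0_at(cv, 0.1), 3)
  expect_equal(b0_at(cv, 0.2), 2)   # edge included at d <= eps
  expect_equal(b0_at(cv, 0.35), 2)
  expect_equal(b0_at(cv, 0.5), 1)
  expect_equal(b0_at(cv, 5), 1)
  expect_error(b0_at(cv, -0.1), "non-negative")
})

test_that("single node gives an empty merge list and B0 = 1 everywhere", {
  cv <- b0_curve(matrix(0, 1, 1))
  expect_length(cv$merge_values, 0)
  expect_equal(b0_at(cv, c(0, 1, 2)), c(1, 1, 1))
})

test_that("merge values equal MST edge weights and B0 equals component
          counts of the thresholded graph", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    cm <- random_connectome(n = 15, t = 40, seed = seed)
    dm <- to_distance(cm)
    cv <- b0_curve(dm)
    g <- igraph::graph_from_adjacency_matrix(unclass(dm), mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst_w <- sort(igraph::E(igraph::mst(g))$weight)
    expect_equal(cv$merge_values, mst_w, tolerance = 1e-12)
    set.seed(seed + 100)
    for (eps in runif(50, 0, 2)) {
      adj <- unclass(dm) <= eps
      diag(adj) <- FALSE
      gt <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(b0_at(cv, eps), igraph::components(gt)$no)
    }
  }
})

test_that("area under the curve is the exact step integral over [0, 2]", {
  expect_equal(b0_auc(toy_curve()), 3 * 0.2 + 2 * 0.3 + 1 * 1.5)  # 2.70
  # everything isolated until the right endpoint: auc = 2n
  d <- 2 - diag(2, 4)
  expect_equal(b0_auc(b0_curve(d)), 8)
  # fine-grid Riemann oracle on a random matrix
  cm <- random_connectome(n = 30, t = 60, seed = 11)
  cv <- b0_curve(to_distance(cm))
  grid <- seq(0, 2 - 1e-5, by = 1e-5)
  riemann <- sum(b0_at(cv, grid)) * 1e-5
  expect_equal(b0_auc(cv), riemann, tolerance = 1e-5)
})

test_that("slope equals the closed-form OLS fit of the staircase", {
  # uniform staircase: merges at 0.1, 0.2, ..., drop of 1 per step
  n <- 8
  m <- seq(0.1, by = 0.1, length.out = n - 1)
  cv <- new_b0_curve(m, n = n)
  ols <- coef(lm(y ~ x, data.frame(x = c(0, m), y = c(n, n - seq_len(n - 1)))))
  expect_equal(b0_slope(cv), unname(ols[2]))
  expect_lt(b0_slope(cv), 0)
  # all merges tied at c: replicated two-point OLS
  cvt <- new_b0_curve(rep(0.4, 5), n = 6)
  olst <- coef(lm(y ~ x, data.frame(x = c(0, rep(0.4, 5)),
                                    y = c(6, rep(1, 5)))))
  expect_equal(b0_slope(cvt), unname(olst[2]))
  # scale equivariance: d -> a d divides the slope by a
  a <- 2.5
  expect_equal(b0_slope(new_b0_curve(a * m, n = n)), b0_slope(cv) / a)
  expect_error(b0_slope(new_b0_curve(numeric(0), n = 1)), "fewer than 2")
})

test_that("kurtosis of the merge distribution matches moment oracles", {
  # uniform merges: excess kurtosis -> -1.2
  set.seed(21)
  m <- sort(runif(4000))
  se3 <- 3 * sqrt(24 / 4000)
  expect_lt(abs(b0_kurtosis(new_b0_curve(m)) - (-1.2)), se3)
  # normal merges: -> 0 (shifted positive to stay curve-like)
  mn <- sort(rnorm(4000, mean = 10))
  expect_lt(abs(b0_kurtosis(new_b0_curve(mn))), se3)
  # translation invariance
  cv <- new_b0_curve(sort(runif(20)))
  expect_equal(b0_kurtosis(cv),
               b0_kurtosis(new_b0_curve(cv$merge_values + 3)))
  expect_error(b0_kurtosis(new_b0_curve(c(0.1, 0.2, 0.3))), "at least 4")
  expect_error(b0_kurtosis(new_b0_curve(rep(0.5, 9))), "degenerate")
})

test_that("features are invariant to node relabeling and fall with
          uniformly raised connectivity", {
  cm <- structured_connectome(seed = 31)
  f0 <- b0_features(cm)
  set.seed(8)
  perm <- sample(nrow(cm))
  f_perm <- b0_features(subset_nodes(cm, perm))
  expect_equal(f0, f_perm, tolerance = 1e-12)
  # shrink all distances: r -> r + delta (1 - r); auc strictly decreases
  auc_prev <- f0$auc
  for (delta in c(0.1, 0.3, 0.6)) {
    r2 <- unclass(cm) + delta * (1 - unclass(cm))
    auc_d <- b0_features(connectivity_matrix(r2))$auc
    expect_lt(auc_d, auc_prev)
    auc_prev <- auc_d
  }
})

test_that("cohort features agree with the single-subject path", {
  coh <- small_cohort(seed = 77, n_case = 3, n_control = 3)
  tab <- cohort_features(coh$connectomes)
  expect_equal(nrow(tab), 6)
  one <- b0_features(coh$connectomes[[4]])
  expect_equal(tab$auc[4], one$auc)
  expect_equal(tab$slope[4], one$slope)
  expect_equal(tab$kurtosis[4], one$kurtosis)
  # subset path consistent with subset_nodes + b0_features
  nodes <- names(coh$partition)[unclass(coh$partition) == "C2"]
  tab2 <- cohort_features(coh$connectomes, nodes = nodes)
  expect_equal(tab2$auc[1],
               b0_features(subset_nodes(coh$connectomes[[1]], nodes))$auc)
})
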