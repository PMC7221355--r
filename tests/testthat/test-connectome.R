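test_that("pearson connectome matches the brute-force correlation oracle", {
  set.seed(42)
  ts <- matrix(rnorm(200 * 10), 200, 10)
  cm <- pearson_connectome(ts)
  expect_s3_class(cm, "connectivity_matrix")
  expect_symmetric_unit_diag(cm)
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    expect_equal(cm[pair[1], pair[2]],
                 cor_oracle(ts[, pair[1]], ts[, pair[2]]), tolerance = 1e-12)
  }
  # pure noise at T = 200: no spurious strong correlations
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.35)
})

test_that("perfectly (anti)correlated columns give r = +/-1", {
  set.seed(1)
  x <- rnorm(50)
  ts <- cbind(a = x, b = x, c = -x + 5, d = rnorm(50))
  cm <- pearson_connectome(ts)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
})

test_that("pearson connectome rejects bad input naming the culprit", {
  ts <- matrix(rnorm(30), 10, 3)
  colnames(ts) <- c("x", "y", "z")
  bad <- ts; bad[, 2] <- 7
  expect_error(pearson_connectome(bad), "y")
  expect_error(pearson_connectome(ts[1:2, ]), "3 time points")
  bad2 <- ts; bad2[3, 1] <- NA
  expect_error(pearson_connectome(bad2), "missing")
})

test_that("correlations are invariant to positive affine transforms", {
  set.seed(3)
  ts <- matrix(rnorm(60 * 6), 60, 6)
  cm1 <- pearson_connectome(ts)
  ts[, 4] <- 3.7 * ts[, 4] - 11
  cm2 <- pearson_connectome(ts)
  expect_equal(unclass(cm1), unclass(cm2), tolerance = 1e-10)
})

test_that("the correlation distance is 1 - r with forced zero diagonal", {
  cm <- connectivity_matrix(matrix(c(1, 0.65, -1, 0.65, 1, 0, -1, 0, 1),
                                   3, 3))
  d <- to_distance(cm)
  expect_s3_class(d, "distance_matrix")
  expect_equal(d[1, 2], 0.35)  # the r = 0.65 threshold correspondence
  expect_equal(d[1, 3], 2)
  expect_equal(d[2, 3], 1)
  expect_equal(unname(diag(d)), rep(0, 3))
  # involution partner: 1 - (1 - r) == r elementwise, round-trip exact
  r_back <- 1 - unclass(d); diag(r_back) <- 1
  expect_identical(r_back, unclass(cm))
})

test_that("matrix validation enforces symmetry tolerance and range", {
  r <- diag(3)
  r[1, 2] <- 0.5; r[2, 1] <- 0.5 + 1e-9
  r[1, 3] <- r[3, 1] <- 0.2; r[2, 3] <- r[3, 2] <- 0.1
  cm <- connectivity_matrix(r)  # tiny asymmetry averaged away
  expect_equal(cm[1, 2], 0.5 + 5e-10)
  expect_equal(cm[1, 2], cm[2, 1])
  r[2, 1] <- 0.6
  expect_error(connectivity_matrix(r), "asymmetry")
  r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 1.5
  expect_error(connectivity_matrix(r), "\\[-1, 1\\]")
})

test_that("node subsetting takes principal submatrices and composes", {
  cm <- random_connectome(n = 10, seed = 5)
  expect_equal(subset_nodes(cm, seq_len(10)), cm)
  two <- subset_nodes(cm, c(3, 8))
  expect_equal(dim(two), c(2, 2))
  expect_equal(two[1, 2], cm[3, 8])
  # nested composition: subset(subset(cm, A), pos of B in A) == subset(cm, B)
  for (seed in 1:5) {
    set.seed(seed)
    A <- sort(sample(10, 7))
    B <- sort(sample(A, 4))
    expect_equal(subset_nodes(subset_nodes(cm, A), match(B, A)),
                 subset_nodes(cm, B))
  }
  expect_error(subset_nodes(cm, c(2, 2, 3)), "duplicate")
  expect_error(subset_nodes(cm, c(1, 99)), "range")
  expect_error(subset_nodes(cm, 4), "at least 2")
})

test_that("subnetwork enumeration yields k(k+1)/2 subsets in sorted order", {
  for (k in c(1, 2, 5, 7, 13, 20)) {
    p <- node_partition(rep(paste0("L", sprintf("%02d", seq_len(k))),
                            each = 3))
    subs <- enumerate_subnetworks(p)
    expect_equal(nrow(subs), k * (k + 1) / 2)
    expect_false(is.unsorted(subs$label_a))
  }
  # k = 1: single subset holding every node
  p1 <- node_partition(rep("all", 6))
  subs1 <- enumerate_subnetworks(p1)
  expect_equal(nrow(subs1), 1)
  expect_setequal(subs1$nodes[[1]], names(p1))
  expect_error(node_partition(character(0)), "empty")
})

test_that("internetwork subsets take the union of both networks' nodes", {
  p <- node_partition(rep(c("Frontal", "Parietal", "Occipital"),
                          c(4, 3, 2)))
  subs <- enumerate_subnetworks(p)
  fp <- subs[subs$label_a == "Frontal" & subs$label_b == "Parietal", ]
  expect_equal(length(fp$nodes[[1]]), 7)
  expect_setequal(fp$nodes[[1]],
                  names(p)[unclass(p) %in% c("Frontal", "Parietal")])
})

test_that("parcel aggregation averages member node signals", {
  set.seed(9)
  ts <- matrix(rnorm(40 * 6), 40, 6,
               dimnames = list(NULL, paste0("V", 1:6)))
  p <- node_partition(rep(c("A", "B"), each = 3),
                      node_ids = paste0("V", 1:6))
  agg <- parcellate_timeseries(ts, p)
  expect_equal(agg[, "A"], rowMeans(ts[, 1:3]))
  expect_equal(agg[, "B"], rowMeans(ts[, 4:6]))
})
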