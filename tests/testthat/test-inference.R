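test_that("z-scoring standardizes dimensional columns and is idempotent", {
  x <- data.frame(subject_id = c("a", "b", "c"), v = c(1, 2, 3),
                  w = c(5, 1, 9), bin = c(0, 1, 0))
  z <- zscore_features(x)
  expect_equal(z$v, c(-1, 0, 1))
  expect_equal(z$bin, x$bin)          # binary untouched
  expect_identical(z$subject_id, x$subject_id)
  for (cc in c("v", "w")) {
    expect_equal(mean(z[[cc]]), 0, tolerance = 1e-12)
    expect_equal(sd(z[[cc]]), 1, tolerance = 1e-12)
  }
  expect_equal(zscore_features(z), z, tolerance = 1e-12)
  x$v <- 2
  expect_error(zscore_features(x, cols = "v"), "zero-variance")
})

test_that("the group model recovers a null and flags missing covariates", {
  coh <- small_cohort(seed = 55, effect_between = 0)
  feats <- cohort_features(coh$connectomes)
  fit <- fit_group_model(feats, coh$phenotypes)
  expect_s3_class(fit, "b0_glm")
  row <- fit$coefficients[fit$coefficients$term == "auc", ]
  expect_gt(row$p, 0.01)
  expect_true(row$ci_low < 1 && row$ci_high > 1)
  expect_equal(row$or, exp(row$beta), tolerance = 1e-12)
  expect_equal(fit$n_cases, 30)
  expect_equal(fit$n_controls, 30)
  no_sex <- coh$phenotypes[setdiff(names(coh$phenotypes), "sex")]
  expect_error(fit_group_model(feats, no_sex), "sex")
})

test_that("odds ratios invert exactly when the group reference is recoded", {
  coh <- small_cohort(seed = 56)
  feats <- cohort_features(coh$connectomes)
  fit_case <- fit_group_model(feats, coh$phenotypes, case = "case")
  fit_ctrl <- fit_group_model(feats, coh$phenotypes, case = "control")
  or1 <- fit_case$coefficients$or[-1]
  or2 <- fit_ctrl$coefficients$or[-1]
  expect_equal(or1, 1 / or2, tolerance = 1e-6)
  expect_equal(fit_case$coefficients$p[-1], fit_ctrl$coefficients$p[-1],
               tolerance = 1e-6)
})

test_that("a k = 1 scan cell reproduces the whole-brain fit exactly", {
  coh <- small_cohort(seed = 57, n_case = 15, n_control = 15)
  p1 <- node_partition(rep("whole", length(coh$partition)),
                       node_ids = names(coh$partition))
  sc <- subnetwork_scan(coh$connectomes, p1, coh$phenotypes)
  expect_equal(nrow(sc$cells), 1)
  feats <- cohort_features(coh$connectomes)
  fit <- fit_group_model(feats, coh$phenotypes)
  row <- fit$coefficients[fit$coefficients$term == "auc", ]
  expect_equal(sc$cells$or_auc, row$or, tolerance = 1e-12)
  expect_equal(sc$cells$p_auc, row$p, tolerance = 1e-12)
})

test_that("undersized networks are marked unevaluable without aborting", {
  coh <- small_cohort(seed = 58, n_case = 15, n_control = 15, n_nodes = 24,
                      k = 2)
  labs <- unclass(coh$partition)
  labs[1:3] <- "tiny"                      # 3-node network
  p <- node_partition(labs, node_ids = names(coh$partition))
  sc <- subnetwork_scan(coh$connectomes, p, coh$phenotypes)
  expect_equal(nrow(sc$cells), 6)
  bad <- sc$cells$label_a == "tiny" | sc$cells$label_b == "tiny"
  expect_true(all(!sc$cells$evaluable[bad]))
  expect_true(all(sc$cells$evaluable[!bad]))
  expect_true(all(is.na(sc$cells$p_auc[bad])))
})

test_that("cells cluster by connectivity on the network graph", {
  la <- c("A", "A", "A", "B", "B", "C")
  lb <- c("A", "B", "C", "B", "C", "C")
  # A-B edge and isolated C self-loop: two clusters of 2 and 1 cells
  cl <- betticonn:::cluster_cells(la, lb, c(TRUE, TRUE, FALSE, FALSE,
                                            FALSE, TRUE))
  expect_equal(sort(cl$sizes), c(1, 2))
  expect_equal(cl$membership[1], cl$membership[2])
  expect_false(isTRUE(cl$membership[6] == cl$membership[1]))
  # everything significant: one cluster with all six cells
  cl_all <- betticonn:::cluster_cells(la, lb, rep(TRUE, 6))
  expect_equal(cl_all$sizes, 6L)
  # nothing significant: no clusters
  cl_none <- betticonn:::cluster_cells(la, lb, rep(FALSE, 6))
  expect_length(cl_none$sizes, 0)
  expect_true(all(is.na(cl_none$membership)))
})

test_that("FWE correction attaches add-one cluster p-values", {
  coh <- small_cohort(seed = 60, effect_between = 0.1)  # strong effect
  sc <- subnetwork_scan(coh$connectomes, coh$partition, coh$phenotypes)
  scf <- fwe_correct(sc, n_perm = 100, seed = 2)
  expect_true(all(c("cluster", "p_fwe") %in% names(scf$cells)))
  sig <- which(scf$cells$p_auc < scf$alpha_cell)
  expect_true(all(!is.na(scf$cells$cluster[sig])))
  expect_true(all(is.na(scf$cells$cluster[-sig])))
  if (nrow(scf$clusters) > 0) {
    expect_true(all(scf$clusters$p_fwe >= 1 / 101))
    expect_equal(sum(scf$clusters$n_cells), length(sig))
  }
  # permutation stream is seed-reproducible
  scf2 <- fwe_correct(sc, n_perm = 100, seed = 2)
  expect_identical(scf$null_max, scf2$null_max)
})

test_that("edge proportion test matches the pooled z oracle", {
  # 2-node connectomes engineered to show the edge in 9/10 vs 2/10 subjects
  mk <- function(r) connectivity_matrix(matrix(c(1, r, r, 1), 2, 2))
  cms <- c(lapply(1:9, function(i) mk(0.8)), list(mk(0.1)),   # cases
           lapply(1:2, function(i) mk(0.8)), lapply(1:8, function(i) mk(0.1)))
  groups <- rep(c("case", "control"), each = 10)
  res <- edge_proportion_test(cms, groups, eps = 0.35)
  expect_equal(res$prop_case, 0.9)
  expect_equal(res$prop_control, 0.2)
  phat <- 11 / 20
  z <- (0.9 - 0.2) / sqrt(phat * (1 - phat) * (1 / 10 + 1 / 10))
  expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  expect_lt(res$p, 0.01)
  expect_true(res$mask)
  # exact binomial cross-check: the pooled z call agrees in direction with
  # Fisher's exact test at this contrast
  expect_lt(fisher.test(matrix(c(9, 1, 2, 8), 2, 2))$p.value, 0.05)
  # label swap flips diffs, keeps p
  res_sw <- edge_proportion_test(cms, groups, eps = 0.35, case = "control")
  expect_equal(res_sw$diff, -res$diff)
  expect_equal(res_sw$p, res$p)
})

test_that("degenerate edge contrasts saturate gracefully", {
  coh <- small_cohort(seed = 61, n_case = 5, n_control = 5, n_nodes = 8,
                      k = 2)
  cms <- coh$connectomes
  groups <- coh$phenotypes$group
  # identical groups: reuse the same matrices for both labels
  same <- c(cms[1:5], cms[1:5])
  res <- edge_proportion_test(same, rep(c("case", "control"), each = 5),
                              eps = 0.7)
  expect_true(all(res$diff == 0))
  expect_true(all(!res$mask))
  # eps = 2: every edge present everywhere, p reported as 1
  res2 <- edge_proportion_test(cms, groups, eps = 2)
  expect_true(all(res2$prop_case == 1 & res2$prop_control == 1))
  expect_true(all(res2$p == 1))
  expect_true(all(!res2$mask))
  expect_error(edge_proportion_test(cms, rep("case", 10)), "two levels")
})

test_that("descriptive effect sizes follow their closed forms", {
  expect_equal(round(cohens_d_summary(12.26, 3.07, 96, 10.5, 2.48, 81), 2),
               0.63)
  expect_equal(cohens_d_summary(5, 2, 10, 5, 3, 12), 0)
  expect_error(cohens_d_summary(1, 0, 10, 2, 1, 10), "positive")
  expect_equal(odds_ratio_2x2(1, 1, 1, 1), 1)
  expect_equal(odds_ratio_2x2(51, 45, 22, 59), 51 * 59 / (45 * 22))
  # Haldane-Anscombe correction keeps zero cells finite
  or0 <- odds_ratio_2x2(0, 5, 5, 5)
  expect_true(is.finite(or0))
  expect_equal(or0, (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "undefined")
})
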