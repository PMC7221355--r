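#' Standardize dimensional columns to z scores
#'
#' Centers and scales the named columns to mean 0 and sample SD 1 over the
#' full analysis sample, the form in which dimensional variables enter the
#' group model. Binary columns are left untouched.
#'
#' @param x Data frame.
#' @param cols Columns to standardize; by default every numeric column with
#'   more than two distinct values, excluding `subject_id`.
#' @return `x` with the selected columns standardized.
#' @export
zscore_features <- function(x, cols = NULL) {
  stopifnot(is.data.frame(x))
  if (is.null(cols)) {
    cols <- names(x)[vapply(x, function(col) {
      is.numeric(col) && length(unique(col)) > 2
    }, logical(1))]
    cols <- setdiff(cols, "subject_id")
  }
  for (cc in cols) {
    v <- x[[cc]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cc)
    x[[cc]] <- (v - mean(v)) / s
  }
  x
}

# Coerce the diagnosis column to a 0/1 indicator (case = 1).
as_group01 <- function(group, case = NULL) {
  if (is.numeric(group) && all(group %in% c(0, 1))) {
    return(list(y = as.integer(group), case = "1", control = "0"))
  }
  g <- as.factor(group)
  levs <- levels(g)
  if (length(levs) != 2) stop("group must take exactly two levels, got ",
                              length(levs))
  if (is.null(case)) {
    known <- c("case", "Case", "CASE", "ADHD", "adhd", "patient", "1", "TRUE")
    hit <- intersect(known, levs)
    case <- if (length(hit)) hit[1] else levs[2]
  }
  if (!case %in% levs) stop("case level '", case, "' not found in group")
  list(y = as.integer(g == case), case = case, control = setdiff(levs, case))
}

#' Logistic group model on Betti-0 curve features
#'
#' Fits the diagnostic-group model
#' `group ~ auc + kurtosis + slope + sex + age + motion` by maximum-likelihood
#' logistic regression, with all dimensional variables (the three curve
#' features, age, motion) standardized to z scores over the analysis sample
#' and sex entering as an unstandardized binary indicator. Each term is
#' summarized by its log-odds coefficient, odds ratio, 95% Wald confidence
#' interval, and two-sided Wald p-value. An odds ratio below 1 on the AUC
#' term means cases have smaller areas under the Betti-0 curve — less
#' segregated connectomes — than controls.
#'
#' @param features Data frame with `subject_id`, `auc`, `slope`, `kurtosis`
#'   (e.g. from [cohort_features()]).
#' @param phenotypes Data frame with `subject_id`, `group`, `sex`, `age`,
#'   `motion`.
#' @param case Level of `group` coding cases; defaults to `"case"`-like
#'   labels when present, else the second factor level.
#' @param standardize Standardize dimensional variables (default TRUE).
#' @return An object of class `b0_glm` with the underlying `glm` fit, a
#'   per-term coefficient table, group sizes, and convergence flags.
#' @export
fit_group_model <- function(features, phenotypes, case = NULL,
                            standardize = TRUE) {
  stopifnot(is.data.frame(features), is.data.frame(phenotypes))
  need_f <- c("subject_id", "auc", "slope", "kurtosis")
  need_p <- c("subject_id", "group", "sex", "age", "motion")
  if (!all(need_f %in% names(features))) {
    stop("features must have columns: ", paste(need_f, collapse = ", "))
  }
  miss <- setdiff(need_p, names(phenotypes))
  if (length(miss)) stop("missing phenotype column(s): ",
                         paste(miss, collapse = ", "))
  dat <- merge(features[need_f], phenotypes[need_p], by = "subject_id")
  if (nrow(dat) < 20) stop("need at least 20 matched subjects, got ",
                           nrow(dat))
  grp <- as_group01(dat$group, case = case)
  if (length(unique(grp$y)) < 2) stop("both diagnostic groups must be present")
  sx <- as_group01(dat$sex)
  dat$group <- grp$y
  dat$sex <- sx$y
  if (standardize) {
    dat <- zscore_features(dat, cols = c("auc", "kurtosis", "slope",
                                         "age", "motion"))
  }
  fit <- withCallingHandlers(
    glm(group ~ auc + kurtosis + slope + sex + age + motion,
        family = binomial(), data = dat),
    warning = function(w) invokeRestart("muffleWarning"))
  separated <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)

  sm <- summary(fit)$coefficients
  z975 <- qnorm(0.975)
  tab <- data.frame(
    term = rownames(sm),
    beta = sm[, "Estimate"],
    or = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - z975 * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + z975 * sm[, "Std. Error"]),
    p = sm[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(fit = fit, coefficients = tab,
                 n_cases = sum(grp$y), n_controls = sum(1 - grp$y),
                 case_level = grp$case, control_level = grp$control,
                 converged = fit$converged && !separated,
                 separation = separated,
                 data = dat),
            class = "b0_glm")
}

#' @export
print.b0_glm <- function(x, digits = 3, ...) {
  cat("Logistic group model: group ~ auc + kurtosis + slope + sex + age +",
      "motion\n")
  cat(sprintf("  %d cases ('%s'), %d controls ('%s')\n", x$n_cases,
              x$case_level, x$n_controls, x$control_level))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly",
                        if (x$separation) "(separation detected)", "\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.b0_glm <- function(object, ...) {
  print(object, ...)
  invisible(object$coefficients)
}

#' @export
coef.b0_glm <- function(object, ...) coef(object$fit, ...)

#' @export
predict.b0_glm <- function(object, ...) predict(object$fit, ...)

#' @export
residuals.b0_glm <- function(object, ...) residuals(object$fit, ...)

#' @export
#' @rdname fit_group_model
#' @param x A `b0_glm` object.
#' @param ... Passed to [plot.default()].
plot.b0_glm <- function(x, ...) {
  tab <- x$coefficients[-1, ]  # drop intercept
  k <- nrow(tab)
  plot(tab$or, seq_len(k), xlim = range(c(tab$ci_low, tab$ci_high, 1)),
       pch = 19, yaxt = "n", xlab = "Odds ratio (95% CI)", ylab = "",
       log = "x", ...)
  segments(tab$ci_low, seq_len(k), tab$ci_high, seq_len(k))
  abline(v = 1, lty = 2, col = "grey")
  axis(2, at = seq_len(k), labels = tab$term, las = 1)
  invisible(x)
}

# Wald p-value of one design column in a logistic fit, on a fixed design
# matrix. Used in the permutation loop where only the outcome changes.
wald_p_logistic <- function(X, y, col) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  p <- ncol(X)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  covm <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(covm)) return(NA_real_)
  se <- sqrt(diag(covm))
  piv <- fit$qr$pivot
  se <- se[order(piv)]
  z <- fit$coefficients / se
  pv <- 2 * pnorm(-abs(z))
  unname(pv[col])
}

#' Subnetwork scan of the group model
#'
#' Re-runs the filtration and the logistic group model on every intranetwork
#' and internetwork node subset of a partition (k(k+1)/2 cells for k
#' networks): the subset's principal submatrix is extracted per subject, its
#' Betti-0 features recomputed, and the full six-term model refitted. Each
#' cell records the AUC-term odds ratio and Wald p. Networks with fewer than
#' `min_nodes` nodes make their cells unevaluable (too few nodes for stable
#' curve features); cell-level failures are recorded without aborting the
#' scan. With k = 1 the scan reduces exactly to the whole-brain model.
#'
#' @param cms Named list of subject [connectivity_matrix] objects.
#' @param partition A [node_partition] over the connectome nodes.
#' @param phenotypes Phenotype data frame (see [fit_group_model()]).
#' @param case Case level of `group`.
#' @param min_nodes Minimum nodes per member network (default 5).
#' @return An object of class `subnetwork_scan`: cell table plus the
#'   per-cell feature tables needed for permutation FWE correction.
#' @export
subnetwork_scan <- function(cms, partition, phenotypes, case = NULL,
                            min_nodes = 5) {
  if (!inherits(partition, "node_partition")) {
    partition <- node_partition(partition)
  }
  cells <- enumerate_subnetworks(partition)
  sizes <- table(unclass(partition))
  k <- length(sizes)

  dlist <- cohort_distances(cms)
  ids <- names(cms) %||% as.character(seq_along(cms))

  cell_features <- vector("list", nrow(cells))
  res <- data.frame(label_a = cells$label_a, label_b = cells$label_b,
                    n_nodes = lengths(cells$nodes),
                    evaluable = NA, or_auc = NA_real_, p_auc = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    a <- cells$label_a[i]; b <- cells$label_b[i]
    if (sizes[[a]] < min_nodes || sizes[[b]] < min_nodes) {
      res$evaluable[i] <- FALSE
      res$note[i] <- sprintf("member network below %d nodes", min_nodes)
      next
    }
    out <- tryCatch({
      idx <- match(cells$nodes[[i]], rownames(dlist[[1]]))
      if (anyNA(idx)) stop("partition nodes missing from connectomes")
      fm <- cohort_feature_matrix(dlist, idx)
      feats <- cbind(data.frame(subject_id = ids,
                                stringsAsFactors = FALSE),
                     as.data.frame(fm, row.names = FALSE))
      fit <- fit_group_model(feats, phenotypes, case = case)
      list(feats = feats, fit = fit)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      res$evaluable[i] <- FALSE
      res$note[i] <- conditionMessage(out)
      next
    }
    res$evaluable[i] <- TRUE
    cell_features[[i]] <- out$feats
    row <- out$fit$coefficients[out$fit$coefficients$term == "auc", ]
    res$or_auc[i] <- row$or
    res$p_auc[i] <- row$p
  }
  structure(list(cells = res, k = k, partition = partition,
                 phenotypes = phenotypes, case = case,
                 cell_features = cell_features),
            class = "subnetwork_scan")
}

#' @export
print.subnetwork_scan <- function(x, digits = 3, ...) {
  cat("Subnetwork scan:", x$k, "networks,", nrow(x$cells), "cells\n")
  tab <- x$cells[c("label_a", "label_b", "n_nodes", "or_auc", "p_auc")]
  tab$or_auc <- signif(tab$or_auc, digits)
  tab$p_auc <- signif(tab$p_auc, digits)
  if (!is.null(x$cells$cluster)) {
    tab$cluster <- x$cells$cluster
    tab$p_fwe <- signif(x$cells$p_fwe, digits)
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

# Connected clusters of significant cells on the network-of-networks graph:
# networks are vertices, internetwork cells edges, intranetwork cells
# self-loops contributing their vertex. Returns per-cell cluster membership
# and per-cluster cell counts.
cluster_cells <- function(label_a, label_b, sig) {
  sig[is.na(sig)] <- FALSE
  if (!any(sig)) {
    return(list(membership = rep(NA_integer_, length(sig)),
                sizes = integer(0)))
  }
  verts <- sort(unique(c(label_a[sig], label_b[sig])))
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in which(sig & label_a != label_b)) {
    ra <- find(match(label_a[e], verts))
    rb <- find(match(label_b[e], verts))
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(verts), find, integer(1))
  comp_id <- match(comp, unique(comp))
  membership <- rep(NA_integer_, length(sig))
  membership[sig] <- comp_id[match(label_a[sig], verts)]
  list(membership = membership,
       sizes = as.integer(table(membership)))
}

#' Permutation family-wise error correction of a subnetwork scan
#'
#' Cluster-based FWE in the spirit of the network-based statistic,
#' transliterated to the intranetwork/internetwork cell grid: cells with
#' two-sided AUC-term p below `alpha_cell` are marked significant; clusters
#' are connected components of significant cells on the network-of-networks
#' graph (internetwork cells are edges, intranetwork cells self-loops); the
#' cluster statistic is the number of cells in the cluster. The null
#' distribution of the maximum cluster statistic is built by permuting the
#' diagnostic labels across subjects (covariates stay attached to their
#' subjects) and re-fitting every cell `n_perm` times; each observed cluster
#' gets the add-one p-value (1 + #\{null max >= observed\}) / (1 + n_perm).
#'
#' @param scan A [subnetwork_scan()] result.
#' @param n_perm Number of label permutations; 10000 matches routine use.
#' @param seed Integer seed for the permutation stream.
#' @param alpha_cell Cell-level two-sided significance threshold.
#' @return The scan with `cluster` and `p_fwe` columns added to `$cells`,
#'   plus `$clusters` (per-cluster table) and `$null_max` (null maxima).
#' @export
fwe_correct <- function(scan, n_perm = 10000, seed = 1L, alpha_cell = 0.05) {
  stopifnot(inherits(scan, "subnetwork_scan"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (1 / (1 + n_perm) > alpha_cell) {
    warning("n_perm too small to ever reach alpha = ", alpha_cell)
  }
  cells <- scan$cells
  eval_ix <- which(cells$evaluable %in% TRUE)

  # fixed per-cell designs; only the outcome is permuted
  designs <- lapply(eval_ix, function(i) {
    feats <- scan$cell_features[[i]]
    phen <- scan$phenotypes
    dat <- merge(feats, phen[c("subject_id", "group", "sex", "age", "motion")],
                 by = "subject_id")
    grp <- as_group01(dat$group, case = scan$case)
    dat$sex <- as_group01(dat$sex)$y
    dat <- zscore_features(dat, cols = c("auc", "kurtosis", "slope",
                                         "age", "motion"))
    X <- cbind(1, dat$auc, dat$kurtosis, dat$slope, dat$sex, dat$age,
               dat$motion)
    list(X = X, y = grp$y)
  })
  obs_sig <- rep(NA, nrow(cells))
  obs_sig[eval_ix] <- cells$p_auc[eval_ix] < alpha_cell
  obs_cl <- cluster_cells(cells$label_a, cells$label_b, obs_sig)

  if (length(designs) == 0 || length(obs_cl$sizes) == 0) {
    cells$cluster <- obs_cl$membership
    cells$p_fwe <- NA_real_
    scan$cells <- cells
    scan$clusters <- data.frame(cluster = integer(0), n_cells = integer(0),
                                p_fwe = numeric(0))
    scan$null_max <- integer(0)
    scan$alpha_cell <- alpha_cell
    scan$n_perm <- as.integer(n_perm)
    return(scan)
  }
  y <- designs[[1]]$y  # identical subject order across cells by construction

  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    yb <- with_seed(derive_seed(seed, b), sample(y))
    pvals <- vapply(designs, function(d) wald_p_logistic(d$X, yb, 2L),
                    numeric(1))
    sig <- rep(NA, nrow(cells))
    sig[eval_ix] <- !is.na(pvals) & pvals < alpha_cell
    cl <- cluster_cells(cells$label_a, cells$label_b, sig)
    null_max[b] <- if (length(cl$sizes)) max(cl$sizes) else 0L
  }

  cells$cluster <- obs_cl$membership
  cells$p_fwe <- NA_real_
  clusters <- data.frame(cluster = seq_along(obs_cl$sizes),
                         n_cells = obs_cl$sizes,
                         p_fwe = NA_real_)
  for (cl in seq_along(obs_cl$sizes)) {
    p <- (1 + sum(null_max >= obs_cl$sizes[cl])) / (1 + n_perm)
    clusters$p_fwe[cl] <- p
    cells$p_fwe[which(cells$cluster == cl)] <- p
  }
  scan$cells <- cells
  scan$clusters <- clusters
  scan$null_max <- null_max
  scan$alpha_cell <- alpha_cell
  scan$n_perm <- as.integer(n_perm)
  scan
}

#' Edge-wise proportion contrast at fixed filtration values
#'
#' For each edge and filtration value eps, a subject "shows" the edge when
#' its correlation distance satisfies d <= eps. The proportion of subjects
#' showing each edge is compared between groups with the pooled two-sample
#' proportion z-test (two-sided); edges are flagged at p < `alpha`
#' (uncorrected). Edges with zero pooled variance (present in everyone or
#' no one) report p = 1.
#'
#' @param dms Named list of subject `distance_matrix` (or connectivity)
#'   objects.
#' @param groups Vector of diagnostic labels, one per subject.
#' @param eps Filtration value(s) in \[0, 2\]; default `c(0.35, 0.5, 0.75, 1)`.
#' @param case Case level of `groups`.
#' @param alpha Uncorrected edge-level threshold (default 0.01).
#' @return Long data frame: `node_i`, `node_j`, `eps`, `prop_case`,
#'   `prop_control`, `diff`, `p`, `mask`.
#' @export
edge_proportion_test <- function(dms, groups, eps = c(0.35, 0.5, 0.75, 1),
                                 case = NULL, alpha = 0.01) {
  if (any(eps < 0 | eps > 2)) stop("eps must lie in [0, 2]")
  dms <- lapply(dms, function(m) {
    if (inherits(m, "connectivity_matrix")) to_distance(m)
    else as_distance_matrix(m)
  })
  grp <- as_group01(groups, case = case)
  if (sum(grp$y) == 0 || sum(1 - grp$y) == 0) {
    stop("both groups must be non-empty")
  }
  n <- nrow(dms[[1]])
  ut <- which(upper.tri(dms[[1]]))
  ij <- arrayInd(ut, c(n, n))
  ids <- rownames(dms[[1]])
  D <- vapply(dms, function(m) unclass(m)[ut], numeric(length(ut)))
  if (is.null(dim(D))) D <- matrix(D, nrow = length(ut))

  n1 <- sum(grp$y); n0 <- sum(1 - grp$y)
  out <- lapply(eps, function(e) {
    pres <- D <= e
    p1 <- rowSums(pres[, grp$y == 1, drop = FALSE]) / n1
    p0 <- rowSums(pres[, grp$y == 0, drop = FALSE]) / n0
    pp <- (p1 * n1 + p0 * n0) / (n1 + n0)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n0)
    z <- ifelse(v > 0, (p1 - p0) / sqrt(v), 0)
    p <- ifelse(v > 0, 2 * pnorm(-abs(z)), 1)
    data.frame(node_i = ids[ij[, 1]], node_j = ids[ij[, 2]], eps = e,
               prop_case = p1, prop_control = p0, diff = p1 - p0,
               p = p, mask = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohen's d from group summaries
#'
#' Pooled-SD standardized mean difference from per-group summary statistics,
#' as used for descriptive effect sizes of dimensional phenotypes.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size.
#' @param mean2,sd2,n2 Second group's mean, SD, size.
#' @return Cohen's d = (mean1 - mean2) / s_pooled.
#' @examples
#' cohens_d_summary(12.26, 3.07, 96, 10.5, 2.48, 81)  # ~0.63
#' @export
cohens_d_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be positive")
  if (any(c(n1, n2) < 2)) stop("group sizes must be at least 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product odds ratio (a d) / (b c) with the Haldane-Anscombe +0.5
#' correction to every cell when any cell is zero.
#'
#' @param a,b,c,d Non-negative counts; rows are groups, columns outcome
#'   levels (`a`/`b` in group 1, `c`/`d` in group 2).
#' @return The odds ratio.
#' @examples
#' odds_ratio_2x2(51, 45, 22, 59)  # ~3.04
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("a full row or column of the table is zero; odds ratio undefined")
  }
  if (any(cnt == 0)) cnt <- cnt + 0.5
  (cnt[1] * cnt[4]) / (cnt[2] * cnt[3])
}
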