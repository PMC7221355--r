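#' Kendall's coefficient of concordance (W)
#'
#' Rank-based agreement of m raters (here: parcellations) over n subjects,
#' with mid-rank ties and the standard tie correction:
#' W = 12 S / (m^2 (n^3 - n) - m sum(T)), where S is the sum of squared
#' deviations of the subject rank sums and T the per-rater tie term
#' sum(t^3 - t) over tie groups. Significance uses the large-sample
#' chi-squared approximation chi2 = m (n - 1) W on n - 1 degrees of freedom;
#' a permutation p-value (shuffling each rater's scores independently) is
#' available for small n.
#'
#' @param ratings Numeric matrix, m raters in rows, n subjects in columns
#'   (m >= 2, n >= 3, no missing values).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm,seed Permutation count and seed for `p_method =
#'   "permutation"`.
#' @return An object of class `kcc` with fields `w`, `m`, `n`, `chi2`,
#'   `df`, `p`.
#' @export
kendalls_w <- function(ratings, p_method = c("chisq", "permutation"),
                       n_perm = 1000, seed = 1L) {
  p_method <- match.arg(p_method)
  x <- as.matrix(ratings)
  m <- nrow(x); n <- ncol(x)
  if (m < 2) stop("need at least 2 raters")
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(x)) stop("ratings contain missing values")

  w_stat <- function(x) {
    rk <- t(apply(x, 1, rank))  # mid-ranks within each rater
    rsum <- colSums(rk)
    s <- sum((rsum - mean(rsum))^2)
    tie <- sum(apply(rk, 1, function(r) {
      t <- table(r); sum(t^3 - t)
    }))
    denom <- m^2 * (n^3 - n) - m * tie
    if (denom <= 0) return(NA_real_)
    12 * s / denom
  }
  w <- w_stat(x)
  chi2 <- m * (n - 1) * w
  df <- n - 1
  p <- if (p_method == "chisq") {
    pchisq(chi2, df = df, lower.tail = FALSE)
  } else {
    with_seed(seed, {
      null_w <- vapply(seq_len(n_perm), function(b) {
        w_stat(t(apply(x, 1, sample)))
      }, numeric(1))
      (1 + sum(null_w >= w)) / (1 + n_perm)
    })
  }
  structure(list(w = w, m = m, n = n, chi2 = chi2, df = df, p = p,
                 p_method = p_method),
            class = "kcc")
}

#' @export
print.kcc <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (m = %d raters, n = %d)\n", x$w, x$m, x$n))
  cat(sprintf("  chi2(%d) = %.2f, p = %.3g [%s]\n", x$df, x$chi2, x$p,
              x$p_method))
  invisible(x)
}

#' Critical value of Kendall's W
#'
#' Smallest W significant at level `alpha` under the chi-squared
#' approximation: W* = qchisq(1 - alpha, n - 1) / (m (n - 1)).
#'
#' @param m Number of raters (>= 2).
#' @param n Number of subjects (>= 3).
#' @param alpha Significance level in (0, 1).
#' @return The critical W.
#' @examples
#' kcc_critical(2, 177, 0.05)  # ~0.59
#' @export
kcc_critical <- function(m, n, alpha = 0.05) {
  stopifnot(m >= 2, n >= 3)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  qchisq(1 - alpha, df = n - 1) / (m * (n - 1))
}

#' Pairwise concordance of curve features across parcellations
#'
#' For every feature and every unordered pair of parcellations, computes
#' Kendall's W with m = 2 raters over the common subjects — the
#' cross-parcellation reliability grid of the curve features.
#'
#' @param feature_tables Named list (one entry per parcellation) of data
#'   frames with `subject_id` and the feature columns.
#' @param features Feature columns to compare.
#' @return Long data frame: `feature`, `parcellation_a`, `parcellation_b`,
#'   `w`, `chi2`, `df`, `p`.
#' @export
pairwise_kcc <- function(feature_tables,
                         features = c("auc", "slope", "kurtosis")) {
  stopifnot(is.list(feature_tables), length(feature_tables) >= 2)
  nm <- names(feature_tables) %||% paste0("P", seq_along(feature_tables))
  ids <- sort(feature_tables[[1]]$subject_id)
  for (tab in feature_tables) {
    if (!identical(sort(tab$subject_id), ids)) {
      stop("feature tables must cover the same subjects")
    }
  }
  aligned <- lapply(feature_tables, function(tab) {
    tab[match(ids, tab$subject_id), , drop = FALSE]
  })
  out <- list()
  for (f in features) {
    for (i in seq_along(aligned)) {
      for (j in seq_along(aligned)) {
        if (j <= i) next
        kcc <- kendalls_w(rbind(aligned[[i]][[f]], aligned[[j]][[f]]))
        out[[length(out) + 1L]] <- data.frame(
          feature = f, parcellation_a = nm[i], parcellation_b = nm[j],
          w = kcc$w, chi2 = kcc$chi2, df = kcc$df, p = kcc$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
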