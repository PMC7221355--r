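#' Rewire a connectivity matrix
#'
#' Weighted null model for one subject: the off-diagonal weights are
#' redistributed over the complete graph's edges while the weight multiset is
#' exactly preserved (so every moment of the weight distribution is
#' conserved), destroying the community topology that structures the Betti-0
#' curve. The default carries this out as a seeded sequence of 10 E random
#' transpositions of upper-triangle entries (E = n(n-1)/2), mirrored to the
#' lower triangle; `method = "shuffle"` draws one uniform permutation of the
#' weights instead. The two are statistically equivalent on a complete
#' weighted graph.
#'
#' @param cm A [connectivity_matrix].
#' @param seed Integer seed; the same seed always reproduces the same
#'   rewiring, and the caller's RNG state is left untouched.
#' @param method `"transpositions"` (default) or `"shuffle"`.
#' @return A rewired [connectivity_matrix].
#' @export
rewire <- function(cm, seed = NULL, method = c("transpositions", "shuffle")) {
  cm <- as_connectivity_matrix(cm)
  method <- match.arg(method)
  n <- nrow(cm)
  if (n < 3) stop("rewiring needs at least 3 nodes")
  ut <- upper.tri(cm)
  w <- unclass(cm)[ut]
  w_new <- with_seed(seed, {
    if (method == "shuffle") sample(w)
    else .transpose_weights(w, as.integer(10 * length(w)))
  })
  out <- unclass(cm)
  out[ut] <- w_new
  out <- t(out)
  out[ut] <- w_new
  out <- t(out)
  diag(out) <- 1
  structure(out, class = class(cm))
}

#' Null ensemble of Betti-0 features under rewiring
#'
#' Repeatedly rewires one subject's connectome and recomputes the three curve
#' features, building the per-subject null distribution against which the
#' observed features are compared. Permutation i uses the sub-seed
#' `derive_seed(seed, i)`, so the ensemble is reproducible and
#' order-independent.
#'
#' @param cm A [connectivity_matrix] (n >= 5).
#' @param n_perm Number of rewirings; 1000 matches routine use, tests and
#'   examples use fewer.
#' @param seed Master seed.
#' @param method Passed to [rewire()].
#' @return An object of class `null_ensemble`: list with `features`
#'   (n_perm x 3 data frame of auc, slope, kurtosis), `n_perm`, `seed`.
#' @export
null_features <- function(cm, n_perm = 1000, seed = 1L,
                          method = c("transpositions", "shuffle")) {
  cm <- as_connectivity_matrix(cm)
  method <- match.arg(method)
  if (n_perm < 1) stop("n_perm must be at least 1")
  rows <- lapply(seq_len(n_perm), function(i) {
    b0_features(rewire(cm, seed = derive_seed(seed, i), method = method))
  })
  structure(list(features = do.call(rbind, rows),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Rewiring null ensemble:", x$n_perm, "permutations (seed", x$seed,
      ")\n")
  print(summary(x$features))
  invisible(x)
}

#' Empirical p-value against a null ensemble
#'
#' Add-one permutation p-value: p = (1 + #\{null at least as extreme\}) /
#' (1 + n_perm), never smaller than 1/(1 + n_perm). The two-sided value
#' doubles the smaller tail and caps at 1.
#'
#' @param observed Observed feature value.
#' @param ensemble A `null_ensemble` (or a numeric vector of null values).
#' @param feature One of `"auc"`, `"slope"`, `"kurtosis"` (ignored for a
#'   numeric `ensemble`).
#' @param alternative `"two.sided"`, `"greater"` (observed in the upper tail)
#'   or `"less"`.
#' @return The empirical p-value.
#' @export
empirical_p <- function(observed, ensemble,
                        feature = c("auc", "slope", "kurtosis"),
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (inherits(ensemble, "null_ensemble")) {
    feature <- match.arg(feature)
    nulls <- ensemble$features[[feature]]
  } else {
    nulls <- as.numeric(ensemble)
  }
  if (length(nulls) == 0) stop("empty null ensemble")
  n <- length(nulls)
  p_ge <- (1 + sum(nulls >= observed)) / (1 + n)
  p_le <- (1 + sum(nulls <= observed)) / (1 + n)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}
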