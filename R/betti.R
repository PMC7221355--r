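#' Betti-0 curve of the Rips filtration
#'
#' Sweeping the filtration value eps over the correlation distance d = 1 - r
#' and connecting every node pair with d <= eps produces a nested family of
#' graphs. The zeroth Betti number B0(eps) is the number of connected
#' components of that graph: n isolated nodes at eps = 0, one component once
#' eps exceeds the last merge. The curve is fully determined by the n - 1
#' filtration values at which two components join, which equal the sorted
#' minimum-spanning-tree edge weights (single-linkage merge heights) of the
#' distance matrix.
#'
#' @param x A `distance_matrix`, a `connectivity_matrix` (converted via
#'   [to_distance()]), or a plain symmetric matrix of distances.
#' @return An object of class `b0_curve` with fields `n` (node count) and
#'   `merge_values` (non-decreasing numeric vector of length n - 1).
#' @examples
#' d <- matrix(c(0, .2, .5, .2, 0, .9, .5, .9, 0), 3, 3)
#' b0_curve(d)$merge_values  # 0.2, 0.5
#' @export
b0_curve <- function(x) {
  if (inherits(x, "connectivity_matrix")) x <- to_distance(x)
  d <- as_distance_matrix(x)
  merges <- .mst_merge_heights(unclass(d))
  new_b0_curve(merges, n = nrow(d))
}

#' Assemble a Betti-0 curve from merge values
#'
#' Low-level constructor used by file readers and tests; [b0_curve()] is the
#' usual entry point.
#'
#' @param merge_values Numeric vector of component-join filtration values.
#' @param n Node count; defaults to `length(merge_values) + 1`.
#' @return A `b0_curve`.
#' @export
new_b0_curve <- function(merge_values, n = length(merge_values) + 1L) {
  merge_values <- as.numeric(merge_values)
  if (anyNA(merge_values)) stop("merge values contain NA")
  if (is.unsorted(merge_values)) stop("merge values must be non-decreasing")
  if (length(merge_values) != n - 1L) {
    stop("expected ", n - 1L, " merge values for ", n, " nodes, got ",
         length(merge_values))
  }
  structure(list(n = as.integer(n), merge_values = merge_values),
            class = "b0_curve")
}

#' @export
print.b0_curve <- function(x, ...) {
  cat("Betti-0 curve:", x$n, "nodes;",
      if (x$n > 1) paste0("merges in [", sprintf("%.4g", min(x$merge_values)),
                          ", ", sprintf("%.4g", max(x$merge_values)), "]")
      else "no merges", "\n")
  invisible(x)
}

#' Number of components at a filtration value
#'
#' Evaluates the step function B0(eps) = n - #\{merge values <= eps\}. At
#' eps = 0 every node with a strictly positive distance to all others is its
#' own component, so B0(0) = n for generic data; B0 reaches 1 at the last
#' merge. Edges are included at d <= eps (non-strict), making the curve
#' right-continuous.
#'
#' @param curve A `b0_curve`.
#' @param eps Filtration value(s), each >= 0.
#' @return Integer vector of component counts.
#' @export
b0_at <- function(curve, eps) {
  stopifnot(inherits(curve, "b0_curve"))
  if (any(eps < 0)) stop("filtration value must be non-negative")
  curve$n - findInterval(eps, curve$merge_values)
}

#' @export
#' @rdname b0_curve
#' @param type,xlab,ylab,... Passed to [plot.default()].
plot.b0_curve <- function(x, type = "s", xlab = expression(epsilon),
                          ylab = expression(B[0]), ...) {
  eps <- c(0, x$merge_values, 2)
  plot(eps, c(x$n, x$n - seq_along(x$merge_values), 1),
       type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Area under the Betti-0 curve
#'
#' Exact integral of the step function B0(eps) over the fixed domain
#' \[0, 2\], the full range of the correlation distance. Fixing the domain
#' for all subjects and node subsets makes areas comparable across subjects:
#' the flat tail after the single component forms contributes the same
#' constant to everyone. Smaller areas mean components merge at lower
#' filtration values, i.e. less segregation.
#'
#' @param curve A `b0_curve`.
#' @param domain Integration interval; default `c(0, 2)`.
#' @return The area, in component x filtration units.
#' @export
b0_auc <- function(curve, domain = c(0, 2)) {
  stopifnot(inherits(curve, "b0_curve"), length(domain) == 2,
            domain[1] < domain[2])
  auc_from_merges(curve$merge_values, curve$n, domain)
}

auc_from_merges <- function(m, n, domain = c(0, 2)) {
  breaks <- c(domain[1], pmin(pmax(m, domain[1]), domain[2]), domain[2])
  sum(diff(breaks) * (n - 0:(n - 1L)))
}

#' Slope of the Betti-0 curve
#'
#' Ordinary least-squares slope of the points (eps_k, B0(eps_k)) sampled at
#' eps = 0 and at every merge value up to and including the last merge. The
#' OLS fit uses the whole staircase rather than the secant between endpoints;
#' the slope is negative whenever n >= 2 and not all merges sit at eps = 0,
#' with lower (more negative) values meaning a faster collapse to a single
#' component. Tied merges contribute replicated points.
#'
#' @param curve A `b0_curve`.
#' @return The slope, components per filtration unit.
#' @export
b0_slope <- function(curve) {
  stopifnot(inherits(curve, "b0_curve"))
  if (curve$n < 2) stop("slope undefined for fewer than 2 nodes")
  slope_from_merges(curve$merge_values, curve$n)
}

slope_from_merges <- function(m, n) {
  x <- c(0, m)
  # B0 evaluated at each merge: ties collapse to the count of merges <= m_j
  y <- c(n, n - findInterval(m, m))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("all merges at eps = 0; slope undefined")
  sum(xc * (y - mean(y))) / sxx
}

#' Kurtosis of the merge-value distribution
#'
#' Sample excess kurtosis (Fisher definition, bias-uncorrected: m4 / m2^2 - 3)
#' of the n - 1 component-merge filtration values. A more peaked merge
#' distribution — merges concentrated around a typical filtration value —
#' gives higher kurtosis, read as a faster transition to a single component.
#'
#' @param curve A `b0_curve` with at least 4 merge values (n >= 5).
#' @return Excess kurtosis, unitless.
#' @export
b0_kurtosis <- function(curve) {
  stopifnot(inherits(curve, "b0_curve"))
  if (length(curve$merge_values) < 4) {
    stop("kurtosis needs at least 4 merge values (n >= 5)")
  }
  kurtosis_from_merges(curve$merge_values)
}

kurtosis_from_merges <- function(m) {
  mc <- m - mean(m)
  m2 <- mean(mc^2)
  if (m2 == 0) stop("degenerate curve: zero variance of merge values")
  mean(mc^4) / m2^2 - 3
}

#' Scalar features of a Betti-0 curve
#'
#' The three curve summaries used for group inference: area under the curve
#' ([b0_auc()]), OLS slope ([b0_slope()]) and excess kurtosis of the merge
#' values ([b0_kurtosis()]).
#'
#' @param x A distance/connectivity matrix or a `b0_curve`; n >= 5.
#' @return A one-row data frame with columns `auc`, `slope`, `kurtosis`.
#' @export
b0_features <- function(x) {
  curve <- if (inherits(x, "b0_curve")) x else b0_curve(x)
  if (curve$n < 5) stop("features need at least 5 nodes")
  data.frame(auc = b0_auc(curve), slope = b0_slope(curve),
             kurtosis = b0_kurtosis(curve))
}

# Strip a cohort down to bare distance matrices for the fast feature path.
cohort_distances <- function(cms) {
  lapply(cms, function(m) {
    if (inherits(m, "distance_matrix")) return(unclass(m))
    if (!inherits(m, "connectivity_matrix")) m <- as_connectivity_matrix(m)
    unclass(to_distance(m))
  })
}

# Feature matrix over a cohort of bare distance matrices, optionally on a
# node-index subset. Skips per-call validation: inputs were validated when
# the distance list was built.
cohort_feature_matrix <- function(dlist, idx = NULL) {
  out <- matrix(NA_real_, length(dlist), 3,
                dimnames = list(names(dlist), c("auc", "slope", "kurtosis")))
  for (i in seq_along(dlist)) {
    d <- dlist[[i]]
    if (!is.null(idx)) d <- d[idx, idx]
    n <- nrow(d)
    m <- .mst_merge_heights(d)
    out[i, ] <- c(auc_from_merges(m, n), slope_from_merges(m, n),
                  kurtosis_from_merges(m))
  }
  out
}

#' Betti-0 features for a cohort of connectomes
#'
#' @param cms Named list of connectivity (or distance) matrices, one per
#'   subject.
#' @param nodes Optional node subset (labels or indices, as in
#'   [subset_nodes()]) restricting the filtration.
#' @return Data frame with columns `subject_id`, `auc`, `slope`, `kurtosis`.
#' @export
cohort_features <- function(cms, nodes = NULL) {
  ids <- names(cms) %||% as.character(seq_along(cms))
  dlist <- cohort_distances(cms)
  idx <- NULL
  if (!is.null(nodes)) {
    if (is.character(nodes)) {
      idx <- match(nodes, rownames(dlist[[1]]))
      if (anyNA(idx)) stop("unknown node label(s): ",
                           paste(nodes[is.na(idx)], collapse = ", "))
    } else idx <- as.integer(nodes)
    if (length(idx) < 5) stop("features need at least 5 nodes")
  }
  fm <- cohort_feature_matrix(dlist, idx)
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
        as.data.frame(fm, row.names = FALSE))
}
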