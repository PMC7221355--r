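#' Construct and validate a connectivity matrix
#'
#' A connectivity matrix is the node-by-node Pearson correlation matrix of one
#' subject's regional signals: symmetric, unit diagonal, off-diagonal entries
#' in \[-1, 1\]. It is the node set on which the Rips filtration is built.
#'
#' Mild asymmetry (entries differing by at most `sym_tol`, as produced by text
#' round-trips) is repaired by averaging the two triangles; larger asymmetry
#' is an error. Diagonal values in the input are ignored and forced to 1.
#'
#' @param r Square numeric matrix of correlations.
#' @param node_ids Character vector of node labels; defaults to the matrix
#'   dimnames, or `V1..Vn` when absent.
#' @param sym_tol Largest tolerated absolute asymmetry before averaging.
#' @return A matrix of class `connectivity_matrix` with node ids as dimnames.
#' @export
connectivity_matrix <- function(r, node_ids = NULL, sym_tol = 1e-6) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) {
    stop("connectivity matrix must be square, got ", nrow(r), "x", ncol(r))
  }
  n <- nrow(r)
  if (!is.numeric(r) || anyNA(r) || any(!is.finite(r))) {
    stop("connectivity matrix contains missing or non-finite values")
  }
  if (is.null(node_ids)) node_ids <- rownames(r) %||% paste0("V", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length does not match matrix order")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")

  asym <- max(abs(r - t(r)))
  if (asym > sym_tol) {
    stop("matrix asymmetry ", format(asym), " exceeds tolerance ", sym_tol)
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  off <- r[upper.tri(r)]
  if (length(off) && (min(off) < -1 || max(off) > 1)) {
    stop("off-diagonal correlations must lie in [-1, 1]; range is [",
         format(min(off)), ", ", format(max(off)), "]")
  }
  dimnames(r) <- list(node_ids, node_ids)
  structure(r, class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Connectivity matrix:", nrow(x), "nodes, off-diagonal r in [",
      sprintf("%.3f", min(x[upper.tri(x)])), ",",
      sprintf("%.3f", max(x[upper.tri(x)])), "]\n")
  invisible(x)
}

node_ids <- function(x) rownames(x)

#' Pearson connectome from node-averaged time series
#'
#' Computes the all-pairs Pearson cross-correlation matrix of regional
#' signals, the functional connectome of one subject.
#'
#' @param timeseries Numeric matrix of node-averaged signals, time points in
#'   rows and nodes in columns (set `nodes_in = "rows"` for the transpose).
#' @param node_ids Optional node labels; defaults to column names.
#' @param nodes_in Orientation of `timeseries`.
#' @return A [connectivity_matrix].
#' @examples
#' ts <- matrix(rnorm(200 * 10), 200, 10)
#' cm <- pearson_connectome(ts)
#' @export
pearson_connectome <- function(timeseries, node_ids = NULL,
                               nodes_in = c("columns", "rows")) {
  nodes_in <- match.arg(nodes_in)
  ts <- as.matrix(timeseries)
  if (nodes_in == "rows") ts <- t(ts)
  if (anyNA(ts)) stop("time series contain missing values")
  if (nrow(ts) < 3) stop("need at least 3 time points, got ", nrow(ts))
  tc <- ts - rep(colMeans(ts), each = nrow(ts))
  ss <- colSums(tc^2)
  if (any(ss == 0)) {
    bad <- which(ss == 0)
    lab <- colnames(ts)[bad] %||% as.character(bad)
    stop("constant time series for node(s): ", paste(lab, collapse = ", "))
  }
  s <- sqrt(ss)
  r <- crossprod(tc) / outer(s, s)
  # clamp eps-level excursions from the closed form before validation
  r[r > 1] <- 1
  r[r < -1] <- -1
  connectivity_matrix(r, node_ids = node_ids %||% colnames(ts))
}

#' Correlation distance matrix of a connectome
#'
#' Applies the correlation dissimilarity d = 1 - r elementwise, the metric on
#' which the Rips filtration is swept: d = 0 for perfectly correlated nodes,
#' 2 for perfectly anticorrelated ones. The diagonal is forced to 0.
#'
#' @param cm A [connectivity_matrix].
#' @return A matrix of class `distance_matrix` with entries in \[0, 2\].
#' @export
to_distance <- function(cm) {
  cm <- as_connectivity_matrix(cm)
  d <- 1 - unclass(cm)
  diag(d) <- 0
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

as_connectivity_matrix <- function(x) {
  if (inherits(x, "connectivity_matrix")) x else connectivity_matrix(x)
}

as_distance_matrix <- function(x) {
  if (inherits(x, "distance_matrix")) return(x)
  d <- as.matrix(x)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (anyNA(d)) stop("distance matrix contains missing values")
  if (max(abs(d - t(d))) > 1e-6) stop("distance matrix is not symmetric")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (min(d) < 0 || max(d) > 2) stop("distances must lie in [0, 2]")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("V", seq_len(nrow(d))),
                        paste0("V", seq_len(nrow(d))))
  }
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Distance matrix (1 - r):", nrow(x), "nodes\n")
  invisible(x)
}

#' Principal submatrix of a connectome
#'
#' Restricts a connectivity or distance matrix to a node subset, preserving
#' symmetry and the diagonal. Used to re-run the filtration on intranetwork
#' and internetwork node sets.
#'
#' @param m A `connectivity_matrix` or `distance_matrix`.
#' @param nodes Distinct node labels or positional indices, at least 2.
#' @return The submatrix, same class, node ids reordered accordingly.
#' @export
subset_nodes <- function(m, nodes) {
  if (!inherits(m, c("connectivity_matrix", "distance_matrix"))) {
    stop("subset_nodes expects a connectivity_matrix or distance_matrix")
  }
  if (is.character(nodes)) {
    idx <- match(nodes, rownames(m))
    if (anyNA(idx)) {
      stop("unknown node label(s): ",
           paste(nodes[is.na(idx)], collapse = ", "))
    }
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1 | idx > nrow(m))) stop("node index out of range")
  }
  if (anyDuplicated(idx)) stop("duplicate nodes in subset")
  if (length(idx) < 2) stop("subset needs at least 2 nodes")
  cls <- class(m)
  out <- unclass(m)[idx, idx, drop = FALSE]
  structure(out, class = cls)
}

#' Construct a node partition
#'
#' Maps every node to exactly one network (or lobe) label. A partition with k
#' labels induces k intranetwork subsets and k(k-1)/2 internetwork subsets.
#'
#' @param labels Character vector of network labels, one per node.
#' @param node_ids Node labels; defaults to the names of `labels`.
#' @return A named character vector of class `node_partition`.
#' @export
node_partition <- function(labels, node_ids = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("empty partition")
  if (anyNA(labels)) stop("partition labels contain NA")
  node_ids <- as.character(node_ids %||% names(labels) %||%
                             paste0("V", seq_along(labels)))
  if (length(node_ids) != length(labels)) {
    stop("node_ids length does not match labels")
  }
  if (anyDuplicated(node_ids)) stop("duplicate node ids in partition")
  names(labels) <- node_ids
  structure(labels, class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  tab <- table(unclass(x))
  cat("Node partition:", length(x), "nodes in", length(tab), "networks\n")
  print(tab)
  invisible(x)
}

n_networks <- function(p) length(unique(unclass(p)))

#' Enumerate intranetwork and internetwork node subsets
#'
#' For a partition with k labels, yields the k intranetwork subsets (one
#' network's nodes) and the k(k-1)/2 internetwork subsets (the union of two
#' networks' nodes), k(k+1)/2 subsets in total, in deterministic sorted-label
#' order. Internetwork subsets take the union of both member networks, so the
#' intra-network edges of both members participate in the filtration.
#'
#' @param p A [node_partition].
#' @return A data frame with columns `label_a`, `label_b` (equal for
#'   intranetwork cells) and a list column `nodes` of member node ids.
#' @examples
#' p <- node_partition(rep(c("A", "B", "C"), each = 4))
#' nrow(enumerate_subnetworks(p))  # 3 * 4 / 2 = 6
#' @export
enumerate_subnetworks <- function(p) {
  if (!inherits(p, "node_partition")) p <- node_partition(p)
  labs <- sort(unique(unclass(p)))
  k <- length(labs)
  grid <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(label_a = labs[i], label_b = labs[i:k],
               stringsAsFactors = FALSE)
  }))
  members <- split(names(p), unclass(p))
  grid$nodes <- lapply(seq_len(nrow(grid)), function(row) {
    a <- grid$label_a[row]; b <- grid$label_b[row]
    if (a == b) members[[a]] else c(members[[a]], members[[b]])
  })
  stopifnot(nrow(grid) == k * (k + 1) / 2)
  grid
}

#' Aggregate node time series into parcel time series
#'
#' Averages node signals within each label of a partition, emulating the
#' extraction of region-average signals under a coarser parcellation of the
#' same underlying sources.
#'
#' @param timeseries Time-by-node matrix with node ids as column names.
#' @param p A [node_partition] over those nodes.
#' @return A time-by-parcel matrix, columns named by partition label.
#' @export
parcellate_timeseries <- function(timeseries, p) {
  ts <- as.matrix(timeseries)
  if (is.null(colnames(ts))) colnames(ts) <- paste0("V", seq_len(ncol(ts)))
  if (!all(colnames(ts) %in% names(p))) {
    stop("partition does not cover all time-series nodes")
  }
  labs <- unclass(p)[colnames(ts)]
  groups <- split(seq_len(ncol(ts)), labs)
  out <- vapply(groups, function(ix) rowMeans(ts[, ix, drop = FALSE]),
                numeric(nrow(ts)))
  out
}
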