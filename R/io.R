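#' Read and write connectivity matrices
#'
#' Connectome files are square numeric CSV grids, with an optional header
#' row of node labels. On read, the diagonal is forced to 1, entries
#' differing from their transpose by at most `sym_tol` are averaged, and
#' larger asymmetry or out-of-range correlations are rejected.
#'
#' @param path File path.
#' @param header Whether the file has a node-label header row.
#' @param sym_tol Symmetrization tolerance (see [connectivity_matrix()]).
#' @return [connectivity_matrix()] for `read_connectome`; the path,
#'   invisibly, for `write_connectome`.
#' @export
read_connectome <- function(path, header = NA, sym_tol = 1e-6) {
  first <- readLines(path, n = 1)
  if (is.na(header)) {
    header <- anyNA(suppressWarnings(as.numeric(strsplit(first, ",")[[1]])))
  }
  x <- read.csv(path, header = header, check.names = FALSE)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("connectome file contains non-numeric entries: ",
                           path)
  ids <- if (header) colnames(x) else NULL
  connectivity_matrix(m, node_ids = ids, sym_tol = sym_tol)
}

#' @rdname read_connectome
#' @param cm A [connectivity_matrix].
#' @export
write_connectome <- function(cm, path) {
  cm <- as_connectivity_matrix(cm)
  df <- as.data.frame(unclass(cm))
  names(df) <- rownames(cm)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a CSV with columns `subject_id`, `group`, `sex`, `age`, `motion`
#' (optionally `adhd_index`, `iq`). Validates that group and sex take
#' exactly two levels, ages are positive, motion non-negative and subject
#' ids unique.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_phenotypes <- function(path) {
  phen <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sex", "age", "motion")
  miss <- setdiff(need, names(phen))
  if (length(miss)) stop("missing phenotype column(s): ",
                         paste(miss, collapse = ", "))
  phen$subject_id <- as.character(phen$subject_id)
  if (anyDuplicated(phen$subject_id)) stop("duplicate subject ids")
  if (length(unique(phen$group)) != 2) stop("group must take exactly two levels")
  if (length(unique(phen$sex)) != 2) stop("sex must take exactly two levels")
  if (any(phen$age <= 0)) stop("ages must be positive")
  if (any(phen$motion < 0)) stop("motion must be non-negative")
  phen
}

#' Read a node partition
#'
#' Expects a CSV with columns `node_id`, `network`, one row per node.
#'
#' @param path File path.
#' @return A [node_partition].
#' @export
read_partition <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "network")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing partition column(s): ",
                         paste(miss, collapse = ", "))
  node_partition(x$network, node_ids = x$node_id)
}

#' @rdname read_partition
#' @param p A [node_partition].
#' @export
write_partition <- function(p, path) {
  write.csv(data.frame(node_id = names(p), network = unclass(p)),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a Betti-0 curve as breakpoints
#'
#' Writes the breakpoint representation (columns `epsilon`, `b0`): the
#' component count at 0 and immediately after each merge.
#'
#' @param curve A `b0_curve`.
#' @param path File path.
#' @export
write_b0_curve <- function(curve, path) {
  stopifnot(inherits(curve, "b0_curve"))
  eps <- c(0, curve$merge_values)
  write.csv(data.frame(epsilon = eps, b0 = b0_at(curve, eps)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_b0_curve
#' @export
read_b0_curve <- function(path) {
  x <- read.csv(path)
  if (!all(c("epsilon", "b0") %in% names(x))) {
    stop("curve file needs columns epsilon, b0")
  }
  new_b0_curve(x$epsilon[-1], n = x$b0[1])
}
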