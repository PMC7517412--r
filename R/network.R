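## Group-level structural covariance network: Pearson correlation of regional
## FD values across the subjects of a group, followed by proportional
## thresholding that keeps the strongest positive coefficients as weighted
## edges.

#' Inter-regional FD correlation matrix for one group
#'
#' Pearson product-moment correlation of each pair of regional FD columns
#' across the subjects of a group ("structural covariance"). Missing FD
#' values are handled by pairwise-complete subjects. Columns that are
#' constant (or with fewer than 2 complete pairs) produce undefined
#' correlations, which are recorded as 0 and counted.
#'
#' @param cohort An `fd_cohort`.
#' @param group Group label selecting the subjects.
#' @return A `correlation_matrix`: list with `values` (68 x 68 symmetric,
#'   unit diagonal), `n_subjects`, `group`, and `n_undefined` (entries
#'   replaced by 0).
#' @export
correlation_matrix <- function(cohort, group) {
  X <- fd_values(cohort, group)
  if (nrow(X) < 3)
    fd_stop("fdnet_domain_error", "at least 3 subjects are required per group")
  vals <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  n_undef <- sum(is.na(vals[upper.tri(vals)]))
  if (n_undef > 0) {
    fd_warn("fdnet_degenerate_warning", sprintf(
      "%d undefined correlation(s) recorded as 0", n_undef))
    vals[is.na(vals)] <- 0
  }
  diag(vals) <- 1
  dimnames(vals) <- list(colnames(X), colnames(X))
  structure(list(values = vals, n_subjects = nrow(X), group = group,
                 n_undefined = n_undef),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d x %d, group '%s', n = %d subjects\n",
              nrow(x$values), ncol(x$values), x$group, x$n_subjects))
  invisible(x)
}

corr_values <- function(x) {
  if (inherits(x, "correlation_matrix")) return(x$values)
  if (inherits(x, "brain_network")) return(x$adjacency)
  if (is.matrix(x)) return(x)
  fd_stop("fdnet_validation_error", "expected a matrix or correlation_matrix")
}

#' Proportional threshold of a correlation matrix
#'
#' Retains the strongest positive correlation coefficients as weighted,
#' undirected edges: the diagonal and all negative entries are set to 0, and
#' among the `E = n(n-1)/2` unique off-diagonal entries the
#' `ceiling(proportion * E)` largest positive values keep their weights
#' (fewer if the matrix has fewer positive entries). Entries tied exactly at
#' the cutoff are all kept, so the realized edge count can exceed the
#' requested count; it is reported alongside.
#'
#' @param corr A `correlation_matrix` or plain symmetric matrix.
#' @param proportion Fraction of unique entries to retain, in (0, 1]
#'   (default 0.20).
#' @param atlas Optional `fd_atlas` carried along for lobe summaries.
#' @return A `brain_network`: list with `adjacency` (non-negative symmetric,
#'   zero diagonal), `threshold_proportion`, `n_edges_requested`, `n_edges`
#'   (realized), `cutoff`, and `atlas`.
#' @export
#' @examples
#' m <- diag(4); m[upper.tri(m)] <- c(.9, .8, .5, .3, .2, -.4)
#' m <- m + t(m); diag(m) <- 1
#' threshold_proportional(m, 0.34)$n_edges
threshold_proportional <- function(corr, proportion = 0.20, atlas = NULL) {
  M <- corr_values(corr)
  if (!is.matrix(M) || nrow(M) != ncol(M))
    fd_stop("fdnet_validation_error", "correlation input must be square")
  if (max(abs(M - t(M))) > 1e-10)
    fd_stop("fdnet_validation_error", "correlation matrix must be symmetric")
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      proportion <= 0 || proportion > 1)
    fd_stop("fdnet_validation_error", "proportion must lie in (0, 1]")
  n <- nrow(M)
  ut <- upper.tri(M)
  E <- n * (n - 1) / 2
  requested <- ceiling(proportion * E)
  vals <- M[ut]
  pos <- vals[vals > 0]
  A <- matrix(0, n, n, dimnames = dimnames(M))
  if (length(pos) == 0) {
    fd_warn("fdnet_empty_network_warning",
            "no positive off-diagonal entries; returning an empty network")
    cutoff <- Inf
  } else {
    k <- min(requested, length(pos))
    cutoff <- sort(pos, decreasing = TRUE)[k]
    keep <- M >= cutoff
    diag(keep) <- FALSE
    A[keep] <- M[keep]
  }
  structure(list(adjacency = A, threshold_proportion = proportion,
                 n_edges_requested = requested,
                 n_edges = sum(A[ut] > 0), cutoff = cutoff,
                 atlas = atlas),
            class = "brain_network")
}

#' Construct a brain network from an adjacency matrix
#'
#' Low-level constructor for pre-thresholded, non-negative weighted
#' adjacency matrices (used by readers and in tests).
#'
#' @param adjacency Non-negative symmetric matrix with zero diagonal.
#' @param threshold_proportion Proportion recorded as having produced it.
#' @param atlas Optional `fd_atlas`.
#' @return A `brain_network`.
#' @export
brain_network <- function(adjacency, threshold_proportion = 1, atlas = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    fd_stop("fdnet_validation_error", "adjacency must be square")
  if (max(abs(adjacency - t(adjacency))) > 1e-10)
    fd_stop("fdnet_validation_error", "adjacency must be symmetric")
  if (any(adjacency < 0))
    fd_stop("fdnet_validation_error", "adjacency weights must be non-negative")
  if (any(diag(adjacency) != 0))
    fd_stop("fdnet_validation_error", "adjacency diagonal must be zero")
  structure(list(adjacency = adjacency,
                 threshold_proportion = threshold_proportion,
                 n_edges_requested = NA_integer_,
                 n_edges = sum(adjacency[upper.tri(adjacency)] > 0),
                 cutoff = NA_real_, atlas = atlas),
            class = "brain_network")
}

as_brain_network <- function(x) {
  if (inherits(x, "brain_network")) return(x)
  if (is.matrix(x)) return(brain_network(x))
  fd_stop("fdnet_validation_error", "expected a brain_network or adjacency matrix")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf(
    "<brain_network> %d nodes, %d edges (proportion %.2f, requested %s)\n",
    nrow(x$adjacency), x$n_edges, x$threshold_proportion,
    ifelse(is.na(x$n_edges_requested), "-", x$n_edges_requested)))
  invisible(x)
}
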