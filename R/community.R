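## Weighted modularity and module detection.
##
## Modularity of a partition c on a weighted network A:
##   Q = (1/2m) * sum_ij [ A_ij - k_i k_j / 2m ] delta(c_i, c_j)
## with k_i the strength of node i and m half the total weight. Modules are
## found by greedy multilevel (Louvain-style) maximisation implemented in
## the package: seeded random node sweeps, aggregation while Q improves,
## best partition over restarts.

#' Modularity of a partition
#'
#' @param network A `brain_network` (or non-negative symmetric adjacency
#'   matrix) with at least one edge.
#' @param assignment Integer vector assigning every node a module id, or a
#'   `module_partition`.
#' @return The modularity Q.
#' @export
#' @examples
#' A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
#' modularity_q(A, c(1, 1, 2, 2))  # 0.5
modularity_q <- function(network, assignment) {
  W <- as_brain_network(network)$adjacency
  if (inherits(assignment, "module_partition")) assignment <- assignment$assignment
  assignment <- as.integer(assignment)
  n <- nrow(W)
  if (length(assignment) != n || anyNA(assignment))
    fd_stop("fdnet_validation_error", "assignment must cover every node")
  m2 <- sum(W)
  if (m2 <= 0)
    fd_stop("fdnet_domain_error", "modularity is undefined for an all-zero network")
  k <- rowSums(W)
  f <- factor(assignment)
  S <- rowsum(t(rowsum(W, f)), f)          # community x community weight sums
  K <- tapply(k, f, sum)
  sum(diag(as.matrix(S)) / m2 - (K / m2)^2)
}

## One full multilevel run; node orders come from the caller's RNG stream.
louvain_run <- function(W) {
  n <- nrow(W)
  mem <- seq_len(n)
  Wcur <- W
  repeat {
    nc <- nrow(Wcur)
    lv <- .louvain_local_move(Wcur, sample.int(nc))
    lv <- match(lv, unique(lv))
    C <- max(lv)
    if (C == nc) break                     # no merge at this level
    mem <- lv[mem]
    f <- factor(lv, levels = seq_len(C))
    Wcur <- rowsum(t(rowsum(Wcur, f)), f)
    if (C == 1) break
  }
  mem
}

#' Detect modules by greedy multilevel modularity maximisation
#'
#' Runs `n_restarts` independent Louvain-style searches (node sweep order
#' shuffled per restart by the seeded RNG; aggregation continues while Q
#' improves) and keeps the best partition by Q, preferring the first
#' encountered among exact ties. Module ids are renumbered by decreasing
#' module size, ties broken by the smallest contained node index, so module
#' 1 is always the largest. If no partition with Q >= 0 is found the trivial
#' all-in-one partition (Q = 0) is returned. Deterministic given `seed`.
#'
#' @param network A `brain_network` (or adjacency matrix) with >= 1 edge.
#' @param seed Integer seed.
#' @param n_restarts Number of restarts (default 100).
#' @return A `module_partition`: list with `assignment` (integer module id
#'   per node, named by the adjacency row names), `n_modules`, and `q`.
#' @export
detect_modules <- function(network, seed = 1L, n_restarts = 100L) {
  net <- as_brain_network(network)
  W <- net$adjacency
  if (sum(W) <= 0)
    fd_stop("fdnet_domain_error", "module detection requires at least one edge")
  if (!is_count(n_restarts))
    fd_stop("fdnet_validation_error", "n_restarts must be a positive integer")
  n <- nrow(W)
  best <- NULL
  best_q <- -Inf
  local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mem <- louvain_run(W)
      q <- modularity_q(net, mem)
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- mem
      }
    }
  })
  if (best_q < 0) {                        # never worse than all-in-one
    best <- rep(1L, n)
    best_q <- modularity_q(net, best)
  }
  assignment <- renumber_modules(best)
  names(assignment) <- rownames(W)
  structure(list(assignment = assignment,
                 n_modules = max(assignment),
                 q = modularity_q(net, assignment)),
            class = "module_partition")
}

## Renumber module ids 1..C by decreasing size, ties by smallest node index.
renumber_modules <- function(mem) {
  mem <- match(mem, unique(mem))
  sizes <- tabulate(mem)
  first <- vapply(seq_along(sizes), function(c) min(which(mem == c)), integer(1))
  rank <- order(-sizes, first)
  match(mem, rank)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules (sizes %s), Q = %.4f\n",
              x$n_modules,
              paste(tabulate(x$assignment), collapse = "/"), x$q))
  invisible(x)
}

#' Export a module partition as a region table
#'
#' @param partition A `module_partition` over the 68 atlas regions.
#' @param atlas An `fd_atlas`.
#' @return Data frame with columns `roi`, `abbreviation`, `hemisphere`,
#'   `lobe`, `module`.
#' @export
partition_table <- function(partition, atlas = load_default_atlas()) {
  atlas <- as_atlas(atlas)
  if (length(partition$assignment) != 68)
    fd_stop("fdnet_validation_error", "partition must cover the 68 atlas regions")
  data.frame(roi = atlas$index, abbreviation = atlas$abbreviation,
             hemisphere = atlas$hemisphere, lobe = atlas$lobe,
             module = as.integer(partition$assignment))
}
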