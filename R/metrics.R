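## Node-level connectivity metrics and lobe summaries.
##
## Within-module degree z-score: z_i = (k_i - mean_{c(i)} k) / sd_{c(i)} k,
## with k_i the node's connectivity to its own module (edge count in binary
## mode, strength in weighted mode) and the mean/SD taken over the module's
## nodes (population SD). Participation coefficient:
## P_i = 1 - sum_c (k_ic / k_i)^2, 0 for a purely intra-modular (or
## isolated) node, approaching 1 for connectivity spread across modules.

metric_matrix <- function(network, weighted) {
  W <- as_brain_network(network)$adjacency
  if (weighted) W else (W > 0) * 1
}

check_partition <- function(assignment, n) {
  if (inherits(assignment, "module_partition")) assignment <- assignment$assignment
  assignment <- as.integer(assignment)
  if (length(assignment) != n || anyNA(assignment))
    fd_stop("fdnet_validation_error", "partition must assign every node a module")
  assignment
}

#' Within-module degree z-score
#'
#' @param network A `brain_network` or adjacency matrix.
#' @param partition A `module_partition` or integer module assignment.
#' @param weighted Use strengths (`TRUE`, default) or edge counts (`FALSE`)
#'   as the within-module degree.
#' @return Numeric vector of z-scores, one per node. Modules whose
#'   within-module degrees have zero SD (including singletons) give z = 0
#'   for all their members.
#' @export
within_module_z <- function(network, partition, weighted = TRUE) {
  W <- metric_matrix(network, weighted)
  comm <- check_partition(partition, nrow(W))
  z <- numeric(nrow(W))
  for (c in unique(comm)) {
    idx <- which(comm == c)
    kin <- rowSums(W[idx, idx, drop = FALSE])
    sdc <- sqrt(mean((kin - mean(kin))^2))   # population SD over the module
    z[idx] <- if (sdc > 0) (kin - mean(kin)) / sdc else 0
  }
  names(z) <- rownames(W)
  z
}

#' Participation coefficient
#'
#' @inheritParams within_module_z
#' @return Numeric vector of participation coefficients in `[0, 1]`;
#'   isolated nodes give 0 by convention.
#' @export
participation_coeff <- function(network, partition, weighted = TRUE) {
  W <- metric_matrix(network, weighted)
  comm <- check_partition(partition, nrow(W))
  k <- rowSums(W)
  kc <- rowsum(t(W), factor(comm))           # module x node strengths
  p <- 1 - colSums((t(t(kc) / ifelse(k > 0, k, 1)))^2)
  p[k == 0] <- 0
  names(p) <- rownames(W)
  p
}

#' Classify hub nodes from within-module degree z-scores
#'
#' Nodes with high within-module degree are hubs; the conventional cutoff
#' z >= 2.5 is the default.
#'
#' @param z Numeric vector of z-scores.
#' @param z_threshold Hub threshold (default 2.5).
#' @return Logical vector, `TRUE` for hubs.
#' @export
classify_hubs <- function(z, z_threshold = 2.5) {
  z >= z_threshold
}

#' Mean of a node metric over a lobe/hemisphere selection
#'
#' The whole-network value (e.g. the network-wide mean z) is obtained with
#' `lobe = "all", hemisphere = "both"`.
#'
#' @param values Numeric vector of 68 node values.
#' @param atlas An `fd_atlas`.
#' @inheritParams rois_in
#' @return Arithmetic mean over the selected regions.
#' @export
lobe_mean <- function(values, atlas = load_default_atlas(),
                      lobe = "all", hemisphere = "both") {
  if (length(values) != 68)
    fd_stop("fdnet_validation_error", "values must have length 68")
  sel <- rois_in(atlas, lobe, hemisphere)
  if (length(sel) == 0)
    fd_stop("fdnet_domain_error", "empty region selection")
  mean(values[sel])
}

#' Lobe-by-hemisphere report of a node metric
#'
#' @param values Numeric vector of 68 node values (e.g. z or P).
#' @param atlas An `fd_atlas`.
#' @return Data frame with one row per lobe and columns `total` (both
#'   hemispheres jointly), `left`, `right`.
#' @export
node_metric_report <- function(values, atlas = load_default_atlas()) {
  data.frame(
    lobe = .lobes,
    total = vapply(.lobes, function(l) lobe_mean(values, atlas, l, "both"), 0),
    left = vapply(.lobes, function(l) lobe_mean(values, atlas, l, "left"), 0),
    right = vapply(.lobes, function(l) lobe_mean(values, atlas, l, "right"), 0),
    row.names = NULL)
}

#' Intra- or inter-lobe connectivity weight of a network
#'
#' Intra-lobe connectivity aggregates the weights of edges whose two
#' endpoints both lie in the selected lobe (and hemisphere); inter-lobe
#' connectivity aggregates edges with exactly one endpoint in the selection.
#' `mode = "sum"` returns the raw weight sum; `mode = "mean"` divides by the
#' number of eligible node pairs (density-normalised), which puts lobes of
#' different sizes on a comparable scale.
#'
#' @param network A `brain_network` or adjacency matrix over the 68 regions.
#' @param atlas An `fd_atlas`.
#' @param scope `"intra"` or `"inter"`.
#' @inheritParams rois_in
#' @param mode `"sum"` or `"mean"`.
#' @return A single connectivity value.
#' @export
lobe_weight_connectivity <- function(network, atlas = load_default_atlas(),
                                     scope = c("intra", "inter"),
                                     lobe = "frontal", hemisphere = "both",
                                     mode = c("sum", "mean")) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  W <- as_brain_network(network)$adjacency
  n <- nrow(W)
  sel <- rois_in(atlas, lobe, hemisphere)
  other <- setdiff(seq_len(n), sel)
  if (scope == "intra") {
    s <- sum(W[sel, sel]) / 2
    pairs <- length(sel) * (length(sel) - 1) / 2
  } else {
    s <- sum(W[sel, other, drop = FALSE])
    pairs <- length(sel) * length(other)
  }
  if (mode == "sum") s else if (pairs == 0) 0 else s / pairs
}

#' Lobe connectivity report
#'
#' Intra- or inter-lobe connectivity for every lobe, for both hemispheres
#' jointly (`total`) and each hemisphere separately.
#'
#' @inheritParams lobe_weight_connectivity
#' @return Data frame with one row per lobe and columns `total`, `left`,
#'   `right`; attributes `scope` and `mode` record how it was computed.
#' @export
lobe_connectivity_report <- function(network, atlas = load_default_atlas(),
                                     scope = c("intra", "inter"),
                                     mode = c("mean", "sum")) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  cell <- function(l, h)
    lobe_weight_connectivity(network, atlas, scope, l, h, mode)
  out <- data.frame(
    lobe = .lobes,
    total = vapply(.lobes, cell, 0, h = "both"),
    left = vapply(.lobes, cell, 0, h = "left"),
    right = vapply(.lobes, cell, 0, h = "right"),
    row.names = NULL)
  attr(out, "scope") <- scope
  attr(out, "mode") <- mode
  out
}

#' Cell-wise percentage ratio of two connectivity reports
#'
#' Computes `100 * numerator / denominator` for every numeric cell of two
#' reports with identical layout — the ratio row of a two-group lobe
#' connectivity table (e.g. elderly over middle-aged). Zero denominators
#' yield `NA`.
#'
#' @param numerator,denominator Data frames with a `lobe` column and
#'   matching numeric columns (e.g. from [lobe_connectivity_report()] or
#'   [node_metric_report()]).
#' @return Data frame of percentages with the same layout; values are
#'   returned at full precision (round to 1 decimal for table display).
#' @export
#' @examples
#' ref <- reference_lobe_connectivity()
#' tmp <- ref[ref$scope == "intra" & ref$lobe == "temporal" &
#'            ref$column == "total", ]
#' 100 * tmp$elderly / tmp$middle  # 126.5
group_ratio <- function(numerator, denominator) {
  if (!identical(dim(numerator), dim(denominator)) ||
      !identical(names(numerator), names(denominator)))
    fd_stop("fdnet_validation_error", "reports must have identical layout")
  num_cols <- vapply(numerator, is.numeric, TRUE)
  out <- numerator
  for (j in which(num_cols)) {
    den <- denominator[[j]]
    out[[j]] <- ifelse(den == 0, NA_real_, 100 * numerator[[j]] / den)
  }
  out
}
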