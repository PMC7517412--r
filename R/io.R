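## Readers and writers: delimited tables (comma or tab auto-detected,
## header required), weighted edge lists, NIfTI volumes, and JSON run
## configurations. All tables round-trip through their readers.

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (length(header) == 0)
    fd_stop("fdnet_input_error", sprintf("empty file: %s", path))
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read or write an FD cohort table
#'
#' Delimited text with a header row and columns `subject_id`, `group`,
#' `sex`, `roi_1` ... `roi_68`. The reader auto-detects comma or tab
#' separation and validates the table.
#'
#' @param path File path.
#' @param cohort An `fd_cohort`.
#' @param sep Field separator for writing (default comma).
#' @return `read_fd_table` returns an `fd_cohort`; `write_fd_table` returns
#'   `path` invisibly.
#' @export
read_fd_table <- function(path) {
  if (!file.exists(path))
    fd_stop("fdnet_input_error", sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(subject_id = "character",
                                         group = "character",
                                         sex = "character"))
  as_fd_cohort(df)
}

#' @rdname read_fd_table
#' @export
write_fd_table <- function(cohort, path, sep = ",") {
  cohort <- as_fd_cohort(cohort)
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read or write a 68 x 68 matrix as labelled delimited text
#'
#' @param m Numeric matrix (e.g. correlation or adjacency values).
#' @param path File path.
#' @return `read_matrix_table` returns a numeric matrix; the writer returns
#'   `path` invisibly.
#' @export
write_matrix_table <- function(m, path) {
  if (is.null(colnames(m))) colnames(m) <- paste0("roi_", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_table
#' @export
read_matrix_table <- function(path) {
  if (!file.exists(path))
    fd_stop("fdnet_input_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    fd_stop("fdnet_input_error", "matrix table must be numeric")
  rownames(m) <- colnames(m)
  m
}

#' Read or write a network as a weighted edge list
#'
#' Three columns `roi_i`, `roi_j`, `weight` with 1-based region indices and
#' `roi_i < roi_j`; only strictly positive edges are written.
#'
#' @param network A `brain_network`.
#' @param path File path.
#' @param n_nodes Number of nodes when reading (default 68).
#' @return `read_edge_list` returns a `brain_network`; the writer returns
#'   `path` invisibly.
#' @export
write_edge_list <- function(network, path) {
  W <- as_brain_network(network)$adjacency
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  df <- data.frame(roi_i = ut[, 1], roi_j = ut[, 2],
                   weight = W[ut])
  df <- df[order(df$roi_i, df$roi_j), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_nodes = 68) {
  if (!file.exists(path))
    fd_stop("fdnet_input_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("roi_i", "roi_j", "weight")
  if (!all(need %in% names(df)))
    fd_stop("fdnet_input_error", "edge list must have columns roi_i, roi_j, weight")
  if (nrow(df) && (any(df$roi_i < 1) || any(df$roi_j > n_nodes)))
    fd_stop("fdnet_validation_error", "edge indices out of range")
  W <- matrix(0, n_nodes, n_nodes,
              dimnames = list(paste0("roi_", seq_len(n_nodes)),
                              paste0("roi_", seq_len(n_nodes))))
  for (r in seq_len(nrow(df))) {
    W[df$roi_i[r], df$roi_j[r]] <- df$weight[r]
    W[df$roi_j[r], df$roi_i[r]] <- df$weight[r]
  }
  brain_network(W)
}

#' Read a labelled parcellation volume from NIfTI
#'
#' @param path Path to a `.nii` or `.nii.gz` file of integer region codes
#'   (0 = background, 1-68 = atlas regions).
#' @return 3D integer array.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    fd_stop("fdnet_input_error", sprintf("file not found: %s", path))
  vol <- RNifti::readNifti(path)
  arr <- array(as.vector(vol), dim(vol))
  if (length(dim(arr)) != 3)
    fd_stop("fdnet_validation_error", "label volume must be 3D")
  if (max(abs(arr - round(arr))) > 1e-6)
    fd_stop("fdnet_validation_error", "label volume must contain integer codes")
  array(as.integer(round(arr)), dim(arr))
}

#' Write a volume or mask to NIfTI
#'
#' @param x A 3D array, or a `voxel_mask` (written as 0/1).
#' @param path Destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  if (inherits(x, "voxel_mask")) x <- array(as.integer(x$occupancy), dim(x$occupancy))
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' Create, write, and read pipeline run configurations
#'
#' A run configuration collects every tunable of the pipeline (threshold
#' proportion, weighted flag, hub threshold, permutation settings, seed) and
#' is persisted as JSON next to the outputs, so any stage can be re-run
#' bit-identically.
#'
#' @param threshold_proportion Proportional threshold in (0, 1].
#' @param weighted Weighted z/P metrics flag.
#' @param hub_z_threshold Hub classification threshold.
#' @param n_permutations,per_sex_draw Permutation settings.
#' @param n_restarts Module-detection restarts.
#' @param seed Top-level seed.
#' @param path JSON file path.
#' @param config A `run_config`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(threshold_proportion = 0.20, weighted = TRUE,
                       hub_z_threshold = 2.5, n_permutations = 1000L,
                       per_sex_draw = 25L, n_restarts = 20L, seed = 1L) {
  if (threshold_proportion <= 0 || threshold_proportion > 1)
    fd_stop("fdnet_config_error", "threshold_proportion must lie in (0, 1]")
  if (!is.logical(weighted) || length(weighted) != 1)
    fd_stop("fdnet_config_error", "weighted must be TRUE or FALSE")
  if (!is.numeric(hub_z_threshold))
    fd_stop("fdnet_config_error", "hub_z_threshold must be numeric")
  for (v in c(n_permutations, per_sex_draw, n_restarts, seed))
    if (!is_count(v, min = 0))
      fd_stop("fdnet_config_error", "counts and seed must be non-negative integers")
  structure(list(threshold_proportion = threshold_proportion,
                 weighted = weighted, hub_z_threshold = hub_z_threshold,
                 n_permutations = as.integer(n_permutations),
                 per_sex_draw = as.integer(per_sex_draw),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    fd_stop("fdnet_config_error", "config must be a run_config")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    fd_stop("fdnet_input_error", sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}
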