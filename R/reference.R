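## Reference summary tables from a published two-group (middle-aged vs
## elderly) FD-based structural covariance study of 100 + 100 healthy adults.
## They parameterise the synthetic-cohort defaults and support worked-example
## arithmetic (connectivity ratios, module size summaries); the underlying
## subject-level scans are not distributed, so these printed summaries are
## the only empirical anchor available to the package.

read_reference_csv <- function(name) {
  path <- system.file("extdata", name, package = "fdnet")
  if (!nzchar(path))
    fd_stop("fdnet_integrity_error", sprintf("packaged reference file %s is missing", name))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference cohort summaries
#'
#' Transcribed summary tables from a reference aging cohort (100 middle-aged
#' and 100 elderly healthy adults, 50/50 female/male in each group) analysed
#' with the same FD covariance-network pipeline this package implements:
#'
#' * `reference_lobe_fd()` — per-lobe, per-hemisphere FD mean and SD for both
#'   groups, with the group-comparison p-value.
#' * `reference_regional_fd()` — the 16 regions whose FD differed
#'   significantly between the groups, with group means and p-values.
#'   Group differences in this table (elderly minus middle-aged) are the
#'   default planted effects of [cohort_config()].
#' * `reference_modules()` — the five-module partitions of each group's
#'   thresholded covariance network (one row per region, columns `group`,
#'   `module`, `label`). The middle-aged partition (module sizes
#'   22/14/13/11/8) is the default planted block structure of
#'   [cohort_config()].
#' * `reference_lobe_connectivity()` — intra- and inter-lobe connectivity per
#'   lobe and hemisphere for both groups (4-decimal values) plus the printed
#'   elderly/middle percentage ratio row, reproducible with [group_ratio()].
#'
#' @return A data frame; see above for the columns of each table.
#' @seealso [group_ratio()], [cohort_config()]
#' @export
#' @examples
#' head(reference_lobe_connectivity())
reference_lobe_fd <- function() read_reference_csv("reference_lobe_fd.csv")

#' @rdname reference_lobe_fd
#' @export
reference_regional_fd <- function() read_reference_csv("reference_regional_fd.csv")

#' @rdname reference_lobe_fd
#' @export
reference_modules <- function() read_reference_csv("reference_modules.csv")

#' @rdname reference_lobe_fd
#' @export
reference_lobe_connectivity <- function() read_reference_csv("reference_lobe_connectivity.csv")
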