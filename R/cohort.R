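## FD cohort tables (subjects x 68 regional FD values with group and sex
## labels) and the synthetic two-group cohort generator.

#' Construct an FD cohort table
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param group Character/factor group label per subject (two groups for the
#'   comparison functions).
#' @param sex `"F"`/`"M"` per subject.
#' @param fd Numeric matrix, one row per subject and 68 columns of regional
#'   FD values; values must lie in (0, 3.5) or be `NA`.
#' @return An `fd_cohort` data frame with columns `subject_id`, `group`,
#'   `sex`, `roi_1` ... `roi_68`.
#' @export
fd_cohort <- function(subject_id, group, sex, fd) {
  fd <- as.matrix(fd)
  df <- data.frame(subject_id = as.character(subject_id),
                   group = as.character(group),
                   sex = as.character(sex),
                   stringsAsFactors = FALSE)
  if (ncol(fd) != 68)
    fd_stop("fdnet_validation_error", "fd must have 68 columns")
  colnames(fd) <- paste0("roi_", 1:68)
  df <- cbind(df, as.data.frame(fd))
  as_fd_cohort(df)
}

#' Coerce and validate an FD cohort table
#'
#' @param df A data frame with columns `subject_id`, `group`, `sex` and
#'   `roi_1` ... `roi_68`.
#' @return An `fd_cohort` data frame.
#' @export
as_fd_cohort <- function(df) {
  need <- c("subject_id", "group", "sex", paste0("roi_", 1:68))
  if (!all(need %in% names(df)))
    fd_stop("fdnet_validation_error",
            "cohort table must have columns subject_id, group, sex, roi_1..roi_68")
  df <- as.data.frame(df)[, need]
  if (anyDuplicated(df$subject_id))
    fd_stop("fdnet_validation_error", "subject ids must be unique")
  if (!all(df$sex %in% c("F", "M")))
    fd_stop("fdnet_validation_error", "sex must be 'F' or 'M'")
  fd <- as.matrix(df[, paste0("roi_", 1:68)])
  if (!is.numeric(fd))
    fd_stop("fdnet_validation_error", "FD columns must be numeric")
  bad <- !is.na(fd) & (fd <= 0 | fd >= 3.5)
  if (any(bad))
    fd_stop("fdnet_validation_error",
            "FD values must lie in (0, 3.5) or be missing")
  rownames(df) <- NULL
  class(df) <- c("fd_cohort", "data.frame")
  df
}

#' Extract the subjects x 68 FD matrix of a cohort
#'
#' @param cohort An `fd_cohort`.
#' @param group Optional group label to subset rows first.
#' @return Numeric matrix with subject ids as row names.
#' @export
fd_values <- function(cohort, group = NULL) {
  cohort <- as_fd_cohort(cohort)
  if (!is.null(group)) {
    cohort <- cohort[cohort$group == group, , drop = FALSE]
    if (nrow(cohort) == 0)
      fd_stop("fdnet_validation_error", sprintf("no subjects in group '%s'", group))
  }
  m <- as.matrix(cohort[, paste0("roi_", 1:68)])
  rownames(m) <- cohort$subject_id
  m
}

## ---- synthetic cohort generator ------------------------------------------

#' Default regional FD means, planted blocks, and group effects
#'
#' Defaults are taken from the packaged reference cohort summaries (see
#' [reference_lobe_fd()]): each region's mean FD is its lobe-by-hemisphere
#' middle-aged mean, overridden by the region-specific middle-aged mean for
#' the 16 regions with printed values; the planted correlation blocks are the
#' middle-aged five-module partition (sizes 22/14/13/11/8); the default
#' group-B effects are the printed elderly-minus-middle FD differences of the
#' 16 significant regions.
#'
#' @param atlas An `fd_atlas`.
#' @return `default_roi_means()`: numeric vector of 68 means.
#'   `default_module_blocks()`: integer vector of 68 block ids (1-5).
#'   `default_effect_table()`: data frame with columns `roi`, `label`,
#'   `delta`.
#' @export
default_roi_means <- function(atlas = load_default_atlas()) {
  atlas <- as_atlas(atlas)
  lob <- reference_lobe_fd()
  mu <- numeric(68)
  for (i in 1:68) {
    row <- lob$lobe == atlas$lobe[i] & lob$hemisphere == atlas$hemisphere[i]
    mu[i] <- lob$middle_mean[row]
  }
  reg <- reference_regional_fd()
  idx <- roi_index(reg$label, atlas)
  mu[idx] <- reg$middle_mean
  names(mu) <- paste0("roi_", 1:68)
  mu
}

#' @rdname default_roi_means
#' @export
default_module_blocks <- function(atlas = load_default_atlas()) {
  mods <- reference_modules()
  mods <- mods[mods$group == "middle", ]
  blocks <- integer(68)
  blocks[roi_index(mods$label, atlas)] <- mods$module
  blocks
}

#' @rdname default_roi_means
#' @export
default_effect_table <- function(atlas = load_default_atlas()) {
  reg <- reference_regional_fd()
  data.frame(roi = roi_index(reg$label, atlas), label = reg$label,
             delta = reg$elderly_mean - reg$middle_mean)
}

#' Configure a synthetic two-group FD cohort
#'
#' Describes two cohorts of `n_per_group` subjects whose 68 regional FD
#' values are drawn from a multivariate normal with block-structured
#' (compound-symmetric within blocks) correlation. Group B's means are
#' shifted by the planted effects. Sex labels are balanced 50/50 within each
#' group. The implied correlation matrix is validated to be positive
#' semi-definite at construction; invalid configurations fail loudly with
#' the offending eigenvalue.
#'
#' @param n_per_group Subjects per group (default 100).
#' @param roi_means Numeric vector of 68 baseline means (default
#'   [default_roi_means()], FD scale about 2.0-2.45).
#' @param roi_sd Common per-region SD across subjects (default 0.10).
#' @param module_blocks Integer vector of 68 block ids defining the planted
#'   correlation modules (default [default_module_blocks()], sizes
#'   22/14/13/11/8).
#' @param within_block_corr,between_block_corr Correlation inside / between
#'   blocks (defaults 0.5 and 0.1).
#' @param effect_rois Data frame with columns `roi`, `delta`: mean shifts
#'   applied to group B only (default [default_effect_table()], the 16
#'   reference regions). Use a zero-row data frame for a null cohort.
#' @param within_block_corr_b Optional group-B override of
#'   `within_block_corr` (default equal), used to plant modular-strength
#'   differences between the groups.
#' @param group_labels Length-2 character vector naming groups A and B
#'   (default `c("middle", "elderly")`).
#' @param seed Integer seed; the generated cohort is a deterministic
#'   function of the configuration.
#' @return A `cohort_config` object.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 20, seed = 1)
#' cohort <- make_cohort(cfg)
cohort_config <- function(n_per_group = 100,
                          roi_means = default_roi_means(),
                          roi_sd = 0.10,
                          module_blocks = default_module_blocks(),
                          within_block_corr = 0.5,
                          between_block_corr = 0.1,
                          effect_rois = default_effect_table(),
                          within_block_corr_b = within_block_corr,
                          group_labels = c("middle", "elderly"),
                          seed = 1L) {
  if (!is_count(n_per_group, min = 2))
    fd_stop("fdnet_config_error", "n_per_group must be an integer >= 2")
  if (length(roi_means) != 68 || !is.numeric(roi_means))
    fd_stop("fdnet_config_error", "roi_means must be a numeric vector of length 68")
  if (!is.numeric(roi_sd) || roi_sd <= 0)
    fd_stop("fdnet_config_error", "roi_sd must be positive")
  module_blocks <- as.integer(module_blocks)
  if (length(module_blocks) != 68 || anyNA(module_blocks) || any(module_blocks < 1))
    fd_stop("fdnet_config_error", "module_blocks must assign every region a block id")
  if (!is.data.frame(effect_rois) || !all(c("roi", "delta") %in% names(effect_rois)))
    fd_stop("fdnet_config_error", "effect_rois must have columns roi and delta")
  if (nrow(effect_rois) && (any(effect_rois$roi < 1) || any(effect_rois$roi > 68)))
    fd_stop("fdnet_config_error", "effect_rois$roi must be region indices in 1..68")
  if (length(group_labels) != 2 || anyDuplicated(group_labels))
    fd_stop("fdnet_config_error", "group_labels must be two distinct labels")
  for (rho in c(within_block_corr, between_block_corr, within_block_corr_b))
    if (!is.numeric(rho) || rho <= -1 || rho >= 1)
      fd_stop("fdnet_config_error", "correlations must lie in (-1, 1)")
  cfg <- structure(list(
    n_per_group = as.integer(n_per_group), roi_means = unname(roi_means),
    roi_sd = roi_sd, module_blocks = module_blocks,
    within_block_corr = within_block_corr,
    between_block_corr = between_block_corr,
    within_block_corr_b = within_block_corr_b,
    effect_rois = effect_rois[, c("roi", "delta")],
    group_labels = group_labels, seed = as.integer(seed)),
    class = "cohort_config")
  for (g in c("a", "b")) {
    C <- block_correlation(cfg, g)
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      fd_stop("fdnet_config_error", sprintf(
        "implied group-%s correlation matrix is not positive semi-definite (min eigenvalue %.3e)",
        toupper(g), ev))
  }
  cfg
}

## Block-structured correlation matrix implied by a config.
block_correlation <- function(cfg, group = c("a", "b")) {
  group <- match.arg(group)
  within <- if (group == "a") cfg$within_block_corr else cfg$within_block_corr_b
  same <- outer(cfg$module_blocks, cfg$module_blocks, "==")
  C <- ifelse(same, within, cfg$between_block_corr)
  diag(C) <- 1
  C
}

#' Generate a synthetic two-group FD cohort
#'
#' Draws `n_per_group` subjects per group from the multivariate normal
#' implied by the configuration (means `roi_means`, common SD `roi_sd`,
#' block-structured correlation), applies the planted mean shifts to group B,
#' and assigns balanced 50/50 sex labels. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @return An `fd_cohort` with `2 * n_per_group` rows.
#' @export
make_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    fd_stop("fdnet_config_error", "config must be a cohort_config object")
  n <- config$n_per_group
  local_seed(config$seed, {
    draw <- function(group_key, mu) {
      R <- chol(block_correlation(config, group_key))
      Z <- matrix(stats::rnorm(n * 68), n, 68)
      sweep(Z %*% R * config$roi_sd, 2, mu, "+")
    }
    mu_b <- config$roi_means
    if (nrow(config$effect_rois))
      mu_b[config$effect_rois$roi] <- mu_b[config$effect_rois$roi] +
        config$effect_rois$delta
    fd_a <- draw("a", config$roi_means)
    fd_b <- draw("b", mu_b)
    sexes <- function() c(rep("F", ceiling(n / 2)), rep("M", floor(n / 2)))
    fd_cohort(
      subject_id = c(sprintf("%s_%03d", config$group_labels[1], seq_len(n)),
                     sprintf("%s_%03d", config$group_labels[2], seq_len(n))),
      group = rep(config$group_labels, each = n),
      sex = c(sexes(), sexes()),
      fd = rbind(fd_a, fd_b))
  })
}

#' Planted ground truth of a synthetic configuration
#'
#' @param config A [cohort_config()].
#' @return List with `partition` (integer block id per region, the planted
#'   module structure) and `effects` (data frame of region indices and true
#'   group-B mean shifts), for downstream recovery scoring.
#' @export
planted_truth <- function(config) {
  if (!inherits(config, "cohort_config"))
    fd_stop("fdnet_config_error", "config must be a cohort_config object")
  list(partition = config$module_blocks, effects = config$effect_rois)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones. Used to score recovery of planted module structure.
#'
#' @param a,b Integer/factor label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    fd_stop("fdnet_validation_error", "partitions must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
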