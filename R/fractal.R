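## 3D box-counting fractal dimension of binary voxel masks.
##
## The FD of a voxelised object follows the power law N(r) ~ r^(-FD), where
## N(r) is the number of grid-aligned cubes of edge r (in voxel units) that
## contain at least one occupied voxel. FD is estimated as the ordinary
## least-squares slope of log N(r) on log(1/r). The counting grid is anchored
## at the minimum corner of the mask's bounding box, and the mask is cropped
## to that bounding box first so that padding cannot distort counts.

#' Construct a binary voxel mask
#'
#' @param occupancy A 3D array (logical, or numeric containing only 0/1)
#'   marking occupied voxels.
#' @param voxel_size Optional physical edge lengths in mm (length 3). Kept as
#'   metadata only: counting is performed in voxel units, so anisotropic
#'   voxels are ignored by the FD estimate.
#' @return A `voxel_mask` object.
#' @export
#' @examples
#' m <- voxel_mask(array(TRUE, c(4, 4, 4)))
voxel_mask <- function(occupancy, voxel_size = NULL) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3)
    fd_stop("fdnet_validation_error", "occupancy must be a 3D array")
  if (is.numeric(occupancy)) {
    if (!all(occupancy %in% c(0, 1)))
      fd_stop("fdnet_validation_error", "occupancy values must be binary (0/1)")
    occupancy <- array(occupancy == 1, dim(occupancy))
  }
  if (!is.logical(occupancy))
    fd_stop("fdnet_validation_error", "occupancy must be logical or 0/1 numeric")
  if (anyNA(occupancy))
    fd_stop("fdnet_validation_error", "occupancy must not contain NA")
  if (!is.null(voxel_size)) stopifnot(is.numeric(voxel_size), length(voxel_size) == 3)
  structure(list(occupancy = occupancy, voxel_size = voxel_size),
            class = "voxel_mask")
}

as_voxel_mask <- function(x) {
  if (inherits(x, "voxel_mask")) x else voxel_mask(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s grid, %d occupied voxels\n",
              paste(dim(x$occupancy), collapse = "x"), sum(x$occupancy)))
  invisible(x)
}

## Crop a logical 3D array to the bounding box of its occupied voxels.
crop_to_bbox <- function(occ) {
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) == 0)
    fd_stop("fdnet_domain_error", "mask contains no occupied voxels")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

#' Count occupied boxes at a set of box sizes
#'
#' For each box edge length `r`, overlays an axis-aligned grid of r-cubes
#' anchored at the minimum corner of the mask's bounding box and counts the
#' cubes containing at least one occupied voxel.
#'
#' @param mask A `voxel_mask` or 3D binary array with at least one occupied
#'   voxel.
#' @param sizes Integer box edge lengths (>= 1, in voxel units). Sizes larger
#'   than the bounding box are allowed and yield a count of 1.
#' @return A `box_count_curve`: list with `sizes` (strictly increasing) and
#'   `counts` (occupied boxes per size).
#' @export
#' @examples
#' box_counts(array(TRUE, c(4, 4, 4)), c(1, 2, 4))
box_counts <- function(mask, sizes) {
  mask <- as_voxel_mask(mask)
  if (!is.numeric(sizes) || length(sizes) == 0 ||
      any(!is.finite(sizes) | sizes < 1 | sizes != round(sizes)))
    fd_stop("fdnet_validation_error", "sizes must be positive integers")
  sizes <- sort(unique(as.integer(sizes)))
  occ <- crop_to_bbox(mask$occupancy)
  idx <- which(occ, arr.ind = TRUE) - 1L  # 0-based coordinates in the bbox
  counts <- vapply(sizes, function(r) {
    b <- idx %/% r
    nb1 <- max(b[, 1]) + 1
    nb2 <- max(b[, 2]) + 1
    id <- b[, 1] + nb1 * (b[, 2] + nb2 * b[, 3])
    length(unique(id))
  }, integer(1))
  structure(list(sizes = sizes, counts = counts), class = "box_count_curve")
}

#' Default geometric box-size progression for a mask
#'
#' Powers of `base` from 1 up to the largest power not exceeding the maximum
#' bounding-box extent. Base 2 is the standard dyadic progression; base 3 is
#' provided for triadic phantoms (Menger sponge, Cantor dust), on which it
#' recovers the analytic dimension exactly.
#'
#' @inheritParams box_counts
#' @param base Either 2 or 3.
#' @return Integer vector of at least three sizes; masks too small to support
#'   three scales raise a domain error.
#' @export
default_sizes <- function(mask, base = 2) {
  mask <- as_voxel_mask(mask)
  if (!base %in% c(2, 3))
    fd_stop("fdnet_validation_error", "base must be 2 or 3")
  occ <- crop_to_bbox(mask$occupancy)
  extent <- max(dim(occ))
  k <- floor(log(extent) / log(base) + 1e-9)
  sizes <- as.integer(base^(0:k))
  if (length(sizes) < 3)
    fd_stop("fdnet_domain_error", sprintf(
      "mask extent %d supports only %d base-%d box size(s); at least 3 are required",
      extent, length(sizes), base))
  sizes
}

#' Estimate the fractal dimension from a box-count curve
#'
#' Ordinary least-squares slope of `log N(r)` on `log(1/r)`. The logarithm
#' base cancels in the slope; natural logs are used.
#'
#' @param curve A `box_count_curve` from [box_counts()], or a list with
#'   `sizes` and `counts`.
#' @return An `fd_estimate`: list with `fd` (the slope), `intercept`,
#'   `r_squared`, and `n_points`. A curve with constant counts (e.g. a single
#'   voxel) has `fd = 0` and, being fitted exactly by a flat line,
#'   `r_squared = 1`.
#' @export
#' @examples
#' estimate_fd(box_counts(array(TRUE, c(4, 4, 4)), c(1, 2, 4)))  # fd = 3
estimate_fd <- function(curve) {
  sizes <- curve$sizes
  counts <- curve$counts
  if (length(sizes) < 2 || length(unique(sizes)) < 2)
    fd_stop("fdnet_domain_error", "at least 2 distinct box sizes are required")
  if (any(counts < 1))
    fd_stop("fdnet_validation_error", "box counts must be >= 1")
  x <- log(1 / sizes)
  y <- log(counts)
  mx <- mean(x); my <- mean(y)
  ssx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / ssx
  ssy <- sum((y - my)^2)
  r2 <- if (ssy == 0) 1 else sum((x - mx) * (y - my))^2 / (ssx * ssy)
  structure(list(fd = slope, intercept = my - slope * mx,
                 r_squared = r2, n_points = length(sizes)),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> fd = %.4f (R^2 = %.4f, %d scales)\n",
              x$fd, x$r_squared, x$n_points))
  invisible(x)
}

#' Per-region fractal dimension from a labelled volume
#'
#' Extracts each region's binary mask from an integer label volume (codes
#' 1-68 per the packaged atlas, 0 = background), crops it to its bounding
#' box, and runs the box-counting FD estimate on it.
#'
#' @param label_volume 3D integer array with codes in `{0} U 1..68`.
#' @param atlas An `fd_atlas` (defines the 68 expected codes).
#' @param min_voxels Regions with fewer occupied voxels than this yield `NA`
#'   (default 8: below that a log-log regression is meaningless).
#' @param base Box-size progression base, see [default_sizes()]. Regions
#'   whose extent supports only two scales are still estimated from those two
#'   points; single-scale regions yield `NA`.
#' @return Named numeric vector of 68 FD values (`roi_1` ... `roi_68`), `NA`
#'   for absent or sub-threshold regions.
#' @export
fd_per_roi <- function(label_volume, atlas = load_default_atlas(),
                       min_voxels = 8, base = 2) {
  if (!is.array(label_volume) || length(dim(label_volume)) != 3)
    fd_stop("fdnet_validation_error", "label_volume must be a 3D array")
  if (anyNA(label_volume))
    fd_stop("fdnet_validation_error", "label_volume must not contain NA")
  codes <- unique(as.vector(label_volume))
  if (any(codes != round(codes)) || any(codes < 0) || any(codes > 68))
    fd_stop("fdnet_validation_error",
            "label codes must be integers in {0} U 1..68")
  atlas <- as_atlas(atlas)
  out <- rep(NA_real_, 68)
  names(out) <- paste0("roi_", 1:68)
  for (i in 1:68) {
    occ <- label_volume == i
    nv <- sum(occ)
    if (nv == 0 || nv < min_voxels) next
    occ <- crop_to_bbox(array(occ, dim(label_volume)))
    extent <- max(dim(occ))
    k <- floor(log(extent) / log(base) + 1e-9)
    if (k < 1) next  # a single scale cannot support a regression
    sizes <- as.integer(base^(0:k))
    out[i] <- estimate_fd(box_counts(occ, sizes))$fd
  }
  out
}

#' Per-lobe, per-hemisphere FD summary of a cohort
#'
#' Mean and SD of FD over all (subject, region) values in each lobe-by-
#' hemisphere cell, in the layout of standard lobe summary tables
#' (each lobe reported for both hemispheres jointly, then left and right
#' separately). For a single-subject table the SD is taken over regions.
#'
#' @param cohort An `fd_cohort` (see [fd_cohort()]); subset rows first to
#'   summarise one group.
#' @param atlas An `fd_atlas`.
#' @return Data frame with columns `lobe`, `hemisphere` (`both`/`left`/
#'   `right`), `mean`, `sd`, `n_values`.
#' @export
aggregate_lobe_fd <- function(cohort, atlas = load_default_atlas()) {
  cohort <- as_fd_cohort(cohort)
  atlas <- as_atlas(atlas)
  fd <- fd_values(cohort)
  rows <- expand.grid(hemisphere = c("both", "left", "right"), lobe = .lobes,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sel <- rois_in(atlas, rows$lobe[i], rows$hemisphere[i])
    vals <- as.vector(fd[, sel, drop = FALSE])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0)
      fd_stop("fdnet_domain_error", sprintf(
        "no FD values available for lobe %s / hemisphere %s",
        rows$lobe[i], rows$hemisphere[i]))
    data.frame(lobe = rows$lobe[i], hemisphere = rows$hemisphere[i],
               mean = mean(vals), sd = stats::sd(vals),
               n_values = length(vals))
  })
  do.call(rbind, res)
}
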