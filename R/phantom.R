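## Deterministic fractal phantoms with known analytic dimension, used to
## validate the box-counting estimator: filled cube (FD 3), plane slab (2),
## straight line (1), single point (0), Menger sponge (log 20 / log 3) and
## triadic Cantor dust (3 log 2 / log 3).

#' Analytic phantom dimensions
#' @keywords internal
phantom_kinds <- function() c("cube", "slab", "line", "point",
                              "menger_sponge", "cantor_dust")

#' Generate a fractal phantom mask
#'
#' @param kind One of `"cube"`, `"slab"`, `"line"`, `"point"`,
#'   `"menger_sponge"`, `"cantor_dust"`.
#' @param level_or_size For `cube`/`slab`/`line`: the edge length in voxels
#'   (<= 512). For `menger_sponge`/`cantor_dust`: the recursion level
#'   (1-5; the grid is `3^level` per axis). Ignored for `point`.
#' @return A `voxel_mask` with attributes `kind`, `level_or_size`, and
#'   `analytic_fd` (the closed-form dimension of the limiting object).
#' @export
#' @examples
#' sum(make_phantom("menger_sponge", 2)$occupancy)  # 400 occupied cells
make_phantom <- function(kind, level_or_size = 16) {
  kind <- match.arg(kind, phantom_kinds())
  s <- level_or_size
  if (kind %in% c("cube", "slab", "line")) {
    if (!is_count(s) || s > 512)
      fd_stop("fdnet_domain_error", "edge length must be an integer in 1..512")
  } else if (kind %in% c("menger_sponge", "cantor_dust")) {
    if (!is_count(s) || s > 5)
      fd_stop("fdnet_domain_error", "recursion level must be an integer in 1..5")
  }
  occ <- switch(kind,
    cube  = array(TRUE, c(s, s, s)),
    slab  = array(TRUE, c(s, s, 1)),
    line  = array(TRUE, c(s, 1, 1)),
    point = array(TRUE, c(1, 1, 1)),
    menger_sponge = menger_occupancy(s),
    cantor_dust   = cantor_occupancy(s))
  fd <- switch(kind,
    cube = 3, slab = 2, line = 1, point = 0,
    menger_sponge = log(20) / log(3),
    cantor_dust   = 3 * log(2) / log(3))
  mask <- voxel_mask(occ)
  attr(mask, "kind") <- kind
  attr(mask, "level_or_size") <- s
  attr(mask, "analytic_fd") <- fd
  mask
}

## Menger sponge by the 20-of-27 subdivision rule: a cell survives iff at no
## recursion depth do at least two of its three base-3 digits equal 1.
menger_occupancy <- function(level) {
  n <- 3L^level
  coords <- 0:(n - 1L)
  keep1 <- function(x) {
    ## digit of x at each of the `level` base-3 positions
    vapply(seq_len(level) - 1L, function(t) as.integer((x %/% 3L^t) %% 3L),
           integer(length(x)))
  }
  d1 <- keep1(coords)  # n x level matrices of digits
  occ <- array(FALSE, c(n, n, n))
  mid1 <- d1 == 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ## middle-count per digit position for (i,j) fixed, vectorised over k
    mij <- mid1[i, ] + mid1[j, ]
    bad <- matrix(mij, nrow = n, ncol = level, byrow = TRUE) + mid1
    occ[i, j, ] <- !apply(bad >= 2L, 1, any)
  }
  occ
}

## Triadic Cantor dust: product of three middle-thirds Cantor sets.
cantor_occupancy <- function(level) {
  n <- 3L^level
  coords <- 0:(n - 1L)
  keep <- vapply(coords, function(x) {
    all((x %/% 3L^(seq_len(level) - 1L)) %% 3L != 1L)
  }, logical(1))
  occ <- array(FALSE, c(n, n, n))
  occ[keep, keep, keep] <- TRUE
  occ
}
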