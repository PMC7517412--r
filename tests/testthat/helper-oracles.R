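# Independent brute-force oracles and small generators used across tests.
# These deliberately use naive loops so they share no code path with the
# package implementations they check.

# Count occupied boxes by explicit triple loop over the box grid.
brute_box_count <- function(occ, r) {
  idx <- which(occ, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  occ <- occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(occ)
  count <- 0L
  for (bx in seq_len(ceiling(d[1] / r))) {
    for (by in seq_len(ceiling(d[2] / r))) {
      for (bz in seq_len(ceiling(d[3] / r))) {
        xs <- ((bx - 1) * r + 1):min(bx * r, d[1])
        ys <- ((by - 1) * r + 1):min(by * r, d[2])
        zs <- ((bz - 1) * r + 1):min(bz * r, d[3])
        if (any(occ[xs, ys, zs])) count <- count + 1L
      }
    }
  }
  count
}

# Modularity by direct double loop over Eq.-style definition.
brute_modularity <- function(W, comm) {
  n <- nrow(W)
  k <- rowSums(W)
  m2 <- sum(W)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (comm[i] == comm[j]) q <- q + W[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

brute_within_z <- function(W, comm, weighted = TRUE) {
  if (!weighted) W <- (W > 0) * 1
  n <- nrow(W)
  kin <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j != i && comm[j] == comm[i]) kin[i] <- kin[i] + W[i, j]
  }
  z <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(comm == comm[i])
    mu <- mean(kin[members])
    sigma <- sqrt(sum((kin[members] - mu)^2) / length(members))
    z[i] <- if (sigma > 0) (kin[i] - mu) / sigma else 0
  }
  z
}

brute_participation <- function(W, comm, weighted = TRUE) {
  if (!weighted) W <- (W > 0) * 1
  n <- nrow(W)
  p <- numeric(n)
  for (i in seq_len(n)) {
    ki <- sum(W[i, ])
    if (ki == 0) { p[i] <- 0; next }
    s <- 0
    for (c in unique(comm)) {
      kic <- sum(W[i, comm == c])
      s <- s + (kic / ki)^2
    }
    p[i] <- 1 - s
  }
  p
}

# Benjamini-Hochberg step-up, written from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (r in (m - 1):1) {
    q[o[r]] <- min(p[o[r]] * m / r, q[o[r + 1]])
  }
  if (m == 1) q <- p
  pmin(q, 1)
}

# All set partitions of 1..n as restricted growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxid + 1)) {
      recurse(c(prefix, c), max(maxid, c))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Random symmetric non-negative weighted network with zero diagonal.
random_network <- function(n, density = 0.4, rng = NULL) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[stats::runif(length(ut)) < density]
  W[on] <- stats::runif(length(on), 0.1, 1)
  W <- W + t(W)
  W
}

# Random binary 3D mask guaranteed non-empty.
random_mask <- function(dmax = 16, p = 0.3) {
  d <- sample(2:dmax, 3, replace = TRUE)
  occ <- array(stats::runif(prod(d)) < p, d)
  if (!any(occ)) occ[1, 1, 1] <- TRUE
  occ
}

# Two disconnected equal-weight cliques of size s.
two_cliques <- function(s, w = 1) {
  n <- 2 * s
  W <- matrix(0, n, n)
  W[1:s, 1:s] <- w
  W[(s + 1):n, (s + 1):n] <- w
  diag(W) <- 0
  W
}
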