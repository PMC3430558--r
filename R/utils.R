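# Lattice helpers shared by the voxelization, geometry and descriptor code.

# shifted[v] = occ[v + o]; positions falling outside the lattice read FALSE.
.shiftOcc <- function(occ, o) {
  d <- dim(occ)
  out <- array(FALSE, d)
  dst <- src <- vector("list", 3L)
  for (k in 1:3) {
    if (o[k] >= 0) {
      if (o[k] >= d[k]) return(out)
      dst[[k]] <- seq_len(d[k] - o[k])
      src[[k]] <- dst[[k]] + o[k]
    } else {
      if (-o[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + o[k])
      dst[[k]] <- src[[k]] - o[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}

# integer offsets o (excluding 0) with ||o|| <= r, r in voxel units
.ballOffsets <- function(r, includeCenter = FALSE) {
  m <- floor(r)
  if (m < 0) stop("ball radius must be non-negative")
  g <- as.matrix(expand.grid(dx = -m:m, dy = -m:m, dz = -m:m))
  keep <- rowSums(g^2) <= r^2 + 1e-12
  if (!includeCenter) keep <- keep & rowSums(abs(g)) > 0
  g[keep, , drop = FALSE]
}

# the 13 lexicographically-positive 26-neighbor offsets (half neighborhood)
.halfOffsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

.offsets6 <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# n x 3 lattice coordinates -> Angstrom centers
.voxelCenters <- function(grid, idx) {
  sweep(idx - 0.5, 2, c(1, 1, 1), "*") * grid@h +
    matrix(grid@origin, nrow(idx), 3, byrow = TRUE)
}

.linearIndex <- function(d, idx) {
  idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
}

.arrayIndex <- function(d, lin) {
  lin <- lin - 1L
  cbind(lin %% d[1] + 1L,
        (lin %/% d[1]) %% d[2] + 1L,
        lin %/% (d[1] * d[2]) + 1L)
}

# Bin positive lengths into a B-bin PDF over [0, dMax].
# Values equal to dMax land in the top bin; the PDF sums to exactly 1.
.histPDF <- function(values, B, mode = c("per_shape_max", "fixed_range"),
                     dMax = NULL) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop("empty distance set")
  if (mode == "per_shape_max") {
    dMax <- max(values)
  } else {
    if (is.null(dMax)) stop("fixed_range mode requires dMax")
    if (dMax < max(values))
      stop("fixed_range dMax smaller than the largest observed value")
  }
  if (dMax <= 0) {
    # all values zero: degenerate shape, put all mass in the first bin
    bins <- numeric(B)
    bins[1] <- 1
    return(list(bins = bins, dMax = dMax))
  }
  k <- pmin(floor(values / dMax * B) + 1L, B)
  bins <- tabulate(k, nbins = B) / length(values)
  list(bins = bins, dMax = dMax)
}

# pairwise squared Euclidean distances between rows of a and b
.cross2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
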