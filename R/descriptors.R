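# The IDSS histogram and the five baseline shape descriptors.
# All histogram methods produce probability densities (sum = 1) so that the
# L1 similarity of two descriptors lives on a common [0, 2] scale.

.newHistDescriptor <- function(method, values, B, mode, dMax, sourceId) {
  hp <- .histPDF(values, B, mode, dMax)
  new("ShapeDescriptor", method = method, bins = hp$bins, B = as.integer(B),
      mode = mode, dMax = hp$dMax, sourceId = sourceId)
}

#' Inner Distance Shape Signature (IDSS)
#'
#' Bins the pairwise inner distances into a `B`-bin (default 128)
#' probability density over `[0, dMax]`. In `per_shape_max` mode `dMax` is
#' the largest observed inner distance, which makes the signature invariant
#' under uniform scaling; `fixed_range` mode uses a caller-supplied `dMax`
#' so that databases can be compared on an absolute length scale.
#'
#' @param distances an [InnerDistanceSet-class].
#' @param B bin count; 128 by convention.
#' @param mode `"per_shape_max"` (default) or `"fixed_range"`.
#' @param dMax histogram upper edge in Angstrom (`fixed_range` only; must
#'   be >= the largest observed distance).
#' @return a [ShapeDescriptor-class] with `method = "IDSS"`.
#' @export
idssDescriptor <- function(distances, B = 128L,
                           mode = c("per_shape_max", "fixed_range"),
                           dMax = NULL) {
  stopifnot(is(distances, "InnerDistanceSet"))
  mode <- match.arg(mode)
  .newHistDescriptor("IDSS", distances@values, B, mode, dMax,
                     distances@sourceId)
}

#' D2 descriptor: Euclidean distances between landmarks
#'
#' The straight-line (chord) analogue of the IDSS on the same Lloyd
#' landmarks. Chords shorten when a shape bends, so D2 separates conformers
#' of one flexible molecule that the IDSS keeps together -- the contrast
#' the benchmark quantifies.
#'
#' @param samples a [SamplePoints-class].
#' @inheritParams idssDescriptor
#' @return a [ShapeDescriptor-class] with `method = "D2"`.
#' @export
d2Descriptor <- function(samples, B = 128L,
                         mode = c("per_shape_max", "fixed_range"),
                         dMax = NULL) {
  stopifnot(is(samples, "SamplePoints"))
  mode <- match.arg(mode)
  P <- .voxelCenters(samples@grid, samples@indices)
  d2 <- .cross2(P, P)
  vals <- sqrt(d2[upper.tri(d2)])
  .newHistDescriptor("D2", vals, B, mode, dMax, samples@grid@sourceId)
}

#' GD descriptor: geodesic distances along the surface
#'
#' Shortest paths restricted to the surface-voxel subgraph (26-connectivity
#' among boundary voxels only), binned like the IDSS. Paths may not cut
#' through the volume, so the GD is a surface-intrinsic baseline.
#'
#' @param surface a [SurfaceVoxels-class].
#' @param samples a [SamplePoints-class] on the same grid.
#' @inheritParams idssDescriptor
#' @return a [ShapeDescriptor-class] with `method = "GD"`.
#' @export
gdDescriptor <- function(surface, samples, B = 128L,
                         mode = c("per_shape_max", "fixed_range"),
                         dMax = NULL) {
  stopifnot(is(surface, "SurfaceVoxels"), is(samples, "SamplePoints"))
  mode <- match.arg(mode)
  grid <- surface@grid
  occ <- array(FALSE, dim(grid@occupancy))
  occ[surface@indices] <- TRUE
  e <- .voxelEdgeList(occ, h = grid@h)
  g <- igraph::make_graph(rbind(e$from, e$to), n = length(e$nodes),
                          directed = FALSE)
  igraph::E(g)$weight <- e$weight
  lin <- .linearIndex(dim(occ), samples@indices)
  nodes <- match(lin, e$nodes)
  if (anyNA(nodes)) stop("sample point is not a surface voxel")
  D <- igraph::distances(g, v = nodes, to = nodes, algorithm = "dijkstra")
  vals <- D[upper.tri(D)]
  if (any(!is.finite(vals)))
    stop("surface subgraph disconnects a sample pair; GD undefined")
  .newHistDescriptor("GD", vals, B, mode, dMax, grid@sourceId)
}

#' SD descriptor: shape distribution over random surface pairs
#'
#' The classical shape-distribution baseline: Euclidean distances between
#' `nPairs` uniformly random (seeded, non-Lloyd) surface voxel pairs,
#' binned to a PDF.
#'
#' @param surface a [SurfaceVoxels-class].
#' @param nPairs number of random pairs (default 8128).
#' @param seed integer seed for the pair draw.
#' @inheritParams idssDescriptor
#' @return a [ShapeDescriptor-class] with `method = "SD"`.
#' @export
sdDescriptor <- function(surface, nPairs = 8128L, B = 128L,
                         mode = c("per_shape_max", "fixed_range"),
                         dMax = NULL, seed = 1L) {
  stopifnot(is(surface, "SurfaceVoxels"))
  mode <- match.arg(mode)
  m <- nrow(surface@indices)
  if (m < 2) stop("need at least 2 surface voxels")
  hasSeed <- exists(".Random.seed", .GlobalEnv)
  if (hasSeed) saved <- get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  i <- sample.int(m, nPairs, replace = TRUE)
  j <- sample.int(m - 1L, nPairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)  # j != i, uniform over the other voxels
  if (hasSeed) assign(".Random.seed", saved, .GlobalEnv)
  else if (exists(".Random.seed", .GlobalEnv))
    rm(".Random.seed", envir = .GlobalEnv)
  P <- .voxelCenters(surface@grid, surface@indices)
  vals <- sqrt(rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
  .newHistDescriptor("SD", vals, B, mode, dMax, surface@grid@sourceId)
}

#' SHD descriptor: rotation-invariant spherical-harmonic energies
#'
#' Centers the shape at its occupancy centroid, restricts the binary
#' occupancy to `nShells` concentric spherical shells up to the maximal
#' radius, expands each shell function in spherical harmonics on a
#' Gauss-Legendre latitude x equispaced longitude grid, and records the
#' rotation-invariant per-frequency energies \eqn{\|f_l\|} for
#' `l = 0..L`. The concatenated `nShells * (L + 1)` energies are
#' L2-normalised (this descriptor is a unit vector, not a PDF).
#'
#' @param grid a [VoxelGrid-class].
#' @param nShells number of radial shells (default 32).
#' @param L maximum spherical-harmonic degree (default 16).
#' @param nTheta,nPhi sphere sampling resolution (default 64 x 128).
#' @return a [ShapeDescriptor-class] with `method = "SHD"`.
#' @export
shdDescriptor <- function(grid, nShells = 32L, L = 16L,
                          nTheta = 64L, nPhi = 128L) {
  stopifnot(is(grid, "VoxelGrid"))
  occ <- grid@occupancy
  d <- dim(occ)
  idx <- .arrayIndex(d, which(occ))
  ctr <- colMeans(idx - 0.5)
  rmax <- sqrt(max(rowSums(sweep(idx - 0.5, 2, ctr)^2))) + 0.5
  gl <- pracma::gaussLegendre(nTheta, -1, 1)
  x <- gl$x; wq <- gl$w
  sinT <- sqrt(pmax(1 - x^2, 0))
  phi <- 2 * pi * (seq_len(nPhi) - 1) / nPhi
  dPhi <- 2 * pi / nPhi
  # unit directions, nTheta x nPhi each
  dx <- outer(sinT, cos(phi)); dy <- outer(sinT, sin(phi))
  dz <- matrix(x, nTheta, nPhi)
  E <- exp(-1i * outer(phi, 0:L)) * dPhi        # nPhi x (L+1)
  Pleg <- lapply(0:L, function(l) {
    if (l == 0) matrix(1, 1, nTheta) else pracma::legendre(l, x)
  })
  Nlm <- lapply(0:L, function(l) {
    m <- 0:l
    sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  })
  radii <- (seq_len(nShells) - 0.5) / nShells * rmax
  energy <- matrix(0, nShells, L + 1)
  for (s in seq_len(nShells)) {
    r <- radii[s]
    px <- floor(ctr[1] + r * dx) + 1L
    py <- floor(ctr[2] + r * dy) + 1L
    pz <- floor(ctr[3] + r * dz) + 1L
    ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
    f <- matrix(0, nTheta, nPhi)
    f[ok] <- as.numeric(occ[cbind(px[ok], py[ok], pz[ok])])
    if (all(f == 0)) next
    Fm <- f %*% E                                # nTheta x (L+1)
    for (l in 0:L) {
      cl <- complex(l + 1)
      for (mm in 0:l) {
        cl[mm + 1] <- Nlm[[l + 1]][mm + 1] *
          sum(wq * Pleg[[l + 1]][mm + 1, ] * Fm[, mm + 1])
      }
      energy[s, l + 1] <- sqrt(Mod(cl[1])^2 +
                                 if (l > 0) 2 * sum(Mod(cl[-1])^2) else 0)
    }
  }
  v <- as.vector(t(energy))   # shell-major blocks of (L+1) energies
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  new("ShapeDescriptor", method = "SHD", bins = v, B = length(v),
      mode = "none", dMax = NA_real_, sourceId = grid@sourceId)
}

#' SAH descriptor: solid-angle (ball occupancy) histogram
#'
#' For every surface voxel, computes the fraction of a radius-`ballRadius`
#' voxel ball centered there that is occupied -- the discrete solid-angle
#' measure of local concavity (flat surface ~ 0.5, spike tips < 0.5, pocket
#' walls > 0.5) -- and bins the fractions over \[0, 1\] into a `B`-bin PDF.
#'
#' @param grid a [VoxelGrid-class].
#' @param ballRadius ball radius in voxels (default 4).
#' @param B bin count (default 64).
#' @return a [ShapeDescriptor-class] with `method = "SAH"`.
#' @export
sahDescriptor <- function(grid, ballRadius = 4L, B = 64L) {
  stopifnot(is(grid, "VoxelGrid"))
  occ <- grid@occupancy
  d <- dim(occ)
  surf <- extractSurface(grid)@indices
  offs <- .ballOffsets(ballRadius, includeCenter = TRUE)
  counts <- numeric(nrow(surf))
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(surf, 2, offs[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    hit <- logical(nrow(surf))
    hit[ok] <- occ[nb[ok, , drop = FALSE]]
    counts <- counts + hit
  }
  frac <- counts / nrow(offs)
  k <- pmin(floor(frac * B) + 1L, B)
  bins <- tabulate(k, nbins = B) / length(frac)
  new("ShapeDescriptor", method = "SAH", bins = bins, B = as.integer(B),
      mode = "fixed_range", dMax = 1, sourceId = grid@sourceId)
}

#' Compute a set of descriptors for one grid
#'
#' Convenience wrapper running the shared stages (surface extraction,
#' Lloyd sampling, voxel graph, inner distances) once and producing the
#' requested descriptors.
#'
#' @param grid a [VoxelGrid-class].
#' @param methods subset of `c("IDSS", "D2", "GD", "SD", "SHD", "SAH")`.
#' @param n number of Lloyd landmarks (default 128).
#' @param B histogram bin count (default 128).
#' @param mode histogram normalisation mode.
#' @param dMax fixed-range upper edge (if `mode = "fixed_range"`).
#' @param seed integer seed for sampling stages.
#' @param sdPairs random pair count for SD (default `n * (n - 1) / 2`).
#' @param sahRadius,sahBins SAH ball radius and bin count.
#' @param shdShells,shdL SHD shell count and maximum degree.
#' @return named list of [ShapeDescriptor-class] objects.
#' @export
describeGrid <- function(grid, methods = c("IDSS", "D2"), n = 128L,
                         B = 128L, mode = "per_shape_max", dMax = NULL,
                         seed = 1L, sdPairs = NULL, sahRadius = 4L,
                         sahBins = 64L, shdShells = 32L, shdL = 16L) {
  methods <- match.arg(methods, c("IDSS", "D2", "GD", "SD", "SHD", "SAH"),
                       several.ok = TRUE)
  out <- list()
  needSurf <- any(methods %in% c("IDSS", "D2", "GD", "SD"))
  if (needSurf) {
    surf <- extractSurface(grid)
    n <- min(n, nrow(surf@indices))
  }
  if (any(methods %in% c("IDSS", "D2", "GD")))
    samples <- lloydSample(surf, n, seed = seed)
  if ("IDSS" %in% methods) {
    vg <- buildVoxelGraph(grid)
    ids <- allPairsInnerDistances(vg, samples)
    out$IDSS <- idssDescriptor(ids, B = B, mode = mode, dMax = dMax)
  }
  if ("D2" %in% methods)
    out$D2 <- d2Descriptor(samples, B = B, mode = mode, dMax = dMax)
  if ("GD" %in% methods)
    out$GD <- gdDescriptor(surf, samples, B = B, mode = mode, dMax = dMax)
  if ("SD" %in% methods) {
    if (is.null(sdPairs)) sdPairs <- as.integer(n * (n - 1) / 2)
    out$SD <- sdDescriptor(surf, nPairs = sdPairs, B = B, mode = mode,
                           dMax = dMax, seed = seed)
  }
  if ("SHD" %in% methods)
    out$SHD <- shdDescriptor(grid, nShells = shdShells, L = shdL)
  if ("SAH" %in% methods)
    out$SAH <- sahDescriptor(grid, ballRadius = sahRadius, B = sahBins)
  out
}

#' Write / read a descriptor as JSON
#'
#' The on-disk record is `{id, method, B, mode, d_max, bins[]}` with full
#' double precision, so a round-trip is bit-exact.
#'
#' @param desc a [ShapeDescriptor-class].
#' @param path file path.
#' @return `readDescriptor` returns a [ShapeDescriptor-class]; the writer
#'   returns `path` invisibly.
#' @export
writeDescriptor <- function(desc, path) {
  stopifnot(is(desc, "ShapeDescriptor"))
  obj <- list(id = desc@sourceId, method = desc@method, B = desc@B,
              mode = desc@mode, d_max = desc@dMax, bins = desc@bins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname writeDescriptor
#' @export
readDescriptor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ShapeDescriptor", method = obj$method, bins = as.numeric(obj$bins),
      B = as.integer(obj$B), mode = obj$mode,
      dMax = if (is.null(obj$d_max)) NA_real_ else as.numeric(obj$d_max),
      sourceId = obj$id)
}
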