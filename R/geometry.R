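# Landmark sampling on the boundary and shortest-path inner distances
# through the voxelized molecular volume.

#' Spread landmark points over a surface with Lloyd relaxation
#'
#' k-means-style relaxation over surface voxel centers: each surface voxel
#' is assigned to its nearest site (ambient Euclidean distance), then each
#' site moves to the member voxel nearest its cluster centroid. Iteration
#' stops when no site moves or after `maxIter` rounds. Initialisation is a
#' seeded uniform draw, so the result is deterministic for a fixed seed.
#' The relaxed sites are approximately uniform (blue-noise) on the surface,
#' which keeps the inner-distance histogram stable across seeds.
#'
#' @param surface a [SurfaceVoxels-class].
#' @param n number of landmarks (1 <= n <= number of surface voxels).
#' @param seed integer seed.
#' @param maxIter maximum relaxation rounds (default 20).
#' @return a [SamplePoints-class].
#' @export
lloydSample <- function(surface, n, seed = 1L, maxIter = 20L) {
  stopifnot(is(surface, "SurfaceVoxels"))
  m <- nrow(surface@indices)
  if (n < 1) stop("n must be >= 1")
  if (n > m) stop("n exceeds the number of surface voxels (", m, ")")
  pts <- surface@indices
  if (n == m) {
    return(new("SamplePoints", indices = pts, grid = surface@grid,
               seed = as.integer(seed)))
  }
  hasSeed <- exists(".Random.seed", .GlobalEnv)
  if (hasSeed) saved <- get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  sites <- sort(sample.int(m, n))
  if (hasSeed) assign(".Random.seed", saved, .GlobalEnv)
  else if (exists(".Random.seed", .GlobalEnv))
    rm(".Random.seed", envir = .GlobalEnv)
  P <- pts * 1.0
  for (it in seq_len(maxIter)) {
    d2 <- .cross2(P, P[sites, , drop = FALSE])
    assign_ <- max.col(-d2, ties.method = "first")
    newSites <- sites
    for (c in seq_len(n)) {
      mem <- which(assign_ == c)
      if (length(mem) == 0) next  # keep the site where it is
      cen <- colMeans(P[mem, , drop = FALSE])
      d2c <- rowSums(sweep(P[mem, , drop = FALSE], 2, cen)^2)
      newSites[c] <- mem[which.min(d2c)]
    }
    if (all(newSites == sites)) break
    sites <- newSites
  }
  sites <- unique(sites)
  # collisions are possible if two clusters relax onto one voxel; top up
  # deterministically with the surface voxels farthest from current sites
  while (length(sites) < n) {
    d2 <- .cross2(P, P[sites, , drop = FALSE])
    far <- order(apply(d2, 1, min), decreasing = TRUE)
    far <- setdiff(far, sites)
    sites <- c(sites, far[seq_len(n - length(sites))])
  }
  new("SamplePoints", indices = pts[sort(sites), , drop = FALSE],
      grid = surface@grid, seed = as.integer(seed))
}

#' Build the weighted 26-connectivity graph of a grid
#'
#' One node per occupied voxel (interior voxels included, so shortest paths
#' may cut through the volume), edges between 26-neighbors weighted by the
#' Euclidean center distance: `h`, `h*sqrt(2)` or `h*sqrt(3)`. The grid
#' must form a single connected component (as guaranteed by [voxelize()]
#' and [makeSyntheticShape()]).
#'
#' @param grid a [VoxelGrid-class].
#' @return a [VoxelGraph-class].
#' @export
buildVoxelGraph <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  occ <- grid@occupancy
  e <- .voxelEdgeList(occ, h = grid@h)
  nv <- length(e$nodes)
  g <- igraph::make_graph(rbind(e$from, e$to), n = nv, directed = FALSE)
  igraph::E(g)$weight <- e$weight
  if (nv > 1 && igraph::components(g)$no > 1)
    stop("grid is disconnected; filter to one component first")
  new("VoxelGraph", graph = g, nodeIndex = as.integer(e$nodes), grid = grid)
}

# map n x 3 lattice coordinates to graph node ids
.graphNodes <- function(vg, idx) {
  lin <- .linearIndex(dim(vg@grid@occupancy), idx)
  node <- match(lin, vg@nodeIndex)
  if (anyNA(node)) stop("voxel is not a node of the graph")
  node
}

#' Inner distance between two voxels
#'
#' The length of the shortest path between the two voxel centers that stays
#' inside the molecular volume (minimum-weight path on the 26-connectivity
#' graph). Unlike the Euclidean chord, this length is nearly unchanged when
#' the shape articulates, which is what makes the IDSS
#' deformation-invariant.
#'
#' @param vgraph a [VoxelGraph-class].
#' @param p,q length-3 lattice coordinates of occupied voxels.
#' @return shortest-path length in Angstrom.
#' @export
innerDistance <- function(vgraph, p, q) {
  stopifnot(is(vgraph, "VoxelGraph"))
  nodes <- .graphNodes(vgraph, rbind(p, q))
  as.numeric(igraph::distances(vgraph@graph, v = nodes[1], to = nodes[2],
                               algorithm = "dijkstra"))
}

#' All pairwise inner distances between landmarks
#'
#' Runs one single-source Dijkstra sweep per landmark and collects the
#' `n(n-1)/2` pairwise shortest-path lengths.
#'
#' @param vgraph a [VoxelGraph-class].
#' @param samples a [SamplePoints-class] on the same grid.
#' @return an [InnerDistanceSet-class].
#' @export
allPairsInnerDistances <- function(vgraph, samples) {
  stopifnot(is(vgraph, "VoxelGraph"), is(samples, "SamplePoints"))
  n <- nrow(samples@indices)
  if (n < 2) stop("need at least 2 sample points")
  nodes <- .graphNodes(vgraph, samples@indices)
  D <- igraph::distances(vgraph@graph, v = nodes, to = nodes,
                         algorithm = "dijkstra")
  new("InnerDistanceSet", values = D[upper.tri(D)], n = as.integer(n),
      sourceId = vgraph@grid@sourceId)
}
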