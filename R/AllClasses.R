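#' @import methods
NULL

#' Atoms of one macromolecular chain
#'
#' Holds the parsed atoms of a single chain: element symbols, Cartesian
#' coordinates (\eqn{\mathrm{\AA}}) and van der Waals radii
#' (\eqn{\mathrm{\AA}}). This is the input to [voxelize()].
#'
#' @slot element character vector of element symbols.
#' @slot coords numeric n x 3 matrix of coordinates in Angstrom.
#' @slot radius numeric vector of van der Waals radii in Angstrom.
#' @slot chainId single chain identifier.
#' @slot sourceId molecule label, e.g. `"1aon-A"`.
#' @seealso [readStructure()]
#' @export
setClass("AtomSet",
  representation(
    element = "character",
    coords = "matrix",
    radius = "numeric",
    chainId = "character",
    sourceId = "character"
  )
)

setValidity("AtomSet", function(object) {
  n <- length(object@element)
  if (n < 1) return("AtomSet must contain at least one atom")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3 ||
      nrow(object@coords) != n)
    return("coords must be an n x 3 numeric matrix matching element count")
  if (length(object@radius) != n) return("one radius per atom required")
  if (any(object@radius <= 0)) return("all van der Waals radii must be > 0")
  if (any(!is.finite(object@coords))) return("all coordinates must be finite")
  TRUE
})

#' Uniform occupancy lattice of a molecular volume
#'
#' A boolean 3D lattice at resolution `h` (\eqn{\mathrm{\AA}}) whose occupied
#' voxels approximate the solvent-excluded molecular volume. Voxel `(i,j,k)`
#' has its center at `origin + (c(i,j,k) - 0.5) * h`.
#'
#' @slot origin numeric length-3 lattice origin in Angstrom.
#' @slot h voxel edge length in Angstrom.
#' @slot occupancy logical 3D array.
#' @slot sourceId molecule label.
#' @seealso [voxelize()], [makeSyntheticShape()], [extractSurface()]
#' @export
setClass("VoxelGrid",
  representation(
    origin = "numeric",
    h = "numeric",
    occupancy = "array",
    sourceId = "character"
  )
)

setValidity("VoxelGrid", function(object) {
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    return("origin must be a finite length-3 numeric")
  if (length(object@h) != 1 || !is.finite(object@h) || object@h <= 0)
    return("resolution h must be a single positive number")
  if (!is.logical(object@occupancy) || length(dim(object@occupancy)) != 3)
    return("occupancy must be a logical 3D array")
  if (!any(object@occupancy)) return("grid must contain >= 1 occupied voxel")
  TRUE
})

#' Boundary voxels of a voxel grid
#'
#' The occupied voxels having at least one unoccupied 6-neighbor (voxels on
#' the lattice boundary count their missing neighbors as unoccupied).
#'
#' @slot indices integer n x 3 matrix of lattice coordinates.
#' @slot grid the parent [VoxelGrid-class].
#' @seealso [extractSurface()], [lloydSample()]
#' @export
setClass("SurfaceVoxels",
  representation(indices = "matrix", grid = "VoxelGrid")
)

setValidity("SurfaceVoxels", function(object) {
  idx <- object@indices
  if (!is.numeric(idx) || ncol(idx) != 3 || nrow(idx) < 1)
    return("indices must be a non-empty n x 3 matrix")
  occ <- object@grid@occupancy
  if (!all(occ[idx])) return("every surface voxel must be occupied")
  TRUE
})

#' Landmark points sampled on a molecular surface
#'
#' `n` distinct surface voxels spread by Lloyd relaxation, the endpoints of
#' the inner-distance pairs that make up the IDSS.
#'
#' @slot indices integer n x 3 matrix of lattice coordinates (surface voxels).
#' @slot grid the parent [VoxelGrid-class].
#' @slot seed integer seed used for the (deterministic) sampling.
#' @seealso [lloydSample()], [allPairsInnerDistances()]
#' @export
setClass("SamplePoints",
  representation(indices = "matrix", grid = "VoxelGrid", seed = "integer")
)

setValidity("SamplePoints", function(object) {
  idx <- object@indices
  if (!is.numeric(idx) || ncol(idx) != 3 || nrow(idx) < 1)
    return("indices must be a non-empty n x 3 matrix")
  if (anyDuplicated(asplit(idx, 1)) > 0)
    return("sample points must be pairwise distinct")
  TRUE
})

#' Weighted graph over the occupied voxels of a grid
#'
#' Nodes are occupied voxels (interior included: shortest paths may cut
#' through the volume); edges join 26-neighbors, weighted by the Euclidean
#' distance between voxel centers (`h`, `h*sqrt(2)`, `h*sqrt(3)`).
#'
#' @slot graph an [igraph::igraph] object.
#' @slot nodeIndex integer vector: linear occupancy index of each node.
#' @slot grid the parent [VoxelGrid-class].
#' @seealso [buildVoxelGraph()], [innerDistance()]
#' @export
setClass("VoxelGraph",
  representation(graph = "ANY", nodeIndex = "integer", grid = "VoxelGrid")
)

#' Multiset of pairwise inner distances
#'
#' The `n(n-1)/2` shortest-path lengths (\eqn{\mathrm{\AA}}) between all
#' pairs of landmark points, the raw material of the IDSS histogram.
#'
#' @slot values numeric vector of non-negative path lengths in Angstrom.
#' @slot n number of sample points the pairs were drawn from.
#' @slot sourceId molecule label.
#' @seealso [allPairsInnerDistances()], [idssDescriptor()]
#' @export
setClass("InnerDistanceSet",
  representation(values = "numeric", n = "integer", sourceId = "character")
)

setValidity("InnerDistanceSet", function(object) {
  n <- object@n
  if (length(object@values) != n * (n - 1) / 2)
    return("value count must equal n(n-1)/2")
  if (any(object@values < 0)) return("inner distances must be non-negative")
  TRUE
})

#' A shape descriptor vector
#'
#' A `B`-bin descriptor of one molecular shape: for the histogram methods
#' (IDSS, D2, GD, SD, SAH) a probability density summing to 1; for SHD an
#' L2-normalised vector of per-shell spherical-harmonic energies.
#'
#' @slot method one of `"IDSS"`, `"D2"`, `"GD"`, `"SD"`, `"SHD"`, `"SAH"`.
#' @slot bins numeric vector of B non-negative values.
#' @slot B bin count (128 for IDSS by convention).
#' @slot mode distance normalisation: `"per_shape_max"` or `"fixed_range"`.
#' @slot dMax upper histogram edge actually used, in Angstrom (NA for SHD/SAH).
#' @slot sourceId molecule label.
#' @seealso [idssDescriptor()], [similarity()]
#' @export
setClass("ShapeDescriptor",
  representation(
    method = "character",
    bins = "numeric",
    B = "integer",
    mode = "character",
    dMax = "numeric",
    sourceId = "character"
  )
)

.HIST_METHODS <- c("IDSS", "D2", "GD", "SD", "SAH")

setValidity("ShapeDescriptor", function(object) {
  if (!object@method %in% c(.HIST_METHODS, "SHD"))
    return("unknown descriptor method")
  if (length(object@bins) != object@B)
    return("bin vector length must equal B")
  if (any(object@bins < 0)) return("descriptor entries must be >= 0")
  if (object@method %in% .HIST_METHODS &&
      abs(sum(object@bins) - 1) > 1e-9)
    return("histogram descriptor must sum to 1 (+/- 1e-9)")
  TRUE
})

#' A searchable database of molecule descriptors
#'
#' Per-molecule records (unique id, conformational group label for
#' evaluation, one descriptor per method) supporting ranked retrieval,
#' precision-recall evaluation and MDS navigation maps.
#'
#' @slot ids character vector of unique molecule ids.
#' @slot groups character vector of group labels (parallel to `ids`).
#' @slot descriptors list (parallel to `ids`) of named lists of
#'   [ShapeDescriptor-class] objects, keyed by method.
#' @seealso [buildIndex()], [queryIndex()], [precisionRecall()]
#' @export
setClass("ShapeIndex",
  representation(ids = "character", groups = "character", descriptors = "list")
)

setValidity("ShapeIndex", function(object) {
  if (anyDuplicated(object@ids)) return("molecule ids must be unique")
  if (length(object@groups) != length(object@ids))
    return("one group label per id required")
  if (length(object@descriptors) != length(object@ids))
    return("one descriptor list per id required")
  TRUE
})

#' Group-averaged precision-recall curve
#'
#' Precision interpolated onto a fixed increasing recall grid, averaged
#' first within each conformational group and then across groups, plus the
#' trapezoidal area under the curve.
#'
#' @slot recall increasing recall grid in (0, 1].
#' @slot precision precision values in \[0, 1\], parallel to `recall`.
#' @slot auc trapezoidal area under the curve over recall in \[0, 1\].
#' @slot perGroup list of per-group precision vectors on the same grid.
#' @seealso [precisionRecall()], [prAUC()]
#' @export
setClass("PRCurve",
  representation(
    recall = "numeric",
    precision = "numeric",
    auc = "numeric",
    perGroup = "list"
  )
)

setValidity("PRCurve", function(object) {
  if (any(diff(object@recall) <= 0))
    return("recall grid must be strictly increasing")
  if (length(object@precision) != length(object@recall))
    return("precision and recall must have equal length")
  if (any(object@precision < 0 | object@precision > 1))
    return("precision must lie in [0, 1]")
  TRUE
})

#' Low-dimensional navigation map of a molecule database
#'
#' 2D or 3D coordinates per molecule from classical multidimensional
#' scaling of the pairwise descriptor distance matrix, with one color per
#' conformational group for map display.
#'
#' @slot coords numeric n x d matrix, d in \{2, 3\}.
#' @slot ids molecule ids (rownames of `coords`).
#' @slot groups group labels, parallel to `ids`.
#' @slot colors hex color per molecule (shared within a group).
#' @slot stress normalised residual
#'   \eqn{\sqrt{\sum(\hat d_{ij}-d_{ij})^2 / \sum d_{ij}^2}}.
#' @seealso [mdsEmbed()], [exportNavigation()]
#' @export
setClass("ShapeEmbedding",
  representation(
    coords = "matrix",
    ids = "character",
    groups = "character",
    colors = "character",
    stress = "numeric"
  )
)

setValidity("ShapeEmbedding", function(object) {
  d <- ncol(object@coords)
  if (!d %in% c(2L, 3L)) return("embedding dimension must be 2 or 3")
  if (nrow(object@coords) != length(object@ids))
    return("one coordinate row per molecule required")
  if (object@stress < 0) return("stress must be non-negative")
  TRUE
})

## ---- show methods ----

setMethod("show", "AtomSet", function(object) {
  cat(sprintf("AtomSet '%s' chain %s: %d atoms\n",
              object@sourceId, object@chainId, length(object@element)))
  cat("  elements:", paste(names(sort(table(object@element),
                                      decreasing = TRUE)), collapse = " "),
      "\n")
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf(
    "VoxelGrid '%s': %d x %d x %d @ h = %.3g A, %d occupied voxels\n",
    object@sourceId, d[1], d[2], d[3], object@h, sum(object@occupancy)))
})

setMethod("show", "SurfaceVoxels", function(object) {
  cat(sprintf("SurfaceVoxels: %d boundary voxels of '%s'\n",
              nrow(object@indices), object@grid@sourceId))
})

setMethod("show", "SamplePoints", function(object) {
  cat(sprintf("SamplePoints: %d Lloyd-relaxed surface landmarks (seed %d)\n",
              nrow(object@indices), object@seed))
})

setMethod("show", "VoxelGraph", function(object) {
  cat(sprintf("VoxelGraph: %d nodes, %d edges (26-connectivity)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "InnerDistanceSet", function(object) {
  cat(sprintf(
    "InnerDistanceSet '%s': %d pairs from %d points, range [%.2f, %.2f] A\n",
    object@sourceId, length(object@values), object@n,
    min(object@values), max(object@values)))
})

setMethod("show", "ShapeDescriptor", function(object) {
  cat(sprintf("ShapeDescriptor %s '%s': %d bins, mode %s, dMax %.3g\n",
              object@method, object@sourceId, object@B, object@mode,
              object@dMax))
})

setMethod("show", "ShapeIndex", function(object) {
  cat(sprintf("ShapeIndex: %d molecules, %d groups, methods: %s\n",
              length(object@ids), length(unique(object@groups)),
              paste(unique(unlist(lapply(object@descriptors, names))),
                    collapse = " ")))
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d recall levels, %d groups, AUC = %.4f\n",
              length(object@recall), length(object@perGroup), object@auc))
})

setMethod("show", "ShapeEmbedding", function(object) {
  cat(sprintf("ShapeEmbedding: %d molecules in %dD, stress = %.4g\n",
              nrow(object@coords), ncol(object@coords), object@stress))
})
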