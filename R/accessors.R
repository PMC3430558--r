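# Accessor generics: user code should not reach into slots directly.

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("gridResolution", function(x) standardGeneric("gridResolution"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("descriptorBins", function(x) standardGeneric("descriptorBins"))

#' @rdname accessors
#' @export
setGeneric("descriptorMethod", function(x) standardGeneric("descriptorMethod"))

#' @rdname accessors
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname accessors
#' @export
setGeneric("surfaceIndices", function(x) standardGeneric("surfaceIndices"))

#' @rdname accessors
#' @export
setGeneric("samplePoints", function(x) standardGeneric("samplePoints"))

#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname accessors
#' @export
setGeneric("embeddingStress", function(x) standardGeneric("embeddingStress"))

#' @rdname accessors
#' @export
setGeneric("indexIds", function(x) standardGeneric("indexIds"))

#' @rdname accessors
#' @export
setGeneric("indexGroups", function(x) standardGeneric("indexGroups"))

#' Accessors for idssr objects
#'
#' Small read-only accessors for the package's S4 containers: the occupancy
#' lattice, resolution and label of a [VoxelGrid-class]; the lattice
#' coordinates of [SurfaceVoxels-class] and [SamplePoints-class]; the bin
#' vector and method of a [ShapeDescriptor-class]; the distance multiset of
#' an [InnerDistanceSet-class]; ids/groups of a [ShapeIndex-class]; and
#' coordinates/stress of a [ShapeEmbedding-class].
#'
#' @param x the object.
#' @return the slot value (a copy; objects are immutable).
#' @name accessors
NULL

#' @rdname accessors
setMethod("occupancy", "VoxelGrid", function(x) x@occupancy)

#' @rdname accessors
setMethod("gridResolution", "VoxelGrid", function(x) x@h)

#' @rdname accessors
setMethod("sourceId", "VoxelGrid", function(x) x@sourceId)

#' @rdname accessors
setMethod("sourceId", "AtomSet", function(x) x@sourceId)

#' @rdname accessors
setMethod("sourceId", "ShapeDescriptor", function(x) x@sourceId)

#' @rdname accessors
setMethod("descriptorBins", "ShapeDescriptor", function(x) x@bins)

#' @rdname accessors
setMethod("descriptorMethod", "ShapeDescriptor", function(x) x@method)

#' @rdname accessors
setMethod("distValues", "InnerDistanceSet", function(x) x@values)

#' @rdname accessors
setMethod("surfaceIndices", "SurfaceVoxels", function(x) x@indices)

#' @rdname accessors
setMethod("samplePoints", "SamplePoints", function(x) x@indices)

#' @rdname accessors
setMethod("embeddingCoords", "ShapeEmbedding", function(x) x@coords)

#' @rdname accessors
setMethod("embeddingStress", "ShapeEmbedding", function(x) x@stress)

#' @rdname accessors
setMethod("indexIds", "ShapeIndex", function(x) x@ids)

#' @rdname accessors
setMethod("indexGroups", "ShapeIndex", function(x) x@groups)
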