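# PDB ingestion and voxelization of the solvent-excluded molecular volume.

# Bondi van der Waals radii (Angstrom); unlisted elements fall back to 1.70.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.VDW_DEFAULT <- 1.70

.vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

#' Read one chain of a PDB structure
#'
#' Parses a PDB file, keeps the `ATOM` records of the requested chain
#' (first model only), drops waters and -- by default -- `HETATM` records,
#' and assigns van der Waals radii from a built-in Bondi table
#' (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, default 1.70
#' \eqn{\mathrm{\AA}}).
#'
#' @param path path to a PDB file.
#' @param chain single chain identifier, e.g. `"A"`.
#' @param includeHetatm keep non-water `HETATM` records (default `FALSE`).
#' @param sourceId molecule label for downstream outputs; defaults to
#'   `"<basename>-<chain>"`.
#' @return an [AtomSet-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' readStructure(pdb, "A")
#' @export
readStructure <- function(path, chain, includeHetatm = FALSE,
                          sourceId = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!chain %in% unique(at$chain)) stop("chain not found: ", chain)
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[at$resid != "HOH" & at$resid != "WAT", , drop = FALSE]
  if (!includeHetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no atoms left after filtering")
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) # fall back on the first letter of the atom name
    elem[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1)
  if (is.null(sourceId))
    sourceId <- paste0(sub("\\.(pdb|ent)$", "", basename(path),
                           ignore.case = TRUE), "-", chain)
  new("AtomSet",
      element = toupper(elem),
      coords = cbind(at$x, at$y, at$z),
      radius = .vdwRadius(elem),
      chainId = chain,
      sourceId = sourceId)
}

#' Voxelize atoms into a solvent-excluded volume
#'
#' Builds the volumetric model on a uniform lattice: voxels whose centers
#' lie within `radius + probe` of any atom are marked (probe-dilated van der
#' Waals union), then the set is eroded by the probe radius (digital-ball
#' erosion, equivalent to thresholding the Euclidean distance transform of
#' the complement at `probe`). The dilation/erosion pair is a morphological
#' closing that approximates the Connolly (solvent-excluded) volume, exactly
#' so as `h -> 0`. Only the largest 26-connected component is kept, since
#' inner distances are undefined across disconnected pieces.
#'
#' If the lattice would exceed `maxDim` voxels along any axis, `h` is scaled
#' up automatically with a warning.
#'
#' @param atoms an [AtomSet-class].
#' @param h lattice resolution in Angstrom (> 0); default 1.0.
#' @param probe solvent probe radius in Angstrom (>= 0); default 1.4.
#' @param maxDim cap on lattice dimensions; default 96.
#' @return a [VoxelGrid-class].
#' @examples
#' a <- new("AtomSet", element = "C", coords = rbind(c(0, 0, 0)),
#'          radius = 2.0, chainId = "A", sourceId = "ball")
#' g <- voxelize(a, h = 0.5, probe = 0)
#' sum(g@occupancy) * 0.5^3  # ~ (4/3) * pi * 2^3
#' @export
voxelize <- function(atoms, h = 1.0, probe = 1.4, maxDim = 96L) {
  stopifnot(is(atoms, "AtomSet"))
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("resolution h must be a single positive number")
  if (!is.numeric(probe) || length(probe) != 1 || probe < 0)
    stop("probe radius must be >= 0")
  xyz <- atoms@coords
  reach <- atoms@radius + probe
  # snap the origin to the global h-lattice so grids of the same molecule
  # at different probe/pad settings sample identical voxel centers
  frame <- function(h) {
    pad <- max(reach) + 2 * h + probe
    lo <- floor((apply(xyz, 2, min) - pad) / h) * h
    hi <- apply(xyz, 2, max) + pad
    list(lo = lo, d = ceiling((hi - lo) / h))
  }
  fr <- frame(h)
  if (max(fr$d) > maxDim) {
    h0 <- h
    while (max(fr$d) > maxDim) {
      h <- h * max(fr$d) / maxDim * 1.001
      fr <- frame(h)
    }
    warning(sprintf(
      "lattice exceeds the %d-voxel cap; rescaling h from %.3g to %.3g A",
      maxDim, h0, h))
  }
  lo <- fr$lo
  d <- pmax(as.integer(fr$d), 1L)
  occ <- array(FALSE, d)
  # dilation: exact sphere rasterisation per atom over its bounding sub-box
  for (i in seq_len(nrow(xyz))) {
    r <- reach[i]
    cv <- (xyz[i, ] - lo) / h + 0.5  # atom center in voxel coordinates
    rng <- lapply(1:3, function(k) {
      max(1L, floor(cv[k] - r / h)):min(d[k], ceiling(cv[k] + r / h))
    })
    ax <- (rng[[1]] - 0.5 - cv[1])^2
    ay <- (rng[[2]] - 0.5 - cv[2])^2
    az <- (rng[[3]] - 0.5 - cv[3])^2
    inside <- outer(outer(ax, ay, "+"), az, "+") <= (r / h)^2
    occ[rng[[1]], rng[[2]], rng[[3]]] <-
      occ[rng[[1]], rng[[2]], rng[[3]]] | inside
  }
  if (probe > 0) {
    offs <- .ballOffsets(probe / h, includeCenter = FALSE)
    if (nrow(offs) > 0) {
      eroded <- occ
      for (i in seq_len(nrow(offs)))
        eroded <- eroded & .shiftOcc(occ, offs[i, ])
      occ <- eroded
    }
  }
  if (!any(occ)) stop("empty occupancy: no voxel survived voxelization")
  occ <- .largestComponent(occ)
  new("VoxelGrid", origin = lo, h = h, occupancy = occ,
      sourceId = atoms@sourceId)
}

# keep the largest 26-connected component of a logical lattice
.largestComponent <- function(occ) {
  e <- .voxelEdgeList(occ)
  nv <- length(e$nodes)
  if (nv == 0) return(occ)
  g <- igraph::make_graph(rbind(e$from, e$to), n = nv, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no <= 1) return(occ)
  keep <- which.max(comp$csize)
  out <- array(FALSE, dim(occ))
  out[e$nodes[comp$membership == keep]] <- TRUE
  out
}

# 26-neighbor edge list over occupied voxels; node ids index e$nodes
.voxelEdgeList <- function(occ, h = 1) {
  d <- dim(occ)
  nodes <- which(occ)
  rank <- integer(length(occ))
  rank[nodes] <- seq_along(nodes)
  offs <- .halfOffsets26()
  from <- to <- integer(0)
  w <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    both <- occ & .shiftOcc(occ, o)
    a <- which(both)
    if (length(a) == 0) next
    b <- a + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    from <- c(from, rank[a])
    to <- c(to, rank[b])
    w <- c(w, rep(h * sqrt(sum(o^2)), length(a)))
  }
  list(nodes = nodes, from = from, to = to, weight = w)
}

#' Extract the boundary voxels of a grid
#'
#' Returns exactly the occupied voxels with at least one unoccupied
#' 6-neighbor; positions beyond the lattice boundary count as unoccupied.
#'
#' @param grid a [VoxelGrid-class].
#' @return a [SurfaceVoxels-class].
#' @export
extractSurface <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  occ <- grid@occupancy
  interior <- occ
  for (i in seq_len(6)) {
    interior <- interior & .shiftOcc(occ, .offsets6()[i, ])
  }
  surf <- occ & !interior
  idx <- .arrayIndex(dim(occ), which(surf))
  new("SurfaceVoxels", indices = idx, grid = grid)
}

#' Write / read a voxel grid
#'
#' The grid container is a plain-text format: a header carrying origin,
#' resolution and lattice shape, followed by the run-length-encoded
#' linearised occupancy (column-major). [writeVoxelList()] additionally
#' exports one `x y z` lattice coordinate per occupied voxel for
#' interoperability.
#'
#' @param grid a [VoxelGrid-class].
#' @param path output (input) file path.
#' @return `readGrid` returns a [VoxelGrid-class]; the writers return
#'   `path` invisibly.
#' @export
writeGrid <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  occ <- as.vector(grid@occupancy)
  r <- rle(occ)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "IDSSVOX 1",
    paste("source", grid@sourceId),
    paste("origin", paste(sprintf("%.17g", grid@origin), collapse = " ")),
    paste("h", sprintf("%.17g", grid@h)),
    paste("shape", paste(dim(grid@occupancy), collapse = " ")),
    paste("rle", paste(ifelse(r$values, "1", "0"), r$lengths,
                       sep = ":", collapse = " "))
  ), con)
  invisible(path)
}

#' @rdname writeGrid
#' @export
readGrid <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "IDSSVOX")) stop("not a grid container file")
  field <- function(key) sub(paste0("^", key, " "), "",
                             grep(paste0("^", key, " "), ln, value = TRUE)[1])
  origin <- as.numeric(strsplit(trimws(field("origin")), "\\s+")[[1]])
  h <- as.numeric(field("h"))
  shp <- as.integer(strsplit(trimws(field("shape")), "\\s+")[[1]])
  runs <- strsplit(strsplit(trimws(field("rle")), "\\s+")[[1]], ":")
  vals <- vapply(runs, function(x) x[1] == "1", logical(1))
  lens <- vapply(runs, function(x) as.integer(x[2]), integer(1))
  occ <- array(inverse.rle(list(values = vals, lengths = lens)), shp)
  new("VoxelGrid", origin = origin, h = h, occupancy = occ,
      sourceId = field("source"))
}

#' @rdname writeGrid
#' @export
writeVoxelList <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  idx <- .arrayIndex(dim(grid@occupancy), which(grid@occupancy))
  utils::write.table(idx, path, row.names = FALSE, col.names = c("x", "y", "z"),
                     quote = FALSE)
  invisible(path)
}
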