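# 2D/3D navigation maps: classical MDS over the pairwise descriptor
# distance matrix, with deterministic class coloring and CSV/JSON export.

#' Pairwise descriptor distance matrix of an index
#'
#' `d[i, j] = 1 - similarity(i, j)`: symmetric, zero diagonal, entries in
#' \[0, 1\]. This is the dissimilarity the navigation map embeds.
#'
#' @param index a [ShapeIndex-class].
#' @param method descriptor method.
#' @return n x n numeric matrix with ids as dimnames.
#' @export
distanceMatrix <- function(index, method = "IDSS") {
  stopifnot(is(index, "ShapeIndex"))
  n <- length(index@ids)
  D <- matrix(0, n, n, dimnames = list(index@ids, index@ids))
  for (i in seq_len(n)) {
    di <- .indexDescriptor(index, i, method)
    for (j in seq_len(n)) {
      if (j <= i) next
      s <- similarity(di, .indexDescriptor(index, j, method))$value
      D[i, j] <- D[j, i] <- 1 - s
    }
  }
  D
}

#' Classical multidimensional scaling embedding
#'
#' Torgerson MDS: double-center `-1/2 * J D^2 J`, take the top-`d`
#' eigenpairs with non-negative eigenvalues (via [stats::cmdscale()]), and
#' report coordinates whose pairwise Euclidean distances approximate `D`.
#' The result is deterministic; each axis's sign is fixed so that its
#' largest-magnitude coordinate is positive. If fewer than `d` positive
#' eigenvalues exist, the missing axes are zero-padded with a warning.
#' Stress is the normalised residual
#' \eqn{\sqrt{\sum_{i<j}(\hat d_{ij}-d_{ij})^2 / \sum_{i<j} d_{ij}^2}}.
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @param d embedding dimension, 2 or 3.
#' @param ids optional molecule ids (default from `rownames(D)`).
#' @param groups optional group labels for coloring (default: each its own).
#' @return a [ShapeEmbedding-class].
#' @export
mdsEmbed <- function(D, d = 2L, ids = rownames(D), groups = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (!d %in% c(2L, 3L)) stop("embedding dimension must be 2 or 3")
  n <- nrow(D)
  if (is.null(ids)) ids <- sprintf("item%03d", seq_len(n))
  if (is.null(groups)) groups <- ids
  fit <- suppressWarnings(stats::cmdscale(D, k = min(d, n - 1), eig = TRUE))
  X <- fit$points
  if (is.null(X) || ncol(X) < d) {
    warning("fewer than ", d, " positive eigenvalues; padding with zero axes")
    X <- cbind(X, matrix(0, n, d - ncol(X)))
  }
  X <- X[, seq_len(d), drop = FALSE]
  for (k in seq_len(d)) {           # sign fix: largest |coord| positive
    i <- which.max(abs(X[, k]))
    if (X[i, k] < 0) X[, k] <- -X[, k]
  }
  dimnames(X) <- list(ids, c("x", "y", "z")[seq_len(d)])
  dhat <- as.matrix(stats::dist(X))
  ut <- upper.tri(D)
  denom <- sum(D[ut]^2)
  stress <- if (denom > 0) sqrt(sum((dhat[ut] - D[ut])^2) / denom) else 0
  new("ShapeEmbedding", coords = X, ids = as.character(ids),
      groups = as.character(groups), colors = .groupColors(groups),
      stress = stress)
}

# deterministic palette: one color per group, in order of first appearance
.groupColors <- function(groups) {
  g <- unique(groups)
  pal <- grDevices::hcl.colors(max(length(g), 2L), palette = "Dark 3")
  pal[match(groups, g)]
}

#' Export a navigation map
#'
#' Writes `<prefix>.csv` (id, group, x, y\[, z\], color) and
#' `<prefix>.json` carrying the same records plus the stress, so a JSON
#' round-trip recovers the coordinates bit-exactly.
#'
#' @param embedding a [ShapeEmbedding-class].
#' @param prefix output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
exportNavigation <- function(embedding, prefix) {
  stopifnot(is(embedding, "ShapeEmbedding"))
  df <- data.frame(id = embedding@ids, group = embedding@groups,
                   embedding@coords, color = embedding@colors,
                   stringsAsFactors = FALSE, row.names = NULL)
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dimension = ncol(embedding@coords), stress = embedding@stress,
         records = df),
    js, auto_unbox = TRUE, digits = I(17), dataframe = "rows")
  invisible(c(csv, js))
}
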