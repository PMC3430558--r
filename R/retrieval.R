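# L1 similarity scoring, descriptor database, ranked retrieval and the
# group-averaged precision-recall / AUC evaluation protocol.

#' L1 similarity between two descriptors
#'
#' The Minkowski L1 distance between two probability densities lies in
#' \[0, 2\]; the similarity score is the affine map `s = 1 - L1/2`, giving
#' 1 for identical descriptors and 0 for densities with disjoint support.
#' For the (L2-normalised, non-PDF) SHD the same map is applied and clamped
#' at 0. Both descriptors must share method, bin count and normalisation
#' mode.
#'
#' @param a,b [ShapeDescriptor-class] objects of the same method/B/mode.
#' @return list with `value` (similarity in \[0, 1\]) and `l1` (the
#'   underlying L1 distance).
#' @export
similarity <- function(a, b) {
  stopifnot(is(a, "ShapeDescriptor"), is(b, "ShapeDescriptor"))
  if (a@method != b@method) stop("descriptor methods differ")
  if (a@B != b@B) stop("descriptor bin counts differ")
  if (a@mode != b@mode) stop("descriptor normalisation modes differ")
  l1 <- sum(abs(a@bins - b@bins))
  list(value = max(0, 1 - l1 / 2), l1 = l1)
}

#' Build a searchable descriptor index
#'
#' @param ids unique molecule ids.
#' @param groups conformational group label per molecule (used only by the
#'   evaluation; pass `ids` themselves if no grouping is known).
#' @param descriptors list (parallel to `ids`) of named lists of
#'   [ShapeDescriptor-class] objects keyed by method.
#' @return a [ShapeIndex-class].
#' @export
buildIndex <- function(ids, groups, descriptors) {
  if (length(ids) < 2) stop("an index needs at least 2 records")
  if (anyDuplicated(ids)) stop("duplicate molecule id in index")
  new("ShapeIndex", ids = as.character(ids), groups = as.character(groups),
      descriptors = descriptors)
}

.indexDescriptor <- function(index, i, method) {
  d <- index@descriptors[[i]][[method]]
  if (is.null(d)) stop("record '", index@ids[i], "' lacks a ", method,
                       " descriptor")
  d
}

#' Ranked retrieval against an index
#'
#' Scores the probe descriptor against every record of matching method and
#' returns the top `k` by descending similarity; ties are broken by
#' lexicographic id; a record whose id equals the probe's `sourceId` (a
#' database self-match) is excluded.
#'
#' @param index a [ShapeIndex-class].
#' @param probe a [ShapeDescriptor-class].
#' @param k number of hits (k >= 1; capped at the database size).
#' @return data.frame with columns `id`, `group`, `similarity`, `l1`.
#' @export
queryIndex <- function(index, probe, k = 10L) {
  stopifnot(is(index, "ShapeIndex"), is(probe, "ShapeDescriptor"))
  if (k < 1) stop("k must be >= 1")
  keep <- which(index@ids != probe@sourceId)
  sims <- vapply(keep, function(i)
    similarity(.indexDescriptor(index, i, probe@method), probe)$value,
    numeric(1))
  l1s <- 2 * (1 - sims)
  ord <- order(-sims, index@ids[keep])
  top <- head(ord, k)
  data.frame(id = index@ids[keep][top], group = index@groups[keep][top],
             similarity = sims[top], l1 = l1s[top],
             stringsAsFactors = FALSE)
}

#' Group-averaged precision-recall evaluation
#'
#' The retrieval protocol: every molecule belonging to a group with >= 2
#' members queries the database (self excluded); the other members of its
#' group are the relevant items. Precision is recorded at each relevant
#' retrieval (recall levels `j / R`, `R` = group size - 1), linearly
#' interpolated onto a fixed recall grid, averaged over the queries of each
#' group, and then averaged across groups. Groups with a single member are
#' excluded (with a warning) but remain in the database as distractors.
#'
#' @param index a [ShapeIndex-class] with group labels.
#' @param method descriptor method to evaluate.
#' @param recallGrid increasing recall levels (default `seq(0.05, 1, 0.05)`).
#' @return a [PRCurve-class] (overall curve, per-group curves, AUC).
#' @export
precisionRecall <- function(index, method = "IDSS",
                            recallGrid = seq(0.05, 1, by = 0.05)) {
  stopifnot(is(index, "ShapeIndex"))
  groups <- index@groups
  tab <- table(groups)
  evalGroups <- names(tab)[tab >= 2]
  if (length(evalGroups) == 0) stop("no group has >= 2 members")
  if (any(tab < 2))
    warning("excluding ", sum(tab < 2), " singleton group(s) from evaluation")
  n <- length(index@ids)
  sims <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    di <- .indexDescriptor(index, i, method)
    for (j in seq_len(n)) {
      if (j < i) { sims[i, j] <- sims[j, i]; next }
      sims[i, j] <- similarity(di, .indexDescriptor(index, j, method))$value
    }
  }
  perGroup <- list()
  for (g in evalGroups) {
    members <- which(groups == g)
    curves <- matrix(NA_real_, length(members), length(recallGrid))
    for (qi in seq_along(members)) {
      q <- members[qi]
      others <- setdiff(seq_len(n), q)
      ord <- others[order(-sims[q, others], index@ids[others])]
      rel <- groups[ord] == g
      R <- sum(rel)
      ranks <- which(rel)
      prec <- seq_len(R) / ranks
      rec <- seq_len(R) / R
      curves[qi, ] <- stats::approx(c(0, rec), c(prec[1], prec),
                                    xout = recallGrid, rule = 2)$y
    }
    perGroup[[g]] <- colMeans(curves)
  }
  precision <- colMeans(do.call(rbind, perGroup))
  curve <- new("PRCurve", recall = recallGrid, precision = precision,
               auc = 0, perGroup = perGroup)
  curve@auc <- prAUC(curve)
  curve
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integral of precision over recall in \[0, 1\], prepending
#' the curve's first precision value at recall 0 (constant extension to the
#' left of the first grid point).
#'
#' @param curve a [PRCurve-class].
#' @return AUC in \[0, 1\].
#' @export
prAUC <- function(curve) {
  stopifnot(is(curve, "PRCurve"))
  r <- curve@recall
  p <- curve@precision
  if (r[1] > 0) { r <- c(0, r); p <- c(p[1], p) }
  pracma::trapz(r, p)
}

#' Save / load an index as JSON lines
#'
#' One JSON record per molecule (`id`, `group`, descriptors keyed by
#' method), written at full double precision so that a round-trip restores
#' every descriptor bit-exactly.
#'
#' @param index a [ShapeIndex-class].
#' @param path file path.
#' @return `loadIndex` returns a [ShapeIndex-class]; the writer returns
#'   `path` invisibly.
#' @export
saveIndex <- function(index, path) {
  stopifnot(is(index, "ShapeIndex"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(index@ids)) {
    descs <- lapply(index@descriptors[[i]], function(d)
      list(method = d@method, B = d@B, mode = d@mode, d_max = d@dMax,
           bins = d@bins))
    rec <- list(id = index@ids[i], group = index@groups[i],
                descriptors = descs)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  lines <- readLines(path)
  ids <- character(0); groups <- character(0); descriptors <- list()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    ids <- c(ids, rec$id)
    groups <- c(groups, rec$group)
    ds <- lapply(rec$descriptors, function(d)
      new("ShapeDescriptor", method = d$method, bins = as.numeric(d$bins),
          B = as.integer(d$B), mode = d$mode,
          dMax = if (is.null(d$d_max)) NA_real_ else as.numeric(d$d_max),
          sourceId = rec$id))
    descriptors[[length(descriptors) + 1L]] <- ds
  }
  buildIndex(ids, groups, descriptors)
}
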