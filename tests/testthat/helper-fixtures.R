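# Fixtures and independent oracles used across the test files.

# VoxelGrid from a logical array (origin 0, h = 1)
gridFromArray <- function(occ, id = "fixture") {
  new("VoxelGrid", origin = c(0, 0, 0), h = 1,
      occupancy = occ, sourceId = id)
}

# solid a x b x c block embedded in a (a+2m) x (b+2m) x (c+2m) empty margin
blockGrid <- function(a, b, c, margin = 1, id = "block") {
  occ <- array(FALSE, c(a, b, c) + 2 * margin)
  occ[margin + seq_len(a), margin + seq_len(b), margin + seq_len(c)] <- TRUE
  gridFromArray(occ, id)
}

# minimal PDB writer: one residue per atom, fixed-width columns
writeMiniPDB <- function(path, elements, xyz, chain = "A",
                         resid = "ALA", type = "ATOM") {
  n <- length(elements)
  type <- rep_len(type, n)
  resid <- rep_len(resid, n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type[i], i, substr(elements[i], 1, 2), resid[i], chain, i,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0, elements[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# independent Bellman-Ford all-sources oracle over the 26-neighborhood of a
# logical lattice; edge detection by brute-force center-distance scan
bfOracle <- function(occ, h = 1) {
  coords <- which(occ, arr.ind = TRUE)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  adj <- which(D > 0 & D <= sqrt(3) + 1e-9, arr.ind = TRUE)
  from <- adj[, 1]; to <- adj[, 2]
  w <- D[adj] * h
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dv <- rep(Inf, n)
    dv[s] <- 0
    for (iter in seq_len(n)) {
      cand <- dv[from] + w
      upd <- tapply(cand, to, min)
      nv <- dv
      ii <- as.integer(names(upd))
      nv[ii] <- pmin(nv[ii], upd)
      if (all(nv >= dv - 1e-12)) { dv <- pmin(dv, nv); break }
      dv <- pmin(dv, nv)
    }
    out[s, ] <- dv
  }
  out
}

# random occupancy pattern on a k^3 lattice, reduced to its largest
# 26-connected component by an independent flood fill
randomConnectedPattern <- function(seed, k = 3, p = 0.6) {
  set.seed(seed)
  occ <- array(runif(k^3) < p, c(k, k, k))
  if (!any(occ)) { occ[sample(k^3, 1)] <- TRUE }
  coords <- which(occ, arr.ind = TRUE)
  n <- nrow(coords)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      dd <- abs(sweep(coords, 2, coords[v, ]))
      nb <- which(comp == 0 & apply(dd, 1, max) <= 1)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  keep <- which(comp == which.max(tabulate(comp)))
  out <- array(FALSE, c(k, k, k))
  out[coords[keep, , drop = FALSE]] <- TRUE
  out
}

# minimum pairwise Euclidean separation of a point set (rows)
minSeparation <- function(P) {
  D <- as.matrix(stats::dist(P))
  min(D[upper.tri(D)])
}
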