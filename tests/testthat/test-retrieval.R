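# Similarity scoring, indexing, ranked retrieval and the precision-recall
# protocol.

pdfDescriptor <- function(bins, id, method = "IDSS", mode = "per_shape_max") {
  new("ShapeDescriptor", method = method, bins = bins / sum(bins),
      B = length(bins), mode = mode, dMax = 10, sourceId = id)
}

test_that("similarity is the affine map of the L1 distance of PDFs", {
  a <- pdfDescriptor(c(1, 1, 2, 0), "a")
  s <- similarity(a, a)
  expect_equal(s$value, 1.0)
  expect_equal(s$l1, 0.0)
  b <- pdfDescriptor(c(0, 0, 0, 1), "b")
  c_ <- pdfDescriptor(c(1, 1, 0, 0), "c")
  s2 <- similarity(b, c_)
  expect_equal(s2$value, 0.0)   # disjoint support
  expect_equal(s2$l1, 2.0)
  expect_equal(similarity(a, b)$l1, similarity(b, a)$l1)  # symmetric
  expect_error(similarity(a, pdfDescriptor(c(1, 1), "d")), "bin counts")
  expect_error(similarity(a, pdfDescriptor(c(1, 1, 1, 1), "e", "D2")),
               "methods differ")
  expect_error(
    similarity(a, pdfDescriptor(c(1, 1, 1, 1), "f", mode = "fixed_range")),
    "modes")
})

test_that("index construction validates and round-trips", {
  d1 <- pdfDescriptor(c(1, 0, 0, 0), "m1")
  d2 <- pdfDescriptor(c(0, 1, 0, 0), "m2")
  idx <- buildIndex(c("m1", "m2"), c("g1", "g1"),
                    list(list(IDSS = d1), list(IDSS = d2)))
  expect_length(indexIds(idx), 2)
  expect_error(buildIndex(c("m1", "m1"), c("g1", "g1"),
                          list(list(IDSS = d1), list(IDSS = d2))),
               "duplicate")
  f <- tempfile(fileext = ".jsonl")
  saveIndex(idx, f)
  idx2 <- loadIndex(f)
  expect_identical(descriptorBins(idx2@descriptors[[1]]$IDSS),
                   descriptorBins(d1))
  expect_identical(indexGroups(idx2), indexGroups(idx))
})

test_that("queries rank by similarity with deterministic tie-breaking", {
  descs <- list(
    m1 = c(8, 1, 1, 0), m2 = c(1, 8, 1, 0), m3 = c(0, 1, 8, 1),
    m4 = c(8, 1, 1, 0)  # identical to m1: tie broken by id
  )
  idx <- buildIndex(names(descs), names(descs),
                    lapply(names(descs), function(i)
                      list(IDSS = pdfDescriptor(descs[[i]], i))))
  probe <- pdfDescriptor(c(8, 1, 1, 0), "probe")
  hits <- queryIndex(idx, probe, k = 2)
  expect_equal(hits$id, c("m1", "m4"))
  expect_equal(hits$similarity[1], 1.0)
  # k beyond the database size returns the full ranking
  expect_equal(nrow(queryIndex(idx, probe, k = 99)), 4)
  # self-match excluded when the probe is a database member
  probeSelf <- pdfDescriptor(descs$m1, "m1")
  expect_false("m1" %in% queryIndex(idx, probeSelf, k = 99)$id)
  expect_error(queryIndex(idx, probe, k = 0), "k must be")
})

test_that("a bent-rod probe retrieves rods ahead of spheres under IDSS", {
  rods <- lapply(1:4, function(k)
    makeSyntheticShape("bent_rod", length = 36, radius = 3,
                       angle = c(0, 25, 50, 75)[k],
                       sourceId = paste0("rod", k)))
  sphs <- lapply(1:4, function(k)
    makeSyntheticShape("sphere", radius = 5 + 2 * k,
                       sourceId = paste0("sph", k)))
  all_ <- c(rods, sphs)
  descs <- lapply(seq_along(all_), function(k)
    list(IDSS = describeGrid(all_[[k]], "IDSS", seed = 40 + k)$IDSS))
  idx <- buildIndex(sapply(all_, sourceId),
                    c(rep("rod", 4), rep("sph", 4)), descs)
  probe <- describeGrid(
    makeSyntheticShape("bent_rod", length = 36, radius = 3, angle = 60,
                       sourceId = "probe"), "IDSS", seed = 99)$IDSS
  hits <- queryIndex(idx, probe, k = 8)
  expect_equal(hits$group[1:4], rep("rod", 4))
})

test_that("perfect retrieval produces the horizontal precision-1 line", {
  bins <- list(g1 = c(4, 1, 0, 0), g2 = c(0, 0, 1, 4))
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  grp <- c("g1", "g1", "g1", "g2", "g2", "g2")
  descs <- lapply(seq_along(ids), function(i)
    list(IDSS = pdfDescriptor(bins[[grp[i]]], ids[i])))
  idx <- buildIndex(ids, grp, descs)
  pr <- precisionRecall(idx)
  expect_true(all(pr@precision == 1.0))
  expect_equal(pr@auc, 1.0)
})

test_that("random descriptors yield chance-level precision", {
  g <- 6  # two groups of six
  set.seed(2024)
  prec <- replicate(20, {
    descs <- lapply(1:(2 * g), function(i)
      list(IDSS = pdfDescriptor(runif(16), paste0("m", i))))
    idx <- buildIndex(paste0("m", 1:(2 * g)),
                      rep(c("x", "y"), each = g), descs)
    mean(precisionRecall(idx)@precision)
  })
  # independent null-model oracle: the same protocol applied directly to
  # random rankings (5 relevant among 11 retrieved), without descriptors
  grid <- seq(0.05, 1, by = 0.05)
  null <- replicate(2000, {
    ranks <- sort(sample.int(2 * g - 1, g - 1))
    p <- seq_len(g - 1) / ranks
    r <- seq_len(g - 1) / (g - 1)
    mean(stats::approx(c(0, r), c(p[1], p), xout = grid, rule = 2)$y)
  })
  expect_lt(abs(mean(prec) - mean(null)), 0.05)
})

test_that("precision-recall output respects its invariants", {
  set.seed(33)
  descs <- lapply(1:9, function(i)
    list(IDSS = pdfDescriptor(runif(8), paste0("m", i))))
  idx <- buildIndex(paste0("m", 1:9),
                    c("a", "a", "a", "b", "b", "b", "c", "c", "lone")[1:9],
                    descs)
  expect_warning(pr <- precisionRecall(idx), "singleton")
  expect_true(all(diff(pr@recall) > 0))
  expect_true(all(pr@precision >= 0 & pr@precision <= 1))
  expect_named(pr@perGroup, c("a", "b", "c"))
})

test_that("AUC integrates the trapezoid and honors known curves", {
  mk <- function(r, p) new("PRCurve", recall = r, precision = p, auc = 0,
                           perGroup = list())
  expect_equal(prAUC(mk(seq(0.05, 1, 0.05), rep(1, 20))), 1.0)
  expect_equal(prAUC(mk(seq(0.05, 1, 0.05), rep(0.5, 20))), 0.5)
  expect_equal(prAUC(mk(c(0.5, 1), c(1, 0))), 0.75)  # hand trapezoid
})

test_that("adding an unrelated record never reorders existing hits", {
  set.seed(5)
  descs <- lapply(1:6, function(i)
    list(IDSS = pdfDescriptor(runif(12), paste0("m", i))))
  idx1 <- buildIndex(paste0("m", 1:6), paste0("m", 1:6), descs)
  probe <- pdfDescriptor(runif(12), "probe")
  r1 <- queryIndex(idx1, probe, k = 6)
  descs2 <- c(descs, list(list(IDSS = pdfDescriptor(runif(12), "extra"))))
  idx2 <- buildIndex(c(paste0("m", 1:6), "extra"),
                     c(paste0("m", 1:6), "extra"), descs2)
  r2 <- queryIndex(idx2, probe, k = 7)
  expect_equal(r2$id[r2$id != "extra"], r1$id)
})
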