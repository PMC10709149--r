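grAt <- function(pos, strand = "+", chrom = "chr1")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L,
                                                 width = 1), strand = strand)

test_that("nearest interval lookup honors the tie rule and matches a linear scan", {
  iv <- grAt(c(100, 500))
  nn <- nearestInterval("chr1", 120, iv)
  expect_identical(nn$interval, 1L)
  expect_equal(nn$distance, 20)
  ## equidistant query resolves toward the lower coordinate
  expect_identical(nearestInterval("chr1", 300, iv)$interval, 1L)
  ## missing chromosome signals not-found
  expect_true(is.na(nearestInterval("chr9", 300, iv)$interval))
  set.seed(23)
  iv2 <- grAt(sort(sample(0:20000, 100)))
  q <- sample(0:20000, 1000, replace = TRUE)
  got <- nearestInterval("chr1", q, iv2)$interval
  expect_identical(got, oracleNearest("chr1", q, iv2))
})

test_that("window filtering keeps calls within half the window of a midpoint", {
  iv <- grAt(1000)
  df <- data.frame(read_id = c("a", "b", "c"), mate = 1L, chrom = "chr1",
                   pos = c(1049L, 1051L, 10000L), context = "GCH",
                   state = "methylated", source = "genomic")
  f <- filterCallsByWindow(df, iv, window = 100)
  ## 49 bp away retained, 51 bp dropped, distant read gone entirely
  expect_identical(f$read_id, "a")
  expect_equal(f$anchor_dist, 49)
})

test_that("anchoring + filtering + pairing equals the exhaustive reference", {
  set.seed(33)
  for (rep in 1:3) {
    anchorsA <- grAt(sort(sample(seq(0, 9000, by = 120), 40)))
    anchorsB <- grAt(sort(sample(seq(150, 9900, by = 130), 40)))
    calls <- randomCallTable(800, maxPos = 10000, nReads = 150)
    got <- pairObservations(calls, anchorsA, anchorsB, window = 100,
                            minSep = 0, maxSep = Inf, context = "GCH")
    got <- got[order(got$pair_id), , drop = FALSE]
    want <- oraclePairPath(calls, anchorsA, anchorsB, window = 100)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
      next
    }
    expect_identical(got$pair_id, want$pair_id)
    expect_identical(got$anchorA, want$anchorA)
    expect_identical(got$anchorB, want$anchorB)
    expect_identical(got$n_callsA, want$n_callsA)
    expect_identical(got$n_callsB, want$n_callsB)
    expect_equal(got$meanA, want$meanA)
    expect_equal(got$meanB, want$meanB)
    expect_equal(got$separation, want$separation)
  }
})

test_that("separation bounds and convergent orientation are enforced", {
  ## two anchor pairs: one convergent (+ then -) 2 kb apart, one
  ## non-convergent 3 kb apart
  anchorsA <- grAt(c(1000, 6000), strand = c("+", "-"))
  anchorsB <- grAt(c(3000, 9000), strand = c("-", "-"))
  mk <- function(rid, p1, p2) data.frame(
    read_id = rid, mate = c(1L, 2L), chrom = "chr1", pos = c(p1, p2),
    context = "GCH", state = "methylated", source = "genomic")
  calls <- rbind(mk("r1", 1000L, 3000L), mk("r2", 6000L, 9000L))
  all <- pairObservations(calls, anchorsA, anchorsB, window = 100,
                          minSep = 1000)
  expect_identical(sort(all$pair_id), c("r1", "r2"))
  conv <- pairObservations(calls, anchorsA, anchorsB, window = 100,
                           minSep = 1000, orientation = "convergent")
  expect_identical(conv$pair_id, "r1")
  ## minimum separation excludes the closer pair only
  far <- pairObservations(calls, anchorsA, anchorsB, window = 100,
                          minSep = 2500)
  expect_identical(far$pair_id, "r2")
  none <- suppressWarnings(
    pairObservations(calls, anchorsA, anchorsB, window = 100,
                     minSep = 10000))
  expect_identical(nrow(none), 0L)
})

test_that("k-means recovers separated blobs and is deterministic under seed", {
  set.seed(41)
  blob <- function(cx, cy, n = 40)
    data.frame(meanA = pmin(pmax(cx + rnorm(n, 0, 0.04), 0), 1),
               meanB = pmin(pmax(cy + rnorm(n, 0, 0.04), 0), 1))
  obs <- rbind(blob(1, 1), blob(1, 0), blob(0, 1), blob(0, 0))
  obs$n_callsA <- obs$n_callsB <- 5L
  cl <- clusterObservations(obs, k = 4, seed = 9)
  ## cluster 1 is the open/open blob; each blob uniform
  expect_identical(unique(cl$assignments[1:40]), 1L)
  expect_identical(length(unique(cl$assignments[41:80])), 1L)
  expect_identical(length(unique(cl$assignments[81:120])), 1L)
  expect_identical(unique(cl$assignments[121:160]), 4L)
  cl2 <- clusterObservations(obs, k = 4, seed = 9)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(clusterObservations(obs[1:3, ], k = 4), "fewer")
})

test_that("k-means beats random assignments on within-cluster sum of squares", {
  set.seed(43)
  obs <- data.frame(meanA = runif(60), meanB = runif(60))
  cl <- clusterObservations(obs, k = 4, seed = 2)
  m <- as.matrix(obs[, c("meanA", "meanB")])
  wss <- function(assign) sum(vapply(unique(assign), function(g) {
    sub <- m[assign == g, , drop = FALSE]
    sum(scale(sub, scale = FALSE)^2)
  }, numeric(1)))
  got <- wss(cl$assignments)
  rand <- replicate(1000, wss(sample(1:4, 60, replace = TRUE)))
  expect_true(all(got <= rand))
})

test_that("binarization applies the threshold and call floor", {
  obs <- data.frame(meanA = c(0.5, 0.0, 0.9), meanB = c(0.4, 0.6, 1.0),
                    n_callsA = c(3L, 1L, 0L), n_callsB = c(2L, 1L, 5L))
  b <- binarizeObservations(obs, minCalls = 1, threshold = 0.5)
  ## mean == threshold counts as open; zero-call mate excluded
  expect_identical(b$openA, c(TRUE, FALSE))
  expect_identical(b$openB, c(FALSE, TRUE))
  expect_identical(b$nExcluded, 1L)
})

test_that("dependence test reports the cross-product odds ratio", {
  mkStates <- function(tb) {
    a <- rep(c(TRUE, TRUE, FALSE, FALSE), times = as.vector(t(tb)))
    b <- rep(c(TRUE, FALSE, TRUE, FALSE), times = as.vector(t(tb)))
    list(a = a, b = b)
  }
  s <- mkStates(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  d <- dependenceTest(s$a, s$b)
  expect_equal(d$odds_ratio, 4)
  expect_equal(d$co_accessible_fraction, 100 * 20 / 60)
  ## independence table: OR 1, p 1
  s2 <- mkStates(matrix(c(25, 25, 25, 25), 2))
  d2 <- dependenceTest(s2$a, s2$b)
  expect_equal(d2$odds_ratio, 1)
  expect_equal(d2$p_value, 1)
  ## zero margin: OR undefined, p = 1
  d3 <- dependenceTest(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(is.na(d3$odds_ratio))
  expect_equal(d3$p_value, 1)
  ## zero cell (no zero margin): Haldane-Anscombe correction applies
  s4 <- mkStates(matrix(c(10, 5, 0, 10), 2, byrow = TRUE))
  d4 <- dependenceTest(s4$a, s4$b)
  expect_equal(d4$odds_ratio, (10.5 * 10.5) / (5.5 * 0.5))
})

test_that("swapping anchor sets transposes the table but fixes OR and p", {
  set.seed(51)
  anchorsA <- grAt(seq(500, 9500, by = 1000))
  anchorsB <- grAt(seq(900, 9900, by = 1000))
  calls <- randomCallTable(1500, maxPos = 10000, nReads = 300)
  r1 <- coAccessibility(calls, anchorsA, anchorsB, window = 200,
                        minSep = 0, k = 2, seed = 3, control = FALSE)
  r2 <- coAccessibility(calls, anchorsB, anchorsA, window = 200,
                        minSep = 0, k = 2, seed = 3, control = FALSE)
  expect_identical(unname(contingencyTable(r2)),
                   unname(t(contingencyTable(r1))))
  expect_equal(oddsRatio(r2), oddsRatio(r1))
  expect_equal(pValue(r2), pValue(r1))
})

test_that("co-accessible fraction is non-increasing in the threshold", {
  set.seed(52)
  obs <- data.frame(meanA = runif(200), meanB = runif(200),
                    n_callsA = 3L, n_callsB = 3L)
  fracs <- vapply(seq(0.1, 1, by = 0.1), function(th) {
    b <- binarizeObservations(obs, threshold = th)
    dependenceTest(b$openA, b$openB)$co_accessible_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("randomized control is seeded and matches anchored fraction under a null", {
  ## uniform openness: anchored and control fractions both ~ 100 p^2
  cfg <- simConfig(genomeLength = 3e5, nPairs = 3000L,
                   nAnchoredPairs = 3000L, p1 = 0.4, p2 = 0.4,
                   oddsRatio = 1, backgroundOpenProb = 0.4,
                   pMethGivenOpen = 1, pMethGivenClosed = 0,
                   conversionFailure = 0, seed = 13L,
                   tadBoundaries = c(1e5, 2e5), compartmentBin = 5e4,
                   anchorFeatures = data.frame(
                     chrom = "chr1",
                     pos = seq(2e4, 2.8e5, length.out = 10),
                     strand = rep(c("+", "-"), 5),
                     label = paste0(rep(c("A", "B"), 5),
                                    rep(1:5, each = 2))))
  sim <- simulateContactPairs(cfg)
  calls <- simulateReadMethCalls(cfg, sim$pairs, sim$truth)
  af <- cfg@anchorFeatures
  anchors <- GenomicRanges::GRanges(af$chrom,
    IRanges::IRanges(af$pos + 1, width = 1), strand = af$strand,
    label = af$label)
  aIdx <- grepl("^A", af$label)
  res <- coAccessibility(calls, anchors[aIdx], anchors[!aIdx],
                         window = 100, minSep = 1000, seed = 5,
                         control = TRUE)
  expect_false(is.null(res@control))
  expect_equal(res@coAccessibleFraction, 100 * 0.4^2, tolerance = 0.15)
  expect_equal(res@control@coAccessibleFraction, 100 * 0.4^2,
               tolerance = 0.25)
  ## determinism of the control under the seed
  ctrl2 <- randomizedControl(calls, anchors, window = 100, minSep = 1000,
                             nMatch = 100, seed = 5)
  ctrl3 <- randomizedControl(calls, anchors, window = 100, minSep = 1000,
                             nMatch = 100, seed = 5)
  expect_identical(ctrl2, ctrl3)
})

test_that("co-methylation runs the same machinery on the CpG channel", {
  ## fully methylated CpG baseline: a single cluster at (1, 1)
  cfg <- simConfig(genomeLength = 2e5, nPairs = 0L,
                   nAnchoredPairs = 400L, cpgMethBaseline = 1,
                   conversionFailure = 0, seed = 17L,
                   tadBoundaries = c(1e5), compartmentBin = 5e4)
  sim <- simulateContactPairs(cfg)
  calls <- simulateReadMethCalls(cfg, sim$pairs, sim$truth)
  af <- cfg@anchorFeatures
  anchors <- GenomicRanges::GRanges(af$chrom,
    IRanges::IRanges(af$pos + 1, width = 1), strand = af$strand)
  aIdx <- grepl("^A", af$label)
  res <- coMethylation(calls, anchors[aIdx], anchors[!aIdx],
                       window = 100, minSep = 1000, k = 1, seed = 2,
                       control = FALSE)
  expect_true(all(observations(res)$meanA == 1))
  expect_true(all(observations(res)$meanB == 1))
  expect_equal(res@coAccessibleFraction, 100)
})
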