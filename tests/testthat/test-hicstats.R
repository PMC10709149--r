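decayMat <- function(n, alpha = 1, depth = 100) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  depth * pmax(d, 1)^(-alpha)
}

test_that("contact binning matches a per-pair loop oracle", {
  df <- data.frame(read_id = "p1", chrom1 = "chr1", pos1 = 1000L,
                   strand1 = "+", chrom2 = "chr1", pos2 = 3000L,
                   strand2 = "-", fend1 = 1L, fend2 = 2L)
  m <- contactCounts(binContacts(ContactPairs(df), 1000,
                                 c(chr1 = 5000))$chr1)
  expect_equal(m[2, 4], 1); expect_equal(m[4, 2], 1)
  expect_equal(sum(m), 2)
  ## empty input gives a zero matrix
  m0 <- contactCounts(binContacts(ContactPairs(), 1000,
                                  c(chr1 = 5000))$chr1)
  expect_true(all(m0 == 0))
  ## random table vs loop oracle
  set.seed(61)
  n <- 400
  df2 <- data.frame(read_id = paste0("r", 1:n), chrom1 = "chr1",
                    pos1 = sample(0:49999, n, TRUE), strand1 = "+",
                    chrom2 = "chr1", pos2 = 0L, strand2 = "-",
                    fend1 = NA_integer_, fend2 = NA_integer_)
  df2$pos2 <- df2$pos1 + sample(0:20000, n, TRUE)
  got <- contactCounts(binContacts(ContactPairs(df2), 5000,
                                   c(chr1 = 80000))$chr1)
  want <- matrix(0, 16, 16)
  for (k in seq_len(n)) {
    i <- df2$pos1[k] %/% 5000 + 1; j <- df2$pos2[k] %/% 5000 + 1
    want[i, j] <- want[i, j] + 1
    if (i != j) want[j, i] <- want[j, i] + 1
  }
  expect_equal(got, want)
  ## matrix total = 2 * cis pairs - diagonal pairs
  nDiag <- sum(df2$pos1 %/% 5000 == df2$pos2 %/% 5000)
  expect_equal(sum(got), 2 * n - nDiag)
})

test_that("decay probabilities normalize and collapse to a single bin", {
  set.seed(62)
  df <- data.frame(read_id = paste0("r", 1:500), chrom1 = "chr1",
                   pos1 = sample(0:100000, 500, TRUE), strand1 = "+",
                   chrom2 = "chr1", pos2 = 0L, strand2 = "+",
                   fend1 = NA_integer_, fend2 = NA_integer_)
  df$pos2 <- df$pos1 + sample(1000:50000, 500, TRUE)
  d <- contactDecay(ContactPairs(df), minDist = 1000)
  expect_equal(sum(d$prob), 1)
  ## all pairs at one distance: all mass in one bin
  df2 <- df; df2$pos2 <- df2$pos1 + 5000L
  d2 <- contactDecay(ContactPairs(df2), nBins = 10, minDist = 1000)
  expect_equal(max(d2$prob), 1)
  expect_identical(sum(d2$count > 0), 1L)
  ## nothing above the floor errors
  df3 <- df; df3$pos2 <- df3$pos1 + 10L
  expect_error(contactDecay(ContactPairs(df3), minDist = 1000), "floor")
})

test_that("insulation is zero on uniform maps, peaks at block junctions, and is transpose-invariant", {
  ## uniform: observed rectangle equals expected rectangle everywhere
  u <- BinnedContactMatrix("chrU", 1000, matrix(10, 60, 60))
  tu <- insulationScore(u, flank = 5000)
  expect_true(all(abs(tu$score[is.finite(tu$score)]) < 1e-12))
  expect_identical(sum(is.finite(tu$score)), 60L - 2L * 5L)
  ## two-block map: maximum insulation at the junction
  m <- matrix(1, 40, 40)
  m[1:20, 1:20] <- 5; m[21:40, 21:40] <- 5
  b2 <- BinnedContactMatrix("chrB", 1000, m)
  tb <- insulationScore(b2, flank = 5000)
  ## the junction lies between bins 20 and 21: maximum on that plateau
  expect_true(which.max(tb$score) %in% c(20L, 21L))
  ## cross-check the rectangle sum at one bin on a small toy
  toy <- matrix(seq_len(100), 10, 10); toy <- toy + t(toy)
  x <- BinnedContactMatrix("chrT", 1000, toy)
  tt <- insulationScore(x, flank = 3000)
  e <- expectedCounts(x)
  i <- 5; f <- 3
  obs <- sum(toy[(i - f):(i - 1), (i + 1):(i + f)])
  dd <- 2:(2 * f); w <- f - abs(dd - (f + 1))
  expSum <- sum(w * e[dd + 1])
  expect_equal(tt$score[i], -log2((obs + 1) / (expSum + 1)))
  ## symmetry: the track of t(M) equals the track of M
  expect_equal(insulationScore(x, flank = 3000)$score,
               insulationScore(BinnedContactMatrix("chrT", 1000, t(toy)),
                               flank = 3000)$score)
  ## oversized flank warns and yields all-NaN
  expect_warning(allNa <- insulationScore(x, flank = 50000), "flank")
  expect_true(all(!is.finite(allNa$score)))
})

test_that("boundary calling finds spikes, rejects constants, and honors plateaus", {
  mkTrack <- function(score) data.frame(
    chrom = "chr1", start = (seq_along(score) - 1) * 1000,
    end = seq_along(score) * 1000, score = score)
  ## constant track: nothing exceeds its own upper quantile strictly
  expect_identical(nrow(callBoundaries(mkTrack(rep(1, 50)))), 0L)
  ## single spike
  sp <- rep(0, 50); sp[25] <- 3
  b <- callBoundaries(mkTrack(sp))
  expect_identical(b$start, 24000)
  ## plateau of equal maxima: lowest coordinate wins
  pl <- rep(0, 50); pl[25:26] <- 3
  bp <- callBoundaries(mkTrack(pl))
  expect_identical(bp$start, 24000)
})

test_that("rescaled TAD pileup recovers planted interior enrichment", {
  n <- 300
  base <- decayMat(n, alpha = 0.8, depth = 200)
  ## plant one TAD on bins 101..200 with interior boost 4
  boost <- matrix(1, n, n); boost[101:200, 101:200] <- 4
  x <- BinnedContactMatrix("chr1", 1000, base * boost)
  tad <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = 100001, end = 200000))
  ## obs = exp map first: all-zero grid
  x0 <- BinnedContactMatrix("chr1", 1000, base)
  g0 <- rescaledTadPileup(x0, tad)
  expect_true(all(abs(g0$grid) < 0.05))
  g <- rescaledTadPileup(x, tad)
  ## grid symmetric about its diagonal
  expect_equal(g$grid, t(g$grid), tolerance = 1e-12)
  ## central third carries ~log2(boost) above its flanks; expected-model
  ## absorption of the planted block means the contrast, not the absolute
  ## level, is diagnostic
  inner <- g$grid[40:61, 40:61]
  corner <- g$grid[1:20, 1:20]
  expect_gt(mean(inner) - mean(corner), 0.8 * log2(4) - 0.35)
  ## TADs whose 3L extension leaves the chromosome are skipped
  edgeTad <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = 1001, end = 150000))
  expect_error(rescaledTadPileup(x, edgeTad), "no usable TADs")
})

test_that("compartment eigenvector recovers planted labels and orients by a track", {
  set.seed(71)
  bl <- c(); while (length(bl) < 100)
    bl <- c(bl, rep(sample(c("A", "B"), 1), sample(3L:12L, 1)))
  bl <- bl[1:100]
  cb <- simulateCheckerboard(nBins = 100, labels = bl, contrast = 2,
                             depth = 200, noise = "poisson", seed = 3)
  ev <- compartmentEigenvector(cb$matrix)
  agree <- max(mean((ev$value >= 0) == (bl == "A"), na.rm = TRUE),
               mean((ev$value < 0) == (bl == "A"), na.rm = TRUE))
  expect_gte(agree, 0.95)
  expect_true(attr(ev, "reliable"))
  ## orientation by accessibility: A bins must end up positive
  acc <- ifelse(bl == "A", 0.7, 0.3)
  ev2 <- compartmentEigenvector(cb$matrix, orientTrack = acc)
  expect_gte(mean(ev2$value[bl == "A"] >= 0), 0.95)
  ## uniform map is degenerate: flagged unreliable
  u <- BinnedContactMatrix("chrU", 250000, matrix(7, 40, 40))
  evu <- compartmentEigenvector(u)
  expect_false(attr(evu, "reliable"))
})

test_that("compartment strength matches closed forms and its symmetries", {
  ## uniform map: exactly 1 under any labeling
  u <- BinnedContactMatrix("chrU", 250000, matrix(50, 100, 100))
  lab <- rep(c("A", "B"), 50)
  expect_equal(compartmentStrength(u, lab, minSep = 2.5e6), 1,
               tolerance = 1e-9)
  ## two-level map: same-label cells 2y, cross y; closed form from the
  ## same obs/exp machinery computed by hand
  y <- 40
  m2 <- ifelse(outer(lab, lab, "=="), 2, 1) * y
  x2 <- BinnedContactMatrix("chrT", 250000, m2)
  e <- expectedCounts(x2)
  idx <- which(upper.tri(m2), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  ok <- sep >= 10
  same <- lab[idx[ok, 1]] == lab[idx[ok, 2]]
  oe <- (m2[idx[ok, , drop = FALSE]] + 1) / (e[sep[ok] + 1] + 1)
  closedForm <- mean(oe[same]) / mean(oe[!same])
  expect_equal(compartmentStrength(x2, lab, minSep = 2.5e6), closedForm,
               tolerance = 1e-9)
  expect_equal(closedForm, 2, tolerance = 0.05)
  ## label swap invariance
  swapped <- ifelse(lab == "A", "B", "A")
  expect_equal(compartmentStrength(x2, swapped, minSep = 2.5e6),
               compartmentStrength(x2, lab, minSep = 2.5e6))
  ## depth invariance (up to the pseudocount) via scaling
  x2s <- BinnedContactMatrix("chrT", 250000, 3 * m2)
  expect_equal(compartmentStrength(x2s, lab, minSep = 2.5e6),
               compartmentStrength(x2, lab, minSep = 2.5e6),
               tolerance = 0.02)
})

test_that("aggregate pair enrichment is 1 on obs=exp and detects planted foci", {
  n <- 400
  base <- decayMat(n, alpha = 1, depth = 100)
  x0 <- BinnedContactMatrix("chr1", 5000, base)
  pairs0 <- data.frame(pos1 = seq(50, 300, by = 50) * 5000,
                       pos2 = seq(80, 330, by = 50) * 5000)
  ap0 <- aggregatePairEnrichment(x0, pairs0, window = 100000)
  expect_equal(ap0$ratio, 1, tolerance = 0.05)
  expect_true(all(abs(ap0$map) < 0.1))
  ## planted 3x3 focal enrichment recovers the boost
  set.seed(72)
  pairs <- data.frame(pos1 = sample(30:180, 50, TRUE) * 5000)
  pairs$pos2 <- pairs$pos1 + sample(40:150, 50, TRUE) * 5000
  m <- base
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$pos1[k] / 5000 + 1; j <- pairs$pos2[k] / 5000 + 1
    m[(i - 1):(i + 1), (j - 1):(j + 1)] <-
      m[(i - 1):(i + 1), (j - 1):(j + 1)] * 4
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  x <- BinnedContactMatrix("chr1", 5000, m)
  ap <- aggregatePairEnrichment(x, pairs, window = 100000)
  expect_gte(ap$ratio, 2)
  ## swapping anchor order transposes the mean map
  apSwap <- aggregatePairEnrichment(
    x, data.frame(pos1 = pairs$pos2, pos2 = pairs$pos1),
    window = 100000)
  expect_equal(apSwap$map, t(ap$map), tolerance = 1e-9)
  ## edge pairs are skipped and counted
  apEdge <- aggregatePairEnrichment(
    x, rbind(pairs, data.frame(pos1 = 0, pos2 = 100000)),
    window = 100000)
  expect_identical(apEdge$nSkipped, 1L)
})

test_that("per-pair scores are 0 on obs=exp, scale-invariant, and separate planted classes", {
  n <- 400
  base <- decayMat(n, alpha = 1, depth = 100)
  x0 <- BinnedContactMatrix("chr1", 5000, base)
  pairs0 <- data.frame(pos1 = seq(50, 300, by = 10) * 5000,
                       pos2 = seq(70, 320, by = 10) * 5000)
  s0 <- perPairScore(x0, pairs0, window = 10000)
  expect_true(all(abs(s0$score) < 0.05))
  ## global scaling cancels through the expected model (pseudocount aside)
  x0s <- BinnedContactMatrix("chr1", 5000, 10 * base)
  s0s <- perPairScore(x0s, pairs0, window = 10000)
  expect_equal(s0s$score, s0$score, tolerance = 0.05)
  ## two planted classes, enrichment 1x vs 4x, Wilcoxon separates them
  set.seed(73)
  mk <- function(boost, n50) {
    p <- data.frame(pos1 = sample(30:180, n50, TRUE) * 5000)
    p$pos2 <- p$pos1 + sample(40:150, n50, TRUE) * 5000
    list(pairs = p, boost = boost)
  }
  cls <- list(mk(1, 50), mk(4, 50))
  m <- base
  for (cl in cls) for (k in seq_len(nrow(cl$pairs))) {
    i <- cl$pairs$pos1[k] / 5000 + 1; j <- cl$pairs$pos2[k] / 5000 + 1
    m[i, j] <- m[i, j] * cl$boost; m[j, i] <- m[i, j]
  }
  mp <- matrix(stats::rpois(n * n, pmax(m, 0)), n, n)
  mp[lower.tri(mp)] <- t(mp)[lower.tri(mp)]
  x <- BinnedContactMatrix("chr1", 5000, mp)
  sA <- perPairScore(x, cls[[1]]$pairs, window = 10000)$score
  sB <- perPairScore(x, cls[[2]]$pairs, window = 10000)$score
  expect_lt(wilcox.test(sA, sB)$p.value, 0.01)
  expect_gt(median(sB, na.rm = TRUE), median(sA, na.rm = TRUE))
})

test_that("feature-gene association applies promoter, floor, TAD and tie rules", {
  tss <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(10000, 53000, 260000, 480000), width = 1),
    strand = c("+", "+", "+", "+"))
  names(tss) <- c("geneP", "geneNear", "geneFar", "geneOut")
  tads <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 300001), end = c(300000, 500000)))
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(7001, 49001, 700001), width = 1))
  scores <- function(chrom, pos1, pos2) {
    ## geneNear (4 kb away) would win on score were it not for the floor
    ifelse(abs(pos2 - pos1) < 5000, 50,
           ifelse(abs(pos2 - pos1) > 100000, 5, 1))
  }
  ## promoter window tightened below the floor so the 4 kb candidate
  ## exercises the minimal-distance rule rather than the promoter rule
  res <- associateFeaturesToGenes(feats, tss, tads, scores,
                                  promoterWindow = 2000)
  ## 3 kb from geneP under the default window: promoter rule
  resDefault <- associateFeaturesToGenes(feats[1], tss, tads, scores)
  expect_identical(resDefault$gene, "geneP")
  expect_identical(resDefault$mode, "promoter")
  ## distal feature at 49000: geneNear is 4 kb away, below the 5 kb
  ## floor, excluded despite its top score; geneFar (211 kb, same TAD)
  ## wins among the eligible; geneOut is outside the TAD
  expect_identical(res$gene[2], "geneFar")
  expect_identical(res$mode[2], "distal")
  ## feature outside any TAD stays unassigned
  expect_identical(res$mode[3], "unassigned")
  ## score tie resolves to the nearest candidate
  tss2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(100000, 200000), width = 1),
    strand = "+")
  names(tss2) <- c("g1", "g2")
  feat2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = 140001, width = 1))
  tie <- associateFeaturesToGenes(
    feat2, tss2, tads, function(chrom, pos1, pos2) rep(1, length(pos1)))
  expect_identical(tie$gene, "g1")
})

test_that("obs/exp statistics ignore global depth scaling", {
  set.seed(74)
  n <- 200
  m <- decayMat(n, alpha = 1, depth = 400)
  m[] <- stats::rpois(n * n, m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  x1 <- BinnedContactMatrix("chr1", 1000, m)
  x5 <- BinnedContactMatrix("chr1", 1000, 5 * m)
  t1 <- insulationScore(x1, flank = 10000)
  t5 <- insulationScore(x5, flank = 10000)
  fin <- is.finite(t1$score)
  expect_equal(t1$score[fin], t5$score[fin], tolerance = 0.05)
})
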