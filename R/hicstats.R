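## Contact-level statistics: decay curves, insulation and TAD boundary
## calling, rescaled TAD pileups, compartment eigenvector and strength,
## aggregate pairwise enrichment, per-pair scores and peak-to-gene
## association.

#' Bin cis contact pairs into a per-chromosome matrix
#'
#' @param pairs deduplicated \linkS4class{ContactPairs}.
#' @param binSize bin size in bp (> 0).
#' @param chromLengths named vector of chromosome lengths; chromosomes
#'   default to spanning their largest observed position.
#' @return named list of \linkS4class{BinnedContactMatrix}, one per
#'   chromosome with cis pairs.
#' @export
binContacts <- function(pairs, binSize, chromLengths = NULL) {
  if (binSize <= 0) stop("binSize must be > 0")
  df <- contactPairs(pairs)
  df <- df[df$chrom1 == df$chrom2, , drop = FALSE]
  chroms <- unique(df$chrom1)
  if (!is.null(chromLengths)) chroms <- union(chroms, names(chromLengths))
  out <- list()
  for (chr in chroms) {
    sub <- df[df$chrom1 == chr, , drop = FALSE]
    L <- if (!is.null(chromLengths) && chr %in% names(chromLengths))
      chromLengths[[chr]] else max(sub$pos2, 0) + 1
    n <- as.integer(ceiling(L / binSize))
    m <- matrix(0, n, n)
    if (nrow(sub)) {
      i <- pmin(floor(sub$pos1 / binSize) + 1L, n)
      j <- pmin(floor(sub$pos2 / binSize) + 1L, n)
      for (k in seq_along(i)) {
        m[i[k], j[k]] <- m[i[k], j[k]] + 1
        if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + 1
      }
    }
    out[[chr]] <- BinnedContactMatrix(chr, binSize, m, L)
  }
  out
}

#' Distance-stratified expected contact counts
#'
#' Per-diagonal mean contact count, constrained to decay monotonically
#' with distance by an isotonic (pool-adjacent-violators) fit. The fit
#' smooths sampling noise at sparse long-range diagonals while leaving
#' any exactly monotone input unchanged. This is the expected model
#' behind every observed/expected statistic in the package; it replaces
#' external kNN-based normalization engines with a transparent
#' distance-only model.
#'
#' @param x a \linkS4class{BinnedContactMatrix}.
#' @return numeric vector \code{e} of length nbins, \code{e[d + 1]} the
#'   expected count at bin distance d.
#' @export
expectedCounts <- function(x) {
  m <- contactCounts(x)
  n <- nrow(m)
  diagMean <- vapply(0:(n - 1), function(d)
    mean(m[cbind(seq_len(n - d), seq_len(n - d) + d)]), numeric(1))
  if (n <= 2) return(diagMean)
  ## monotone non-increasing over distance d >= 1; the main diagonal is
  ## kept as its own stratum
  iso <- isoreg(-diagMean[-1])
  pmax(c(diagMean[1], -iso$yf), 0)
}

## elementwise observed/expected with pseudocount
.oeMatrix <- function(x, expected = NULL, pseudocount = 1) {
  m <- contactCounts(x)
  if (is.null(expected)) expected <- expectedCounts(x)
  n <- nrow(m)
  ed <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
  (m + pseudocount) / (matrix(expected[ed], n, n) + pseudocount)
}

#' Contact probability as a function of genomic distance
#'
#' Cis-only decay curve over log-spaced distance bins: the fraction of
#' contacts per bin, and the per-bp density used for slope fitting.
#'
#' @param pairs a \linkS4class{ContactPairs}.
#' @param nBins number of log-spaced bins.
#' @param minDist distance floor in bp (default 1 kb).
#' @param maxDist optional ceiling; defaults to the largest separation.
#' @return data.frame with \code{binStart}, \code{binEnd}, \code{mid}
#'   (geometric), \code{count}, \code{prob} (sums to 1) and
#'   \code{density} (prob per bp).
#' @export
contactDecay <- function(pairs, nBins = 40L, minDist = 1000,
                         maxDist = NULL) {
  df <- contactPairs(pairs)
  s <- (df$pos2 - df$pos1)[df$chrom1 == df$chrom2]
  s <- s[s >= minDist]
  if (!length(s)) stop("no cis pairs above the distance floor")
  if (is.null(maxDist)) maxDist <- max(s) + 1
  s <- s[s < maxDist]
  edges <- exp(seq(log(minDist), log(maxDist), length.out = nBins + 1))
  b <- findInterval(s, edges, rightmost.closed = TRUE)
  cnt <- tabulate(b, nbins = nBins)
  width <- diff(edges)
  data.frame(binStart = edges[-length(edges)], binEnd = edges[-1],
             mid = sqrt(edges[-length(edges)] * edges[-1]),
             count = cnt, prob = cnt / sum(cnt),
             density = cnt / sum(cnt) / width)
}

#' Fit the log-log slope of a decay curve
#'
#' Linear regression of log10 contact density on log10 distance over the
#' requested range; for a power law P(s) ~ s^-alpha the slope estimates
#' -alpha.
#'
#' @param decay data.frame from \code{\link{contactDecay}}.
#' @param range distance range (bp) over which to fit.
#' @return slope (numeric scalar).
#' @export
fitDecaySlope <- function(decay, range = c(-Inf, Inf)) {
  sel <- decay$count > 0 & decay$mid >= range[1] & decay$mid <= range[2]
  if (sum(sel) < 3) stop("need at least 3 populated bins to fit")
  unname(coef(lm(log10(density) ~ log10(mid), data = decay[sel, ]))[2])
}

#' Insulation score track
#'
#' For every bin, the contacts crossing it are summed over the
#' upstream-flank x downstream-flank rectangle and normalized by the
#' expected-model sum over the same cells; the log2 ratio (pseudocount
#' 1) is sign-flipped so that TAD boundaries, which deplete crossing
#' contacts, appear as local maxima. Bins within one flank of the
#' chromosome edges are NaN.
#'
#' @param x a \linkS4class{BinnedContactMatrix} (typically at 1 kb).
#' @param flank flank size in bp (default 250 kb).
#' @param pseudocount added to observed and expected sums.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{score}.
#' @export
insulationScore <- function(x, flank = 250000, pseudocount = 1) {
  m <- contactCounts(x)
  n <- nrow(m)
  f <- as.integer(round(flank / binSize(x)))
  score <- rep(NaN, n)
  if (f < 1 || 2 * f >= n) {
    warning("flank too large for this chromosome; all-NaN track")
  } else {
    e <- expectedCounts(x)
    ## expected rectangle sum is position independent: distance d = a+b,
    ## a, b in 1..f, has f - |d - (f+1)| cells
    dd <- 2:(2 * f)
    w <- f - abs(dd - (f + 1))
    expSum <- sum(w * e[pmin(dd + 1L, length(e))])
    ## sum of m[r1..r2, c1..c2] via 2D cumulative sums
    S <- apply(m, 2, cumsum)
    S <- cbind(0, t(apply(S, 1, cumsum)))
    S <- rbind(0, S)
    rect <- function(r1, r2, c1, c2)
      S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
    for (i in (f + 1):(n - f)) {
      obs <- rect(i - f, i - 1, i + 1, i + f)
      score[i] <- -log2((obs + pseudocount) / (expSum + pseudocount))
    }
  }
  bs <- binSize(x)
  data.frame(chrom = x@chrom, start = (seq_len(n) - 1) * bs,
             end = pmin(seq_len(n) * bs, x@chromLength), score = score)
}

#' Call TAD boundaries from an insulation track
#'
#' A bin is a boundary when its (sign-flipped) insulation score exceeds
#' the genome-wide quantile threshold and is the maximum within the
#' local span on both sides; ties across a plateau resolve to the lowest
#' coordinate.
#'
#' @param track insulation data.frame (possibly row-bound over
#'   chromosomes) from \code{\link{insulationScore}}.
#' @param quantile genome-wide quantile threshold (default 0.90).
#' @param localSpan bp span on each side for the local-maximum rule
#'   (default 2 kb).
#' @return data.frame of boundary bins (\code{chrom}, \code{start},
#'   \code{end}, \code{score}).
#' @export
callBoundaries <- function(track, quantile = 0.90, localSpan = 2000) {
  sc <- track$score
  finite <- is.finite(sc)
  if (!any(finite)) stop("no finite insulation values")
  thr <- stats::quantile(sc[finite], quantile, names = FALSE)
  keep <- logical(nrow(track))
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    bs <- track$end[idx[1]] - track$start[idx[1]]
    span <- max(1L, as.integer(round(localSpan / bs)))
    v <- sc[idx]
    for (ii in seq_along(idx)) {
      if (!is.finite(v[ii]) || v[ii] <= thr) next
      lo <- max(1, ii - span); hi <- min(length(v), ii + span)
      wnd <- v[lo:hi]
      wnd[!is.finite(wnd)] <- -Inf
      if (v[ii] < max(wnd)) next
      ## plateau tie: only the lowest coordinate wins
      before <- v[lo:ii][-(ii - lo + 1)]
      if (length(before) && any(is.finite(before) & before == v[ii])) next
      keep[idx[ii]] <- TRUE
    }
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescaled TAD pileup
#'
#' Each TAD of length L is extended by L on both sides; the 3L region is
#' rescaled onto a 100 x 100 grid of log2 observed/expected enrichment
#' and averaged across TADs, so TADs of different sizes align. TADs
#' whose extension leaves the chromosome are skipped and counted.
#'
#' @param x a \linkS4class{BinnedContactMatrix}.
#' @param tads \code{GRanges} of TADs on the same chromosome.
#' @param gridBins grid dimension (default 100).
#' @param pseudocount for the log ratio.
#' @param track optional pileup data.frame (chrom/pos/fraction); when
#'   given, per-grid-bin mean track values are also returned.
#' @return list with \code{grid} (gridBins x gridBins mean log2
#'   enrichment), \code{nUsed}, \code{nSkipped}, and optionally
#'   \code{trackProfile} (length gridBins).
#' @export
rescaledTadPileup <- function(x, tads, gridBins = 100L, pseudocount = 1,
                              track = NULL) {
  oe <- log2(.oeMatrix(x, pseudocount = pseudocount))
  bs <- binSize(x)
  n <- nrow(oe)
  acc <- matrix(0, gridBins, gridBins)
  cnt <- 0L; skipped <- 0L
  profAcc <- rep(0, gridBins); profCnt <- rep(0L, gridBins)
  for (t in seq_along(tads)) {
    if (as.character(seqnames(tads)[t]) != x@chrom) { skipped <- skipped + 1L; next }
    s <- start(tads)[t] - 1; e <- end(tads)[t]
    L <- e - s
    lo <- s - L; hi <- e + L
    if (lo < 0 || hi > x@chromLength) { skipped <- skipped + 1L; next }
    ## nearest-bin sampling of the rescaled grid
    coords <- lo + (seq_len(gridBins) - 0.5) / gridBins * (3 * L)
    bins <- pmin(pmax(floor(coords / bs) + 1, 1), n)
    acc <- acc + oe[bins, bins]
    cnt <- cnt + 1L
    if (!is.null(track)) {
      for (g in seq_len(gridBins)) {
        gLo <- lo + (g - 1) / gridBins * (3 * L)
        gHi <- lo + g / gridBins * (3 * L)
        sel <- track$chrom == x@chrom & track$pos >= gLo & track$pos < gHi
        if (any(sel)) {
          profAcc[g] <- profAcc[g] + mean(track$fraction[sel])
          profCnt[g] <- profCnt[g] + 1L
        }
      }
    }
  }
  if (cnt == 0L) stop("no usable TADs after extension")
  out <- list(grid = acc / cnt, nUsed = cnt, nSkipped = skipped)
  if (!is.null(track))
    out$trackProfile <- ifelse(profCnt > 0, profAcc / profCnt, NA_real_)
  out
}

#' A/B compartment eigenvector
#'
#' Leading eigenvector of the correlation matrix of the distance-
#' normalized (observed/expected) contact map, the standard compartment
#' call at coarse bins (typically 250 kb). Zero-coverage bins are masked.
#' The sign is oriented so the A (positive) compartment correlates
#' positively with \code{orientTrack} (e.g. an accessibility track) when
#' provided, otherwise the first non-masked entry is made positive.
#'
#' @param x a \linkS4class{BinnedContactMatrix} at coarse bins.
#' @param orientTrack optional numeric per-bin track for sign
#'   orientation.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{value} (eigenvector, NA at masked bins) and \code{label}
#'   ("A"/"B" by sign). Attribute \code{"reliable"} is FALSE when the
#'   eigenvector is effectively constant (degenerate, e.g. a uniform
#'   map).
#' @export
compartmentEigenvector <- function(x, orientTrack = NULL) {
  m <- contactCounts(x)
  n <- nrow(m)
  mask <- rowSums(m) == 0
  value <- rep(NA_real_, n)
  reliable <- FALSE
  if (sum(!mask) >= 3) {
    oe <- .oeMatrix(x)[!mask, !mask, drop = FALSE]
    cm <- suppressWarnings(cor(oe))
    ## a constant obs/exp map has no defined correlations: degenerate
    finiteFrac <- mean(is.finite(cm[upper.tri(cm)]))
    cm[!is.finite(cm)] <- 0
    ev <- eigen(cm, symmetric = TRUE)$vectors[, 1]
    value[!mask] <- ev
    reliable <- finiteFrac > 0.5 &&
      sd(ev) > 1e-6 * max(abs(ev), 1e-12)
    flip <- FALSE
    if (!is.null(orientTrack)) {
      ct <- suppressWarnings(cor(value, orientTrack,
                                 use = "complete.obs"))
      if (is.finite(ct) && ct < 0) flip <- TRUE
    } else {
      firstNZ <- which(!mask & abs(value) > 0)[1]
      if (!is.na(firstNZ) && value[firstNZ] < 0) flip <- TRUE
    }
    if (flip) value <- -value
  }
  bs <- binSize(x)
  out <- data.frame(chrom = x@chrom, start = (seq_len(n) - 1) * bs,
                    end = pmin(seq_len(n) * bs, x@chromLength),
                    value = value,
                    label = ifelse(is.na(value), NA_character_,
                                   ifelse(value >= 0, "A", "B")))
  attr(out, "reliable") <- reliable
  out
}

#' Compartment strength
#'
#' Ratio of observed/expected contacts within compartments to those
#' between compartments, (AA + BB) / (AB + BA), over intrachromosomal
#' bin pairs separated by at least \code{minSep} (default 10 Mb). The
#' within- and between-compartment sums are normalized by their pair
#' counts (i.e. the ratio of mean obs/exp values), so the statistic is
#' invariant both to sequencing depth and to the A/B label balance: a
#' structureless uniform map scores exactly 1.
#'
#' @param x a \linkS4class{BinnedContactMatrix}.
#' @param labels per-bin "A"/"B" labels (NA = unlabeled), e.g. from
#'   \code{\link{compartmentEigenvector}}.
#' @param minSep minimum separation in bp.
#' @param pseudocount for the obs/exp ratio.
#' @return strength (numeric scalar).
#' @export
compartmentStrength <- function(x, labels, minSep = 1e7,
                                pseudocount = 1) {
  n <- nrow(contactCounts(x))
  stopifnot(length(labels) == n)
  oe <- .oeMatrix(x, pseudocount = pseudocount)
  minBins <- ceiling(minSep / binSize(x))
  idx <- which(upper.tri(oe), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  ok <- sep >= minBins & !is.na(labels[idx[, 1]]) &
    !is.na(labels[idx[, 2]])
  if (!any(ok)) stop("no qualifying bin pairs at this separation")
  same <- labels[idx[ok, 1]] == labels[idx[ok, 2]]
  vals <- oe[idx[ok, , drop = FALSE]]
  if (!any(same) || all(same))
    stop("need both within- and between-compartment pairs")
  mean(vals[same]) / mean(vals[!same])
}

#' Aggregate pairwise contact enrichment (APA-style pileup)
#'
#' Stacks log2 observed/expected submatrices centred on anchor bin pairs
#' and averages them. The central enrichment is the mean over the
#' central nine bins (3 x 3); each corner is a 3 x 3 block; the
#' center/corner ratio is computed on the linear enrichment scale.
#' Pairs whose window leaves the matrix are skipped and counted.
#'
#' @param x a \linkS4class{BinnedContactMatrix}.
#' @param anchorPairs data.frame with bp columns \code{pos1},
#'   \code{pos2} (cis anchor midpoints, pos1 < pos2).
#' @param window total window width in bp around each anchor pair.
#' @param pseudocount for the log ratio.
#' @return list with \code{map} (mean log2 enrichment), \code{ratio}
#'   (center vs mean corner, linear scale), \code{perCorner} (four
#'   ratios), \code{nUsed}, \code{nSkipped}.
#' @export
aggregatePairEnrichment <- function(x, anchorPairs, window = 100000,
                                    pseudocount = 1) {
  e <- expectedCounts(x)
  m <- contactCounts(x)
  n <- nrow(m)
  bs <- binSize(x)
  w <- max(1L, as.integer(round(window / bs / 2)))
  dim <- 2L * w + 1L
  if (dim < 6L) stop("window too small for 3x3 center and corner blocks")
  accLin <- matrix(0, dim, dim)
  cnt <- 0L; skipped <- 0L
  for (p in seq_len(nrow(anchorPairs))) {
    i <- floor(anchorPairs$pos1[p] / bs) + 1L
    j <- floor(anchorPairs$pos2[p] / bs) + 1L
    if (i - w < 1 || j + w > n || j - w < 1 || i + w > n) {
      skipped <- skipped + 1L; next
    }
    ri <- (i - w):(i + w); rj <- (j - w):(j + w)
    ed <- abs(outer(ri, rj, "-")) + 1L
    lin <- (m[ri, rj] + pseudocount) /
      (matrix(e[ed], dim, dim) + pseudocount)
    accLin <- accLin + lin
    cnt <- cnt + 1L
  }
  if (cnt == 0L) stop("no usable anchor pairs in the matrix")
  meanLin <- accLin / cnt
  c0 <- w + 1L
  center <- mean(meanLin[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)])
  cornerBlock <- function(r, c) mean(meanLin[r:(r + 2), c:(c + 2)])
  corners <- c(topleft = cornerBlock(1L, 1L),
               topright = cornerBlock(1L, dim - 2L),
               bottomleft = cornerBlock(dim - 2L, 1L),
               bottomright = cornerBlock(dim - 2L, dim - 2L))
  list(map = log2(meanLin), ratio = center / mean(corners),
       perCorner = center / corners, nUsed = cnt, nSkipped = skipped)
}

#' Per-pair contact scores
#'
#' Mean log2 observed/expected enrichment in a window (default 10 kb)
#' centred on each anchor pair separately, suitable for comparing pair
#' classes with a Wilcoxon rank-sum test. This distance-normalized score
#' is the package's transparent stand-in for kNN-smoothed per-pair
#' contact scores.
#'
#' @inheritParams aggregatePairEnrichment
#' @param window total window width in bp (default 10 kb).
#' @return data.frame: the anchor pairs with a \code{score} column (NA
#'   for pairs whose window leaves the matrix).
#' @export
perPairScore <- function(x, anchorPairs, window = 10000,
                         pseudocount = 1) {
  e <- expectedCounts(x)
  m <- contactCounts(x)
  n <- nrow(m)
  bs <- binSize(x)
  w <- max(0L, as.integer(round(window / bs / 2)))
  score <- rep(NA_real_, nrow(anchorPairs))
  for (p in seq_len(nrow(anchorPairs))) {
    i <- floor(anchorPairs$pos1[p] / bs) + 1L
    j <- floor(anchorPairs$pos2[p] / bs) + 1L
    if (min(i, j) - w < 1 || max(i, j) + w > n) next
    ri <- (i - w):(i + w); rj <- (j - w):(j + w)
    ed <- abs(outer(ri, rj, "-")) + 1L
    lin <- (m[ri, rj] + pseudocount) /
      (matrix(e[ed], length(ri), length(rj)) + pseudocount)
    score[p] <- mean(log2(lin))
  }
  cbind(anchorPairs, score = score)
}

#' Associate features (peaks) with genes
#'
#' Features within the promoter window (+/- 5 kb of a TSS) are assigned
#' to their nearest TSS; distal features are assigned to the TSS within
#' the same TAD with the highest contact score among candidates between
#' 5 kb and 2 Mb away (ties resolve to the nearest). Features outside
#' any TAD, or without candidates, stay unassigned.
#'
#' @param features \code{GRanges} of peaks/features.
#' @param tss \code{GRanges} of transcription start sites; gene names in
#'   \code{names(tss)} or \code{mcols(tss)$gene}.
#' @param tads \code{GRanges} of TADs.
#' @param scoreFun function(chrom, pos1, pos2) returning a contact score
#'   per candidate pair, e.g. built on \code{\link{perPairScore}}.
#' @param promoterWindow,minDist,maxDist association distance rules (bp).
#' @return data.frame with one row per feature: \code{feature},
#'   \code{gene}, \code{mode} ("promoter", "distal" or "unassigned"),
#'   \code{distance}, \code{score}.
#' @export
associateFeaturesToGenes <- function(features, tss, tads, scoreFun,
                                     promoterWindow = 5000,
                                     minDist = 5000, maxDist = 2e6) {
  stopifnot(is(features, "GRanges"), is(tss, "GRanges"),
            is(tads, "GRanges"))
  genes <- if (!is.null(names(tss))) names(tss)
           else if (!is.null(mcols(tss)$gene)) mcols(tss)$gene
           else as.character(seq_along(tss))
  fMid <- floor((start(features) + end(features)) / 2)
  tPos <- ifelse(as.character(strand(tss)) == "-", end(tss), start(tss))
  fChr <- as.character(seqnames(features))
  tChr <- as.character(seqnames(tss))
  res <- data.frame(feature = seq_along(features),
                    gene = NA_character_, mode = "unassigned",
                    distance = NA_real_, score = NA_real_,
                    stringsAsFactors = FALSE)
  ovTad <- GenomicRanges::findOverlaps(features, tads, select = "first")
  for (i in seq_along(features)) {
    sameChr <- which(tChr == fChr[i])
    if (!length(sameChr)) next
    d <- abs(tPos[sameChr] - fMid[i])
    prox <- which(d <= promoterWindow)
    if (length(prox)) {
      j <- prox[which.min(d[prox])]
      res$gene[i] <- genes[sameChr[j]]
      res$mode[i] <- "promoter"
      res$distance[i] <- d[j]
      next
    }
    ti <- ovTad[i]
    if (is.na(ti)) next
    inTad <- tPos[sameChr] >= start(tads)[ti] - 1 &
      tPos[sameChr] <= end(tads)[ti]
    cand <- which(inTad & d >= minDist & d <= maxDist)
    if (!length(cand)) next
    sc <- scoreFun(fChr[i], pmin(fMid[i], tPos[sameChr[cand]]),
                   pmax(fMid[i], tPos[sameChr[cand]]))
    best <- which(sc == max(sc, na.rm = TRUE))
    if (!length(best) || all(is.na(sc))) next
    j <- cand[best[which.min(d[cand][best])]]
    res$gene[i] <- genes[sameChr[j]]
    res$mode[i] <- "distal"
    res$distance[i] <- d[j]
    res$score[i] <- max(sc, na.rm = TRUE)
  }
  res
}
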