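## Single-molecule co-accessibility / co-methylation: anchoring of reads
## to filter intervals, window filtering of calls, read-pair merging,
## k-means clustering, Fisher exact dependence testing and randomized
## controls.

.intervalMidpoints <- function(intervals) {
  ## GRanges are 1-based closed; midpoints reported 0-based to match calls
  floor((start(intervals) + end(intervals)) / 2) - 1L
}

#' Nearest filter interval for genomic positions
#'
#' Binary-search lookup of the interval whose midpoint is closest to each
#' query position; ties break toward the lower coordinate.
#'
#' @param chrom,pos query chromosome (scalar) and 0-based positions.
#' @param intervals \code{GRanges} of filter intervals (e.g. TF motifs
#'   overlapping ChIP-seq peaks).
#' @return data.frame with \code{interval} (index into \code{intervals},
#'   NA when the chromosome has none) and \code{distance} (bp to the
#'   midpoint).
#' @export
nearestInterval <- function(chrom, pos, intervals) {
  stopifnot(is(intervals, "GRanges"))
  onChrom <- which(as.character(seqnames(intervals)) == chrom)
  if (!length(onChrom))
    return(data.frame(interval = rep(NA_integer_, length(pos)),
                      distance = rep(NA_real_, length(pos))))
  mids <- .intervalMidpoints(intervals[onChrom])
  ord <- order(mids)
  midsSorted <- mids[ord]
  j <- findInterval(pos, midsSorted)            # last midpoint <= pos
  lo <- pmax(j, 1L)
  hi <- pmin(j + 1L, length(midsSorted))
  dLo <- abs(pos - midsSorted[lo])
  dHi <- abs(pos - midsSorted[hi])
  pick <- ifelse(dLo <= dHi, lo, hi)            # tie -> lower coordinate
  data.frame(interval = onChrom[ord][pick],
             distance = pmin(dLo, dHi))
}

#' Filter methylation calls to windows around filter intervals
#'
#' Retains calls lying within \code{window / 2} bp of the midpoint of
#' their nearest filter interval (a "100 bp window" therefore means
#' midpoint +/- 50 bp). Reads whose calls all fall outside every window
#' disappear, implementing the rule that only reads containing at least
#' one retained methylation call survive.
#'
#' @param calls a \linkS4class{MethCallTable} or its data.frame.
#' @param intervals \code{GRanges} of filter intervals.
#' @param window total window width in bp (default 100).
#' @return data.frame of retained calls annotated with \code{anchor}
#'   (interval index), \code{anchor_mid} (0-based midpoint) and
#'   \code{anchor_dist}.
#' @export
filterCallsByWindow <- function(calls, intervals, window = 100) {
  df <- if (is(calls, "MethCallTable")) methCalls(calls) else calls
  stopifnot(window > 0)
  out <- vector("list", 0L)
  mids <- .intervalMidpoints(intervals)
  for (chr in unique(df$chrom)) {
    sel <- which(df$chrom == chr)
    nn <- nearestInterval(chr, df$pos[sel], intervals)
    keep <- !is.na(nn$interval) & nn$distance <= window / 2
    if (!any(keep)) next
    sub <- df[sel[keep], , drop = FALSE]
    sub$anchor <- nn$interval[keep]
    sub$anchor_mid <- mids[nn$interval[keep]]
    sub$anchor_dist <- nn$distance[keep]
    out[[length(out) + 1L]] <- sub
  }
  if (!length(out))
    return(cbind(df[0, , drop = FALSE],
                 anchor = integer(), anchor_mid = integer(),
                 anchor_dist = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## per (read_id, mate) summary of anchored calls: modal anchor, call
## count and mean methylated fraction over calls at that anchor
.summarizeAnchoredReads <- function(filtered) {
  if (!nrow(filtered))
    return(data.frame(read_id = character(), mate = integer(),
                      anchor = integer(), anchor_mid = integer(),
                      n_calls = integer(), mean_state = numeric()))
  key <- paste(filtered$read_id, filtered$mate, filtered$anchor, sep = "\r")
  meth <- rowsum((filtered$state == "methylated") + 0, key)
  tot <- rowsum(rep(1L, nrow(filtered)), key)
  first <- !duplicated(key)
  info <- filtered[first, c("read_id", "mate", "anchor", "anchor_mid")]
  info <- info[match(rownames(meth), key[first]), ]
  res <- data.frame(info, n_calls = as.integer(tot),
                    mean_state = as.numeric(meth / tot),
                    stringsAsFactors = FALSE)
  ## a read landing in several windows keeps its best-covered anchor
  ord <- order(res$read_id, res$mate, -res$n_calls, res$anchor)
  res <- res[ord, ]
  res[!duplicated(res[, c("read_id", "mate")]), , drop = FALSE]
}

#' Merge anchored mates into paired read observations
#'
#' Joins mate-1 calls anchored to interval set A with mate-2 calls
#' anchored to set B on the full read name, so only read pairs
#' overlapping both filter intervals survive. Per mate, the mean
#' accessibility (or methylation) over retained calls is computed. By
#' default the symmetric assignment (mate 1 to B, mate 2 to A) is pooled
#' in as well. The separation between anchor midpoints must lie within
#' \code{[minSep, maxSep]}; an orientation rule can additionally require
#' convergent anchors (+ motif at the lower coordinate, - at the
#' higher).
#'
#' @param calls a \linkS4class{MethCallTable}; subset to one context
#'   (e.g. GCH) before calling, or use the \code{context} argument.
#' @param anchorsA,anchorsB \code{GRanges} filter interval sets.
#' @param window total call window width in bp around interval midpoints.
#' @param minSep,maxSep separation bounds (bp) between anchor midpoints.
#' @param orientation "none" or "convergent".
#' @param context retain only calls of this context (NULL = all).
#' @param symmetric also pool the mate-swapped assignment.
#' @return data.frame with one row per qualifying read pair:
#'   \code{pair_id}, \code{anchorA}, \code{anchorB}, \code{n_callsA},
#'   \code{n_callsB}, \code{meanA}, \code{meanB}, \code{midA},
#'   \code{midB} (anchor midpoints, 0-based) and \code{separation}.
#' @export
pairObservations <- function(calls, anchorsA, anchorsB, window = 100,
                             minSep = 1000, maxSep = Inf,
                             orientation = c("none", "convergent"),
                             context = "GCH", symmetric = TRUE) {
  orientation <- match.arg(orientation)
  df <- if (is(calls, "MethCallTable")) methCalls(calls) else calls
  if (!is.null(context)) df <- df[df$context == context, , drop = FALSE]
  df <- df[df$source == "genomic", , drop = FALSE]

  onePass <- function(mateA, mateB) {
    fA <- .summarizeAnchoredReads(
      filterCallsByWindow(df[df$mate == mateA, , drop = FALSE],
                          anchorsA, window))
    fB <- .summarizeAnchoredReads(
      filterCallsByWindow(df[df$mate == mateB, , drop = FALSE],
                          anchorsB, window))
    m <- merge(fA, fB, by = "read_id", suffixes = c("A", "B"))
    if (!nrow(m)) return(NULL)
    data.frame(pair_id = m$read_id, anchorA = m$anchorA,
               anchorB = m$anchorB, n_callsA = m$n_callsA,
               n_callsB = m$n_callsB, meanA = m$mean_stateA,
               meanB = m$mean_stateB,
               midA = m$anchor_midA, midB = m$anchor_midB,
               separation = abs(m$anchor_midA - m$anchor_midB),
               stringsAsFactors = FALSE)
  }
  obs <- onePass(1L, 2L)
  if (symmetric) obs <- rbind(obs, onePass(2L, 1L))
  if (is.null(obs) || !nrow(obs)) {
    warning("no qualifying read pairs")
    return(data.frame(pair_id = character(), anchorA = integer(),
                      anchorB = integer(), n_callsA = integer(),
                      n_callsB = integer(), meanA = numeric(),
                      meanB = numeric(), midA = integer(),
                      midB = integer(), separation = numeric()))
  }
  ## a read pair qualifying in both mate assignments keeps one
  ## observation, chosen by swap-invariant keys (call support, then
  ## anchor coordinates, then means) so that exchanging sets A and B
  ## transposes the result instead of changing it
  ord <- order(obs$pair_id,
               -(obs$n_callsA + obs$n_callsB),
               pmin(obs$midA, obs$midB),
               pmax(obs$midA, obs$midB),
               -pmax(obs$meanA, obs$meanB),
               -pmin(obs$meanA, obs$meanB))
  obs <- obs[ord, , drop = FALSE]
  obs <- obs[!duplicated(obs$pair_id), , drop = FALSE]
  obs <- obs[obs$separation >= minSep & obs$separation <= maxSep, ,
             drop = FALSE]
  if (orientation == "convergent") {
    midsA <- .intervalMidpoints(anchorsA)[obs$anchorA]
    midsB <- .intervalMidpoints(anchorsB)[obs$anchorB]
    strA <- as.character(strand(anchorsA))[obs$anchorA]
    strB <- as.character(strand(anchorsB))[obs$anchorB]
    upStrand <- ifelse(midsA <= midsB, strA, strB)
    dnStrand <- ifelse(midsA <= midsB, strB, strA)
    obs <- obs[upStrand == "+" & dnStrand == "-", , drop = FALSE]
  }
  rownames(obs) <- NULL
  obs
}

#' k-means clustering of paired observations
#'
#' Clusters the (meanA, meanB) observation matrix with seeded k-means
#' (10 restarts) and relabels clusters 1..k by descending grand mean of
#' their centroids, so cluster 1 is the most open/most methylated
#' (typically the co-accessible open/open cluster).
#'
#' @param obs observation data.frame from \code{\link{pairObservations}}.
#' @param k number of clusters (default 4).
#' @param seed integer seed making assignments reproducible.
#' @param nstart k-means restarts.
#' @return list with \code{assignments} (integer per observation) and
#'   \code{centers} (k x 2 matrix, ordered).
#' @export
clusterObservations <- function(obs, k = 4L, seed = 1L, nstart = 10L) {
  m <- cbind(meanA = obs$meanA, meanB = obs$meanB)
  if (nrow(m) < k) stop("fewer observations than clusters")
  set.seed(as.integer(seed))
  km <- kmeans(m, centers = k, nstart = nstart, iter.max = 100L)
  ord <- order(-rowMeans(km$centers), km$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(assignments = relabel[km$cluster],
       centers = km$centers[ord, , drop = FALSE])
}

#' Binarize paired observations into open/closed states
#'
#' A mate is called open when its mean accessibility is at or above the
#' threshold. Observations with fewer than \code{minCalls} calls on
#' either mate are excluded and counted.
#'
#' @param obs observation data.frame.
#' @param minCalls minimum calls per mate (default 1).
#' @param threshold open/closed cutoff on the per-read mean (default
#'   0.5; mean == threshold is open).
#' @return list with logical vectors \code{openA}, \code{openB},
#'   logical \code{included} and \code{nExcluded}.
#' @export
binarizeObservations <- function(obs, minCalls = 1L, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  included <- obs$n_callsA >= minCalls & obs$n_callsB >= minCalls
  list(openA = obs$meanA[included] >= threshold,
       openB = obs$meanB[included] >= threshold,
       included = included, nExcluded = sum(!included))
}

#' Fisher exact dependence test on binary mate states
#'
#' Tests whether open/closed states of the two mates of a molecule are
#' independent, via the two-sided Fisher exact test on the 2x2
#' contingency table. The reported odds ratio is the sample
#' cross-product (n11 n00) / (n10 n01), with a Haldane-Anscombe 0.5
#' correction when any cell is zero; a zero margin leaves the odds ratio
#' undefined (NA) with p = 1.
#'
#' @param openA,openB logical state vectors (same length).
#' @return list with \code{table} (2x2, rows = mate A open/closed,
#'   cols = mate B), \code{odds_ratio}, \code{p_value} and
#'   \code{co_accessible_fraction} (percent open/open).
#' @examples
#' ## table [[20,10],[10,20]] has cross-product odds ratio 4
#' @export
dependenceTest <- function(openA, openB) {
  stopifnot(length(openA) == length(openB), length(openA) >= 1)
  tb <- matrix(c(sum(openA & openB), sum(openA & !openB),
                 sum(!openA & openB), sum(!openA & !openB)),
               nrow = 2, byrow = TRUE,
               dimnames = list(A = c("open", "closed"),
                               B = c("open", "closed")))
  marginZero <- any(rowSums(tb) == 0) || any(colSums(tb) == 0)
  if (marginZero) {
    orHat <- NA_real_
    p <- 1
  } else {
    ct <- if (any(tb == 0)) tb + 0.5 else tb
    orHat <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
    p <- fisher.test(tb)$p.value
  }
  list(table = tb, odds_ratio = orHat, p_value = p,
       co_accessible_fraction = 100 * tb[1, 1] / sum(tb))
}

#' Randomized control for the co-accessibility analysis
#'
#' Builds the background observation set in which only one mate of a
#' read pair is required to overlap a filter interval. The anchored mate
#' is processed as usual; the unanchored mate's calls are taken around
#' the midpoint of its own call span (no feature anchoring). The control
#' is subsampled (seeded) to the size of the observed set when
#' \code{nMatch} is given, and the same separation bounds apply.
#'
#' @param calls a \linkS4class{MethCallTable}.
#' @param intervals combined \code{GRanges} of filter intervals.
#' @param window,minSep,maxSep,context as in
#'   \code{\link{pairObservations}}.
#' @param nMatch subsample size (NULL = keep all).
#' @param seed seed for the subsampling.
#' @return observation data.frame with the
#'   \code{\link{pairObservations}} schema.
#' @export
randomizedControl <- function(calls, intervals, window = 100,
                              minSep = 1000, maxSep = Inf,
                              context = "GCH", nMatch = NULL, seed = 1L) {
  df <- if (is(calls, "MethCallTable")) methCalls(calls) else calls
  if (!is.null(context)) df <- df[df$context == context, , drop = FALSE]
  df <- df[df$source == "genomic", , drop = FALSE]

  onePass <- function(mateA, mateB) {
    fA <- .summarizeAnchoredReads(
      filterCallsByWindow(df[df$mate == mateA, , drop = FALSE],
                          intervals, window))
    other <- df[df$mate == mateB, , drop = FALSE]
    ## unanchored mate: window centred on its own retained-call span
    sp <- split(seq_len(nrow(other)), other$read_id)
    ids <- names(sp)
    summB <- do.call(rbind, lapply(seq_along(sp), function(i) {
      rows <- other[sp[[i]], , drop = FALSE]
      mid <- floor((min(rows$pos) + max(rows$pos)) / 2)
      keep <- abs(rows$pos - mid) <= window / 2
      data.frame(read_id = ids[i], mid = mid,
                 n_calls = sum(keep),
                 mean_state = mean(rows$state[keep] == "methylated"),
                 stringsAsFactors = FALSE)
    }))
    ## anchored on exactly one side: drop reads whose other mate is
    ## itself anchored
    fBanch <- .summarizeAnchoredReads(
      filterCallsByWindow(other, intervals, window))
    fA <- fA[!(fA$read_id %in% fBanch$read_id), , drop = FALSE]
    m <- merge(fA, summB, by = "read_id")
    if (!nrow(m)) return(NULL)
    data.frame(pair_id = m$read_id, anchorA = m$anchor,
               anchorB = NA_integer_, n_callsA = m$n_calls.x,
               n_callsB = m$n_calls.y, meanA = m$mean_state.x,
               meanB = m$mean_state.y,
               separation = abs(m$anchor_mid - m$mid),
               stringsAsFactors = FALSE)
  }
  obs <- rbind(onePass(1L, 2L), onePass(2L, 1L))
  if (is.null(obs) || !nrow(obs)) {
    warning("no qualifying control pairs")
    return(data.frame(pair_id = character(), anchorA = integer(),
                      anchorB = integer(), n_callsA = integer(),
                      n_callsB = integer(), meanA = numeric(),
                      meanB = numeric(), separation = numeric()))
  }
  obs <- obs[!duplicated(obs$pair_id), , drop = FALSE]
  obs <- obs[obs$separation >= minSep & obs$separation <= maxSep &
             obs$n_callsB >= 1, , drop = FALSE]
  if (!is.null(nMatch) && nrow(obs) > nMatch) {
    set.seed(as.integer(seed))
    obs <- obs[sort(sample(nrow(obs), nMatch)), , drop = FALSE]
  }
  rownames(obs) <- NULL
  obs
}

.resultFromObservations <- function(obs, k, seed, minCalls, threshold,
                                    control = NULL) {
  cl <- if (nrow(obs) >= k)
    clusterObservations(obs, k = k, seed = seed)
  else list(assignments = integer(0),
            centers = matrix(numeric(), ncol = 2))
  bin <- binarizeObservations(obs, minCalls, threshold)
  dep <- if (length(bin$openA)) dependenceTest(bin$openA, bin$openB)
         else list(table = matrix(0L, 2, 2), odds_ratio = NA_real_,
                   p_value = 1, co_accessible_fraction = NA_real_)
  topFrac <- if (length(cl$assignments))
    100 * mean(cl$assignments == 1L) else NA_real_
  new("CoAccessibilityResult", observations = obs,
      clusters = as.integer(cl$assignments), clusterMeans = cl$centers,
      table = dep$table, oddsRatio = dep$odds_ratio,
      pValue = dep$p_value,
      coAccessibleFraction = dep$co_accessible_fraction,
      coAccessibleFractionCluster = topFrac,
      nExcluded = as.integer(bin$nExcluded), control = control)
}

#' Single-molecule co-accessibility analysis
#'
#' The full single-molecule path: anchor mate 1 to interval set A and
#' mate 2 to set B (pooling the symmetric assignment), retain calls
#' within the window around anchor midpoints, merge mates on the full
#' read name, compute per-mate mean GpC accessibility, cluster the
#' two-column matrix with seeded k-means, binarize, and test dependence
#' of the two mates' open states with the Fisher exact test. Optionally
#' builds the randomized control in which only one mate must overlap an
#' interval.
#'
#' Presets from the long-range analyses: convergent CTCF pairs use
#' \code{minSep = 1000, orientation = "convergent"}; CRE-TSS pairs use
#' \code{minSep = 5000}; adjacent TF motif pairs use \code{window = 50,
#' minSep = 100, maxSep = 300}.
#'
#' @inheritParams pairObservations
#' @param k k-means cluster count (default 4).
#' @param seed seed for clustering and control subsampling.
#' @param minCalls,threshold binarization rule (see
#'   \code{\link{binarizeObservations}}).
#' @param control build the randomized control.
#' @return A \linkS4class{CoAccessibilityResult}.
#' @export
coAccessibility <- function(calls, anchorsA, anchorsB, window = 100,
                            minSep = 1000, maxSep = Inf,
                            orientation = c("none", "convergent"),
                            k = 4L, seed = 1L, minCalls = 1L,
                            threshold = 0.5, context = "GCH",
                            control = TRUE) {
  orientation <- match.arg(orientation)
  obs <- pairObservations(calls, anchorsA, anchorsB, window = window,
                          minSep = minSep, maxSep = maxSep,
                          orientation = orientation, context = context)
  ctrl <- NULL
  if (control && nrow(obs)) {
    combined <- c(granges(anchorsA), granges(anchorsB))
    cobs <- randomizedControl(calls, combined, window = window,
                              minSep = minSep, maxSep = maxSep,
                              context = context, nMatch = nrow(obs),
                              seed = seed)
    if (nrow(cobs))
      ctrl <- .resultFromObservations(cobs, k, seed, minCalls, threshold)
  }
  .resultFromObservations(obs, k, seed, minCalls, threshold, ctrl)
}

#' Single-molecule co-methylation analysis
#'
#' Identical machinery to \code{\link{coAccessibility}} with the call
#' context switched to the endogenous CpG channel (HCG): the per-mate
#' mean is a methylation level and "open" reads as "methylated". Cluster
#' ordering is still by descending mean.
#'
#' @inheritParams coAccessibility
#' @return A \linkS4class{CoAccessibilityResult}.
#' @export
coMethylation <- function(calls, anchorsA, anchorsB, window = 100,
                          minSep = 1000, maxSep = Inf,
                          orientation = c("none", "convergent"),
                          k = 4L, seed = 1L, minCalls = 1L,
                          threshold = 0.5, control = TRUE) {
  coAccessibility(calls, anchorsA, anchorsB, window = window,
                  minSep = minSep, maxSep = maxSep,
                  orientation = orientation, k = k, seed = seed,
                  minCalls = minCalls, threshold = threshold,
                  context = "HCG", control = control)
}
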