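## Independent brute-force reference implementations used as oracles.
## These deliberately share no code with the package internals.

## exhaustive sliding-window scan for junction motifs: every window of
## width 8 is compared against every motif
oracleScanJunctions <- function(seq, motifs = tridram::JUNCTION_MOTIFS) {
  n <- nchar(seq)
  out <- data.frame(offset = integer(), motif = character())
  if (n >= 8) {
    windows <- substring(seq, 1:(n - 7), 8:n)
    for (m in motifs) {
      hit <- which(windows == m) - 1L
      if (length(hit))
        out <- rbind(out, data.frame(offset = hit, motif = m,
                                     stringsAsFactors = FALSE))
    }
  }
  out[order(out$offset, out$motif), , drop = FALSE]
}

## linear-scan nearest interval midpoint (ties toward lower coordinate)
oracleNearest <- function(chrom, pos, intervals) {
  mids <- floor((GenomicRanges::start(intervals) +
                 GenomicRanges::end(intervals)) / 2) - 1L
  chr <- as.character(GenomicRanges::seqnames(intervals))
  vapply(pos, function(p) {
    cand <- which(chr == chrom)
    if (!length(cand)) return(NA_integer_)
    d <- abs(p - mids[cand])
    best <- cand[d == min(d)]
    best[which.min(mids[best])]
  }, integer(1))
}

## linear-scan fend assignment on one chromosome's cut sites
oracleFendLocal <- function(pos, strand, cutSites) {
  n <- length(cutSites)
  if (strand == "+") {
    ds <- cutSites[cutSites >= pos]
    if (!length(ds)) return(2L * n + 1L)
    2L * which(cutSites == min(ds))[1] - 1L
  } else {
    us <- cutSites[cutSites <= pos]
    if (!length(us)) return(0L)
    2L * which(cutSites == max(us))[1]
  }
}

## exhaustive O(calls x intervals) single-molecule anchoring + window
## filtering + read-pair merging
oraclePairPath <- function(callsDf, anchorsA, anchorsB, window,
                           minSep = 0, maxSep = Inf) {
  midsOf <- function(gr) floor((GenomicRanges::start(gr) +
                                GenomicRanges::end(gr)) / 2) - 1L
  summarize <- function(df, anchors) {
    mids <- midsOf(anchors)
    chr <- as.character(GenomicRanges::seqnames(anchors))
    rows <- list()
    for (rid in unique(df$read_id)) {
      sub <- df[df$read_id == rid, , drop = FALSE]
      ## per call: nearest interval, keep if within window/2
      kept <- data.frame(anchor = integer(), state = character())
      for (ci in seq_len(nrow(sub))) {
        cand <- which(chr == sub$chrom[ci])
        if (!length(cand)) next
        d <- abs(sub$pos[ci] - mids[cand])
        best <- cand[d == min(d)]
        best <- best[which.min(mids[best])]
        if (min(d) <= window / 2)
          kept <- rbind(kept, data.frame(anchor = best,
                                         state = sub$state[ci]))
      }
      if (!nrow(kept)) next
      counts <- table(kept$anchor)
      top <- as.integer(names(counts)[counts == max(counts)])
      a <- min(top)
      sel <- kept[kept$anchor == a, , drop = FALSE]
      rows[[rid]] <- data.frame(
        read_id = rid, anchor = a, anchor_mid = mids[a],
        n_calls = nrow(sel),
        mean_state = mean(sel$state == "methylated"))
    }
    do.call(rbind, c(rows, list(NULL)))
  }
  obs <- list()
  for (dir in 1:2) {
    mA <- if (dir == 1) 1L else 2L
    fA <- summarize(callsDf[callsDf$mate == mA, , drop = FALSE], anchorsA)
    fB <- summarize(callsDf[callsDf$mate == (3L - mA), , drop = FALSE],
                    anchorsB)
    if (is.null(fA) || is.null(fB)) next
    common <- intersect(fA$read_id, fB$read_id)
    for (rid in common) {
      ra <- fA[fA$read_id == rid, ]; rb <- fB[fB$read_id == rid, ]
      obs[[paste(rid, dir)]] <- data.frame(
        pair_id = rid, anchorA = ra$anchor, anchorB = rb$anchor,
        n_callsA = ra$n_calls, n_callsB = rb$n_calls,
        meanA = ra$mean_state, meanB = rb$mean_state,
        midA = ra$anchor_mid, midB = rb$anchor_mid,
        separation = abs(ra$anchor_mid - rb$anchor_mid))
    }
  }
  obs <- do.call(rbind, c(obs, list(NULL)))
  if (is.null(obs)) return(NULL)
  ## one observation per read pair, chosen by the swap-invariant keys:
  ## most supporting calls, then lower/upper anchor coordinates, then
  ## larger sorted means
  pick <- lapply(split(obs, obs$pair_id), function(g) {
    o <- order(-(g$n_callsA + g$n_callsB),
               pmin(g$midA, g$midB), pmax(g$midA, g$midB),
               -pmax(g$meanA, g$meanB), -pmin(g$meanA, g$meanB))
    g[o[1], , drop = FALSE]
  })
  obs <- do.call(rbind, pick)
  obs <- obs[obs$separation >= minSep & obs$separation <= maxSep, ,
             drop = FALSE]
  obs[order(obs$pair_id), , drop = FALSE]
}

## random call table spread around interval midpoints
randomCallTable <- function(nCalls, chroms = "chr1", maxPos = 10000,
                            nReads = ceiling(nCalls / 4)) {
  data.frame(
    read_id = sprintf("r%04d", sample(nReads, nCalls, replace = TRUE)),
    mate = sample(1:2, nCalls, replace = TRUE),
    chrom = sample(chroms, nCalls, replace = TRUE),
    pos = sample(0:maxPos, nCalls, replace = TRUE),
    context = "GCH",
    state = sample(c("methylated", "unmethylated"), nCalls,
                   replace = TRUE),
    source = "genomic", stringsAsFactors = FALSE)
}
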