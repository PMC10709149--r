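## Synthetic-data generator: seeded genomes, features, contact pairs and
## per-read methylation calls with planted ground truth.

#' SimConfig: parameters of the synthetic-data generator
#'
#' Holds every knob of the simulator: genome geometry, restriction motif,
#' informative-cytosine spacings, planted TAD/compartment structure, the
#' contact distance-decay exponent, anchored-feature geometry, the joint
#' Bernoulli law of per-molecule accessibility at anchored feature pairs
#' (marginals and odds ratio), GpC/CpG emission probabilities, the
#' bisulfite conversion-failure rate and the master seed. All randomness
#' in the generator derives from \code{seed} through fixed per-stage
#' substreams, so adding a downstream stage never perturbs earlier draws.
#'
#' @export
setClass("SimConfig",
         slots = c(genomeLength = "numeric", nChroms = "integer",
                   restrictionMotif = "character",
                   restrictionSpacing = "numeric",
                   gpcSpacing = "numeric", cpgSpacing = "numeric",
                   tadBoundaries = "numeric", tadBoost = "numeric",
                   compartmentBin = "numeric", compartmentBoost = "numeric",
                   decayExponent = "numeric", minDistance = "numeric",
                   maxDistance = "numeric",
                   anchorFeatures = "data.frame", anchorPairs = "matrix",
                   p1 = "numeric", p2 = "numeric", oddsRatio = "numeric",
                   pMethGivenOpen = "numeric", pMethGivenClosed = "numeric",
                   backgroundOpenProb = "numeric",
                   cpgMethBaseline = "numeric",
                   conversionFailure = "numeric",
                   nPairs = "integer", nAnchoredPairs = "integer",
                   readLen = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  probs <- c(object@p1, object@p2, object@pMethGivenOpen,
             object@pMethGivenClosed, object@backgroundOpenProb,
             object@cpgMethBaseline, object@conversionFailure)
  if (any(probs < 0 | probs > 1)) return("all probabilities must lie in [0, 1]")
  if (object@oddsRatio <= 0) return("oddsRatio must be > 0")
  if (object@decayExponent <= 0) return("decayExponent must be > 0")
  if (is.unsorted(object@tadBoundaries, strictly = TRUE))
    return("tadBoundaries must be strictly increasing")
  if (length(object@tadBoundaries) &&
      (min(object@tadBoundaries) <= 0 ||
       max(object@tadBoundaries) >= object@genomeLength))
    return("tadBoundaries must lie strictly inside the chromosome")
  if (object@tadBoost <= 0 || object@compartmentBoost <= 0)
    return("structure boosts must be > 0")
  if (object@minDistance < 1 || object@maxDistance <= object@minDistance)
    return("need 1 <= minDistance < maxDistance")
  if (object@nPairs < 0 || object@nAnchoredPairs < 0)
    return("pair counts must be >= 0")
  if (nrow(object@anchorFeatures) &&
      !all(c("chrom", "pos", "strand", "label") %in%
           names(object@anchorFeatures)))
    return("anchorFeatures needs columns chrom, pos, strand, label")
  if (nrow(object@anchorPairs) &&
      (max(object@anchorPairs) > nrow(object@anchorFeatures) ||
       min(object@anchorPairs) < 1))
    return("anchorPairs must index rows of anchorFeatures")
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChroms, "chromosome(s) x",
      object@genomeLength, "bp; alpha =", object@decayExponent, "\n")
  cat("  pairs:", object@nPairs, "background +", object@nAnchoredPairs,
      "anchored; seed", object@seed, "\n")
  cat("  joint law: p1 =", object@p1, ", p2 =", object@p2,
      ", odds ratio =", object@oddsRatio, "\n")
})

#' Build a simulation configuration
#'
#' Defaults describe a compact but structurally realistic test genome:
#' one 2 Mb chromosome with DpnII-like cut sites every ~300 bp, GpC
#' dinucleotides every ~15 bp and CpGs every ~75 bp, four TAD boundaries,
#' a 250 kb compartment checkerboard, distance decay with exponent 1 above
#' a 1 kb floor, and anchored feature pairs whose per-molecule open/closed
#' states follow a joint Bernoulli law with configurable marginals and
#' odds ratio.
#'
#' @param genomeLength bp per chromosome.
#' @param nChroms number of chromosomes.
#' @param restrictionMotif restriction recognition motif.
#' @param restrictionSpacing mean bp between planted cut sites.
#' @param gpcSpacing,cpgSpacing mean bp between informative GCH / HCG
#'   cytosines.
#' @param tadBoundaries planted TAD boundary positions (bp, applied to
#'   every chromosome).
#' @param tadBoost contact weight multiplier for within-TAD pairs.
#' @param compartmentBin compartment checkerboard bin (bp); labels
#'   alternate A/B per bin.
#' @param compartmentBoost weight multiplier for same-compartment pairs.
#' @param decayExponent power-law exponent alpha of the cis contact
#'   distance decay P(s) ~ s^-alpha.
#' @param minDistance decay sampling floor (bp).
#' @param maxDistance decay sampling ceiling (bp); defaults to half the
#'   chromosome to limit placement edge effects.
#' @param anchorFeatures data.frame(chrom, pos, strand, label) of planted
#'   anchor features.
#' @param anchorPairs two-column matrix of anchorFeatures row indices
#'   naming which feature pairs anchored read pairs connect; defaults to
#'   consecutive pairs (1,2), (3,4), ...
#' @param p1,p2 marginal open probabilities of the two anchor classes.
#' @param oddsRatio odds ratio theta of the joint open/open law.
#' @param pMethGivenOpen,pMethGivenClosed probability that a GCH call on
#'   an open / closed molecule is methylated.
#' @param backgroundOpenProb marginal open probability of non-anchored
#'   reads.
#' @param cpgMethBaseline probability that an HCG call is methylated.
#' @param conversionFailure epsilon: probability that a truly
#'   unmethylated cytosine escapes conversion (read as methylated), and
#'   symmetrically that a methylated one fails detection.
#' @param nPairs number of background contact pairs.
#' @param nAnchoredPairs number of anchored read pairs.
#' @param readLen read length (bp).
#' @param seed master seed; fixes all generator output bit-for-bit.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nPairs = 1000L, seed = 7L)
#' @export
simConfig <- function(genomeLength = 2e6, nChroms = 1L,
                      restrictionMotif = "GATC", restrictionSpacing = 300,
                      gpcSpacing = 15, cpgSpacing = 75,
                      tadBoundaries = c(4e5, 8e5, 1.2e6, 1.6e6),
                      tadBoost = 3, compartmentBin = 2.5e5,
                      compartmentBoost = 2,
                      decayExponent = 1, minDistance = 1000,
                      maxDistance = genomeLength / 2,
                      anchorFeatures = .defaultAnchors(genomeLength, nChroms),
                      anchorPairs = NULL,
                      p1 = 0.3, p2 = 0.3, oddsRatio = 1,
                      pMethGivenOpen = 0.85, pMethGivenClosed = 0.05,
                      backgroundOpenProb = 0.15, cpgMethBaseline = 0.7,
                      conversionFailure = 0.02,
                      nPairs = 50000L, nAnchoredPairs = 0L,
                      readLen = 100L, seed = 1L) {
  if (is.null(anchorPairs)) {
    nf <- nrow(anchorFeatures)
    anchorPairs <- if (nf >= 2)
      matrix(seq_len(nf - nf %% 2), ncol = 2, byrow = TRUE)
    else matrix(integer(), ncol = 2)
  }
  tadBoundaries <- tadBoundaries[tadBoundaries > 0 &
                                 tadBoundaries < genomeLength]
  new("SimConfig", genomeLength = genomeLength,
      nChroms = as.integer(nChroms), restrictionMotif = restrictionMotif,
      restrictionSpacing = restrictionSpacing, gpcSpacing = gpcSpacing,
      cpgSpacing = cpgSpacing, tadBoundaries = as.numeric(tadBoundaries),
      tadBoost = tadBoost, compartmentBin = compartmentBin,
      compartmentBoost = compartmentBoost, decayExponent = decayExponent,
      minDistance = minDistance, maxDistance = maxDistance,
      anchorFeatures = anchorFeatures,
      anchorPairs = if (is.matrix(anchorPairs)) anchorPairs
                    else matrix(as.integer(anchorPairs), ncol = 2),
      p1 = p1, p2 = p2, oddsRatio = oddsRatio,
      pMethGivenOpen = pMethGivenOpen, pMethGivenClosed = pMethGivenClosed,
      backgroundOpenProb = backgroundOpenProb,
      cpgMethBaseline = cpgMethBaseline,
      conversionFailure = conversionFailure, nPairs = as.integer(nPairs),
      nAnchoredPairs = as.integer(nAnchoredPairs),
      readLen = as.integer(readLen), seed = as.integer(seed))
}

## default anchor layout: 10 feature pairs on chr1, convergent strands,
## separated by 5 kb within a pair and spread across the chromosome
.defaultAnchors <- function(genomeLength, nChroms) {
  nPairs <- 10L
  centers <- round(seq(0.05, 0.95, length.out = nPairs) * genomeLength)
  data.frame(
    chrom = "chr1",
    pos = as.numeric(rbind(centers - 2500, centers + 2500)),
    strand = rep(c("+", "-"), nPairs),
    label = paste0(rep(c("A", "B"), nPairs), rep(seq_len(nPairs), each = 2)),
    stringsAsFactors = FALSE)
}

## deterministic per-stage substreams off the master seed
.substream <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + as.numeric(k)) %% 2147483647)
}

#' Solve the joint Bernoulli law for given marginals and odds ratio
#'
#' Finds the unique 2x2 cell probabilities (p11, p10, p01, p00) with
#' marginals p1 = p11 + p10, p2 = p11 + p01 and odds ratio
#' theta = p11 p00 / (p10 p01). For theta != 1 the admissible p11 is the
#' root of the quadratic (theta-1) x^2 - ((theta-1)(p1+p2) + 1) x +
#' theta p1 p2 lying in (max(0, p1+p2-1), min(p1, p2)); for theta = 1 it
#' is the product of the marginals.
#'
#' @param p1,p2 marginal success probabilities, in (0, 1).
#' @param theta odds ratio, > 0.
#' @return Named numeric vector \code{c(p11, p10, p01, p00)}.
#' @examples
#' solveJointBernoulli(0.5, 0.5, 1)   # p11 = 0.25
#' solveJointBernoulli(0.3, 0.3, 3)   # positively associated
#' @export
solveJointBernoulli <- function(p1, p2, theta) {
  if (!is.finite(theta) || theta <= 0)
    stop("odds ratio must be finite and > 0")
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("marginals must lie strictly in (0, 1)")
  if (abs(theta - 1) < 1e-12) {
    p11 <- p1 * p2
  } else {
    a <- theta - 1
    b <- -((theta - 1) * (p1 + p2) + 1)
    cc <- theta * p1 * p2
    disc <- b * b - 4 * a * cc
    if (disc < 0) disc <- 0
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
    lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop("no admissible joint probability found")
    p11 <- min(max(roots[ok][1], lo), hi)
  }
  out <- c(p11 = p11, p10 = p1 - p11, p01 = p2 - p11,
           p00 = 1 - p1 - p2 + p11)
  pmax(out, 0)
}

#' Simulate a test genome with planted motifs
#'
#' Random uniform ACGT sequence per chromosome in which the restriction
#' motif, GpC dinucleotides and CpG dinucleotides are planted at their
#' configured mean spacings (jittered), giving realistic densities of
#' informative cytosines without attempting realistic base composition.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A \code{DNAStringSet}, one entry per chromosome.
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(.substream(config@seed, 101L))
  L <- as.integer(config@genomeLength)
  seqs <- character(config@nChroms)
  for (i in seq_len(config@nChroms)) {
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    plant <- function(positions, pattern) {
      pat <- strsplit(pattern, "")[[1]]
      positions <- positions[positions >= 1 &
                             positions + length(pat) - 1 <= L]
      for (k in seq_along(pat)) bases[positions + k - 1] <<- pat[k]
    }
    jittered <- function(spacing) {
      n <- floor(L / spacing)
      pos <- round(seq_len(n) * spacing +
                   runif(n, -spacing / 3, spacing / 3))
      pos[pos >= 10 & pos <= L - 10]
    }
    ## plant GpC (preceded by A so it classifies GCH, followed by non-G)
    gpc <- jittered(config@gpcSpacing)
    plant(gpc, "AGCA")
    ## plant CpG (flanked so it classifies HCG)
    cpg <- jittered(config@cpgSpacing) + 7L
    plant(cpg, "ACGA")
    ## restriction sites last so fend geometry is exact
    plant(jittered(config@restrictionSpacing) + 3L, config@restrictionMotif)
    seqs[i] <- paste(bases, collapse = "")
  }
  names(seqs) <- paste0("chr", seq_len(config@nChroms))
  DNAStringSet(seqs)
}

## inverse-CDF sampling of distances with density ~ s^-alpha on [a, b]
.sampleDecayDistances <- function(n, a, b, alpha) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) {
    s <- a * (b / a)^u
  } else {
    e <- 1 - alpha
    s <- (u * (b^e - a^e) + a^e)^(1 / e)
  }
  round(s)
}

.tadSegment <- function(pos, boundaries) findInterval(pos, boundaries)

.compartmentLabelOf <- function(pos, compartmentBin) {
  ifelse((floor(pos / compartmentBin) %% 2) == 0, "A", "B")
}

#' Simulate cis contact pairs with planted structure
#'
#' Background pairs draw distances from a truncated power law
#' P(s) ~ s^-alpha on [minDistance, maxDistance] and are placed uniformly;
#' rejection sampling up-weights within-TAD pairs by \code{tadBoost} and
#' same-compartment pairs by \code{compartmentBoost}. Anchored read pairs
#' connect the configured anchor feature pairs, and each carries a latent
#' open/closed state per mate drawn from the joint Bernoulli law
#' (\code{\link{solveJointBernoulli}}); these latent states are the ground
#' truth that downstream odds-ratio estimation must recover.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return A list with elements \code{pairs} (a
#'   \linkS4class{ContactPairs}) and \code{truth} (a list carrying the
#'   anchored-pair latent states, planted TAD boundaries and compartment
#'   labels).
#' @export
simulateContactPairs <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(.substream(config@seed, 202L))
  L <- config@genomeLength
  chromNames <- paste0("chr", seq_len(config@nChroms))
  joint <- solveJointBernoulli(max(config@p1, 1e-9), max(config@p2, 1e-9),
                               config@oddsRatio)

  ## --- background pairs: rejection sampling against structure weights
  n <- config@nPairs
  keptC <- character(0); keptP1 <- keptP2 <- numeric(0)
  wmax <- max(config@tadBoost, 1) * max(config@compartmentBoost, 1)
  while (length(keptP1) < n && n > 0) {
    m <- max(2L * (n - length(keptP1)), 1000L)
    s <- .sampleDecayDistances(m, config@minDistance,
                               min(config@maxDistance, L - 1),
                               config@decayExponent)
    chrom <- sample(chromNames, m, replace = TRUE)
    pos1 <- floor(runif(m) * (L - s))
    pos2 <- pos1 + s
    w <- rep(1, m)
    sameTad <- .tadSegment(pos1, config@tadBoundaries) ==
      .tadSegment(pos2, config@tadBoundaries)
    w[sameTad] <- w[sameTad] * config@tadBoost
    sameComp <- .compartmentLabelOf(pos1, config@compartmentBin) ==
      .compartmentLabelOf(pos2, config@compartmentBin)
    w[sameComp] <- w[sameComp] * config@compartmentBoost
    acc <- runif(m) < w / wmax
    keptC <- c(keptC, chrom[acc])
    keptP1 <- c(keptP1, pos1[acc]); keptP2 <- c(keptP2, pos2[acc])
  }
  if (n > 0) {
    keptC <- keptC[seq_len(n)]
    keptP1 <- keptP1[seq_len(n)]; keptP2 <- keptP2[seq_len(n)]
  }
  bg <- data.frame(
    read_id = if (n > 0) sprintf("sim_bg_%06d", seq_len(n)) else character(),
    chrom1 = keptC, pos1 = keptP1,
    strand1 = if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(),
    chrom2 = keptC, pos2 = keptP2,
    strand2 = if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(),
    stringsAsFactors = FALSE)

  ## --- anchored pairs with latent joint-Bernoulli states
  na <- config@nAnchoredPairs
  truthAnchored <- data.frame(read_id = character(), labelA = character(),
                              labelB = character(), chrom = character(),
                              anchorPosA = numeric(), anchorPosB = numeric(),
                              readStartA = numeric(), readStartB = numeric(),
                              openA = logical(), openB = logical(),
                              stringsAsFactors = FALSE)
  anch <- bg[0, ]
  if (na > 0) {
    if (!nrow(config@anchorPairs))
      stop("nAnchoredPairs > 0 requires anchorPairs in the config")
    pairIdx <- rep_len(seq_len(nrow(config@anchorPairs)), na)
    fa <- config@anchorFeatures[config@anchorPairs[pairIdx, 1], ]
    fb <- config@anchorFeatures[config@anchorPairs[pairIdx, 2], ]
    ## latent states from the joint law
    u <- runif(na)
    cell <- findInterval(u, cumsum(joint)[1:3]) + 1L  # 1=11,2=10,3=01,4=00
    openA <- cell %in% c(1L, 2L)
    openB <- cell %in% c(1L, 3L)
    half <- floor(config@readLen / 2)
    jit <- function(k) round(runif(k, -20, 20))
    rsA <- pmax(0, fa$pos - half + jit(na))
    rsB <- pmax(0, fb$pos - half + jit(na))
    ids <- sprintf("sim_anchored_%06d", seq_len(na))
    anch <- data.frame(
      read_id = ids, chrom1 = fa$chrom, pos1 = rsA,
      strand1 = sample(c("+", "-"), na, replace = TRUE),
      chrom2 = fb$chrom, pos2 = rsB,
      strand2 = sample(c("+", "-"), na, replace = TRUE),
      stringsAsFactors = FALSE)
    truthAnchored <- data.frame(
      read_id = ids, labelA = fa$label, labelB = fb$label,
      chrom = fa$chrom, anchorPosA = fa$pos, anchorPosB = fb$pos,
      readStartA = rsA, readStartB = rsB,
      openA = openA, openB = openB, stringsAsFactors = FALSE)
  }

  all <- rbind(bg, anch)
  all$fend1 <- rep(NA_integer_, nrow(all))
  all$fend2 <- rep(NA_integer_, nrow(all))
  nComp <- ceiling(L / config@compartmentBin)
  list(pairs = ContactPairs(all),
       truth = list(anchored = truthAnchored,
                    joint = joint,
                    tadBoundaries = config@tadBoundaries,
                    compartmentLabels = .compartmentLabelOf(
                      (seq_len(nComp) - 1) * config@compartmentBin,
                      config@compartmentBin),
                    compartmentBin = config@compartmentBin))
}

## informative + strand cytosine positions (0-based) of a context in one
## chromosome sequence, by exact dinucleotide scan + flank classification
.contextPositions <- function(seqstr, context = c("GCH", "HCG")) {
  context <- match.arg(context)
  s <- as.character(seqstr)
  di <- if (context == "GCH") "GC" else "CG"
  hits <- start(matchPattern(di, DNAString(s)))  # 1-based start of dinuc
  if (!length(hits)) return(integer(0))
  cpos <- if (context == "GCH") hits + 1L else hits  # 1-based C position
  prevB <- substring(s, cpos - 1L, cpos - 1L)
  nextB <- substring(s, cpos + 1L, cpos + 1L)
  keep <- if (context == "GCH") prevB == "G" & nextB != "G" & nextB != ""
          else prevB != "G" & prevB != "" & nextB == "G"
  sort(cpos[keep]) - 1L  # 0-based
}

## indices of sorted positions falling in [start, end) per range
.positionsInRanges <- function(sortedPos, starts, ends) {
  lo <- findInterval(starts - 0.5, sortedPos) + 1L
  hi <- findInterval(ends - 0.5, sortedPos)
  cnt <- pmax(hi - lo + 1L, 0L)
  idx <- sequence(cnt, from = lo)
  list(range = rep(seq_along(starts), cnt), posIdx = idx)
}

#' Simulate per-read methylation calls for contact pairs
#'
#' Each mate emits GCH (accessibility) calls at the genome's informative
#' GpC positions within \code{readLen} of its mapped position, and HCG
#' (endogenous CpG) calls at informative CpG positions. Anchored mates
#' emit calls according to their latent open/closed state
#' (\code{pMethGivenOpen} / \code{pMethGivenClosed}); background mates
#' draw a latent state with \code{backgroundOpenProb}. HCG calls are
#' methylated with \code{cpgMethBaseline}. Conversion failure epsilon
#' flips truly-unmethylated calls to methylated, and symmetrically
#' methylated calls to unmethylated (detection failure).
#'
#' @param config A \linkS4class{SimConfig}.
#' @param pairs,truth output of \code{\link{simulateContactPairs}}.
#' @param genome optional \code{DNAStringSet}; regenerated from the
#'   config seed when missing.
#' @return A \linkS4class{MethCallTable}. Mate 1 rows belong to the read
#'   at the first anchor (or pair side 1), mate 2 to the second.
#' @export
simulateReadMethCalls <- function(config, pairs, truth, genome = NULL) {
  stopifnot(is(config, "SimConfig"), is(pairs, "ContactPairs"))
  if (is.null(genome)) genome <- simulateGenome(config)
  set.seed(.substream(config@seed, 303L))

  gch <- lapply(seq_along(genome), function(i) .contextPositions(genome[[i]], "GCH"))
  hcg <- lapply(seq_along(genome), function(i) .contextPositions(genome[[i]], "HCG"))
  names(gch) <- names(hcg) <- names(genome)

  df <- contactPairs(pairs)
  anchoredIds <- truth$anchored$read_id
  isAnch <- df$read_id %in% anchoredIds

  ## reads: anchored mates use truth read starts (immune to canonical
  ## side swapping); background mates use the pair sides
  mkReads <- function() {
    bgdf <- df[!isAnch, ]
    bg <- data.frame(
      read_id = rep(bgdf$read_id, 2),
      mate = rep(c(1L, 2L), each = nrow(bgdf)),
      chrom = c(bgdf$chrom1, bgdf$chrom2),
      start = c(bgdf$pos1, bgdf$pos2),
      open = rep(NA, 2 * nrow(bgdf)), stringsAsFactors = FALSE)
    ta <- truth$anchored
    an <- data.frame(
      read_id = rep(ta$read_id, 2),
      mate = rep(c(1L, 2L), each = nrow(ta)),
      chrom = rep(ta$chrom, 2),
      start = c(ta$readStartA, ta$readStartB),
      open = c(ta$openA, ta$openB), stringsAsFactors = FALSE)
    rbind(bg, an)
  }
  reads <- mkReads()
  if (!nrow(reads)) return(MethCallTable())
  nbg <- sum(is.na(reads$open))
  reads$open[is.na(reads$open)] <- runif(nbg) < config@backgroundOpenProb

  eps <- config@conversionFailure
  emit <- function(posList, context, pMeth) {
    out <- vector("list", length(genome))
    for (ci in seq_along(genome)) {
      chr <- names(genome)[ci]
      sel <- which(reads$chrom == chr)
      if (!length(sel)) next
      hitIdx <- .positionsInRanges(posList[[chr]], reads$start[sel],
                                   reads$start[sel] + config@readLen)
      if (!length(hitIdx$range)) next
      r <- sel[hitIdx$range]
      p <- pMeth(reads$open[r])
      meth <- runif(length(r)) < p
      ## epsilon: unconverted (false methylated) and missed (false unmeth)
      flip <- runif(length(r)) < eps
      meth <- ifelse(flip, !meth, meth)
      out[[ci]] <- data.frame(
        read_id = reads$read_id[r], mate = reads$mate[r], chrom = chr,
        pos = posList[[chr]][hitIdx$posIdx], context = context,
        state = ifelse(meth, "methylated", "unmethylated"),
        source = "genomic", stringsAsFactors = FALSE)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
  gchCalls <- emit(gch, "GCH", function(open)
    ifelse(open, config@pMethGivenOpen, config@pMethGivenClosed))
  hcgCalls <- emit(hcg, "HCG", function(open)
    rep(config@cpgMethBaseline, length(open)))
  calls <- rbind(gchCalls, hcgCalls)
  if (is.null(calls)) return(MethCallTable())
  calls <- calls[order(calls$chrom, calls$pos, calls$read_id, calls$mate), ]
  MethCallTable(calls)
}

#' Simulate bisulfite spike-in control calls
#'
#' Emulates conversion-control templates: on an unmethylated template
#' (lambda DNA) each cytosine call is read methylated with probability
#' epsilon (conversion failure); on a fully methylated template (pUC19 or
#' in-situ-methylated lambda) each call is read unmethylated with
#' probability epsilon (detection failure).
#'
#' @param nCalls number of calls to simulate (> 0).
#' @param epsilon failure probability, in [0, 1].
#' @param methylated logical: is the template fully methylated?
#' @param seed integer seed.
#' @param context call context, "HCG" (CpG channel) or "GCH".
#' @param source spike-in source label.
#' @return A \linkS4class{MethCallTable} with spike-in source labels.
#' @examples
#' qc <- conversionQC(simulateSpikein(1000, 0.02, seed = 1))
#' @export
simulateSpikein <- function(nCalls, epsilon, methylated = FALSE, seed = 1L,
                            context = "HCG",
                            source = if (methylated) "puc19_spikein"
                                     else "lambda_spikein") {
  stopifnot(nCalls > 0, epsilon >= 0, epsilon <= 1)
  set.seed(as.integer(seed))
  fail <- runif(nCalls) < epsilon
  state <- if (methylated) ifelse(fail, "unmethylated", "methylated")
           else ifelse(fail, "methylated", "unmethylated")
  MethCallTable(data.frame(
    read_id = sprintf("spike_%06d", seq_len(nCalls)),
    mate = 1L, chrom = if (methylated) "pUC19" else "lambda",
    pos = seq_len(nCalls) - 1L, context = context, state = state,
    source = source, stringsAsFactors = FALSE))
}

#' Construct a BinnedContactMatrix
#'
#' @param chrom chromosome name.
#' @param binSize bin size in bp.
#' @param counts square symmetric non-negative matrix.
#' @param chromLength chromosome length in bp; defaults to
#'   \code{nrow(counts) * binSize}.
#' @return A validated \linkS4class{BinnedContactMatrix}.
#' @export
BinnedContactMatrix <- function(chrom, binSize, counts,
                                chromLength = nrow(counts) * binSize) {
  new("BinnedContactMatrix", chrom = chrom, binSize = binSize,
      counts = counts, chromLength = chromLength)
}

#' Simulate a checkerboard compartment contact matrix
#'
#' Constructs a binned cis contact matrix whose expected counts follow a
#' power-law distance decay multiplied by a compartment checkerboard:
#' same-label bin pairs carry \code{contrast} times the contacts of
#' cross-label pairs. Optional Poisson noise. Used for planted-truth
#' recovery tests of the compartment eigenvector and strength.
#'
#' @param nBins number of bins.
#' @param binSize bin size in bp.
#' @param contrast same-label / cross-label contact ratio (>= 1).
#' @param blockSize bins per alternating A/B block; ignored when
#'   \code{labels} is given.
#' @param labels optional explicit "A"/"B" label vector (length nBins),
#'   e.g. irregular block sizes as in real chromosomes.
#' @param alpha distance-decay exponent.
#' @param depth expected counts on the near diagonal.
#' @param noise "none" for the expected matrix itself, "poisson" for
#'   Poisson-sampled counts.
#' @param seed seed used when \code{noise = "poisson"}.
#' @return list(matrix = \linkS4class{BinnedContactMatrix},
#'   labels = character vector of planted "A"/"B" labels).
#' @export
simulateCheckerboard <- function(nBins = 100L, binSize = 250000,
                                 contrast = 2, blockSize = 5L,
                                 labels = NULL,
                                 alpha = 0.5, depth = 100,
                                 noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(labels))
    labels <- ifelse((floor((seq_len(nBins) - 1) / blockSize) %% 2) == 0,
                     "A", "B")
  stopifnot(length(labels) == nBins)
  d <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
  base <- depth * pmax(d, 1)^(-alpha)
  same <- outer(labels, labels, "==")
  m <- base * ifelse(same, contrast, 1)
  if (noise == "poisson") {
    set.seed(as.integer(seed))
    up <- upper.tri(m, diag = TRUE)
    m[up] <- stats::rpois(sum(up), m[up])
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
  }
  list(matrix = BinnedContactMatrix("chrS", binSize, m), labels = labels)
}
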