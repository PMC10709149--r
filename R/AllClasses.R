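## S4 containers. Tables are kept as plain data.frames inside lightweight
## S4 wrappers with schema validity checks; genomic intervals use GRanges.

.METH_CONTEXTS <- c("HCG", "GCH", "GCG_ambiguous", "other")
.METH_STATES <- c("methylated", "unmethylated")
.CALL_SOURCES <- c("genomic", "lambda_spikein", "puc19_spikein")

.METHCALL_COLS <- c("read_id", "mate", "chrom", "pos", "context",
                    "state", "source")
.PAIR_COLS <- c("read_id", "chrom1", "pos1", "strand1",
                "chrom2", "pos2", "strand2", "fend1", "fend2")

#' MethCallTable: per-read cytosine methylation calls
#'
#' One row per (read id, mate, position) methylation call, carrying the
#' NOMe sequence context (HCG = endogenous CpG channel, GCH = GpC
#' accessibility channel, GCG_ambiguous = excluded, other = uninformative)
#' and the called state. Spike-in rows are labelled by source and never
#' enter genomic tracks.
#'
#' @slot calls data.frame with columns \code{read_id}, \code{mate} (1 or
#'   2), \code{chrom}, \code{pos} (0-based bp), \code{context},
#'   \code{state}, \code{source}.
#' @export
setClass("MethCallTable", slots = c(calls = "data.frame"))

setValidity("MethCallTable", function(object) {
  df <- object@calls
  if (!all(.METHCALL_COLS %in% names(df)))
    return(paste("missing columns:",
                 paste(setdiff(.METHCALL_COLS, names(df)), collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$mate %in% c(1L, 2L))) return("mate must be 1 or 2")
    if (!all(df$context %in% .METH_CONTEXTS)) return("unknown context value")
    if (!all(df$state %in% .METH_STATES)) return("unknown state value")
    if (!all(df$source %in% .CALL_SOURCES)) return("unknown source value")
    if (any(df$pos < 0)) return("pos must be >= 0 (0-based)")
  }
  TRUE
})

#' Construct a MethCallTable
#'
#' @param calls data.frame with the MethCallTable schema (see
#'   \linkS4class{MethCallTable}).
#' @return A \linkS4class{MethCallTable}.
#' @export
MethCallTable <- function(calls = data.frame(
    read_id = character(), mate = integer(), chrom = character(),
    pos = integer(), context = character(), state = character(),
    source = character())) {
  calls$mate <- as.integer(calls$mate)
  calls$pos <- as.integer(calls$pos)
  rownames(calls) <- NULL
  new("MethCallTable", calls = calls[, .METHCALL_COLS, drop = FALSE])
}

#' @describeIn MethCallTable-class Underlying data.frame of calls.
#' @param x,object A MethCallTable.
#' @export
setGeneric("methCalls", function(x) standardGeneric("methCalls"))

#' @rdname MethCallTable-class
#' @export
setMethod("methCalls", "MethCallTable", function(x) x@calls)

#' @rdname MethCallTable-class
#' @export
setMethod("length", "MethCallTable", function(x) nrow(x@calls))

setMethod("show", "MethCallTable", function(object) {
  df <- object@calls
  cat("MethCallTable with", nrow(df), "calls\n")
  if (nrow(df)) {
    cat("  contexts:", paste(sprintf("%s=%d", names(table(df$context)),
                                     table(df$context)), collapse = " "), "\n")
    cat("  sources: ", paste(unique(df$source), collapse = ", "), "\n")
  }
})

#' ContactPairs: deduplicable ligation pair table
#'
#' One row per proximity-ligation product: two sides with chromosome,
#' 0-based position, strand, and (once assigned) restriction fragment-end
#' (fend) index. Rows are kept in canonical order: (chrom1, pos1) <=
#' (chrom2, pos2).
#'
#' @slot pairs data.frame with columns \code{read_id}, \code{chrom1},
#'   \code{pos1}, \code{strand1}, \code{chrom2}, \code{pos2},
#'   \code{strand2}, \code{fend1}, \code{fend2}.
#' @export
setClass("ContactPairs", slots = c(pairs = "data.frame"))

setValidity("ContactPairs", function(object) {
  df <- object@pairs
  if (!all(.PAIR_COLS %in% names(df)))
    return(paste("missing columns:",
                 paste(setdiff(.PAIR_COLS, names(df)), collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$strand1 %in% c("+", "-") & df$strand2 %in% c("+", "-")))
      return("strands must be '+' or '-'")
    bad <- df$chrom1 > df$chrom2 |
      (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
    if (any(bad)) return("pairs must be in canonical (chrom1,pos1) <= (chrom2,pos2) order")
  }
  TRUE
})

.canonicalizePairs <- function(df) {
  flip <- df$chrom1 > df$chrom2 |
    (df$chrom1 == df$chrom2 & df$pos1 > df$pos2)
  if (any(flip)) {
    sw <- function(a, b) {
      tmp <- df[[a]][flip]; df[[a]][flip] <<- df[[b]][flip]
      df[[b]][flip] <<- tmp
    }
    sw("chrom1", "chrom2"); sw("pos1", "pos2")
    sw("strand1", "strand2"); sw("fend1", "fend2")
  }
  df
}

#' Construct a ContactPairs table
#'
#' Sides are swapped where needed so that every row satisfies the
#' canonical (chrom1, pos1) <= (chrom2, pos2) ordering.
#'
#' @param pairs data.frame with the ContactPairs schema; \code{fend1},
#'   \code{fend2} may be NA before \code{\link{assignFends}}.
#' @return A \linkS4class{ContactPairs}.
#' @export
ContactPairs <- function(pairs = data.frame(
    read_id = character(), chrom1 = character(), pos1 = integer(),
    strand1 = character(), chrom2 = character(), pos2 = integer(),
    strand2 = character(), fend1 = integer(), fend2 = integer())) {
  if (is.null(pairs$fend1)) pairs$fend1 <- NA_integer_
  if (is.null(pairs$fend2)) pairs$fend2 <- NA_integer_
  pairs$pos1 <- as.integer(pairs$pos1)
  pairs$pos2 <- as.integer(pairs$pos2)
  pairs <- .canonicalizePairs(pairs)
  rownames(pairs) <- NULL
  new("ContactPairs", pairs = pairs[, .PAIR_COLS, drop = FALSE])
}

#' @describeIn ContactPairs-class Underlying data.frame of pairs.
#' @param x,object A ContactPairs object.
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname ContactPairs-class
#' @export
setMethod("contactPairs", "ContactPairs", function(x) x@pairs)

#' @rdname ContactPairs-class
#' @export
setMethod("length", "ContactPairs", function(x) nrow(x@pairs))

setMethod("show", "ContactPairs", function(object) {
  df <- object@pairs
  ncis <- sum(df$chrom1 == df$chrom2)
  cat("ContactPairs with", nrow(df), "pairs (", ncis, "cis )\n")
  if (nrow(df))
    cat("  fends assigned:", !anyNA(df$fend1), "\n")
})

#' FragmentIndex: restriction cut-site index
#'
#' Sorted cut-site coordinates per chromosome (0-based position of the
#' first base of the recognition motif). Each cut site carries two fends,
#' one per side; see \code{\link{assignFends}} for the numbering.
#'
#' @slot cutSites named list of strictly increasing integer vectors.
#' @slot motif recognition motif (e.g. "GATC").
#' @slot chromLengths named numeric vector of chromosome lengths.
#' @export
setClass("FragmentIndex",
         slots = c(cutSites = "list", motif = "character",
                   chromLengths = "numeric"))

setValidity("FragmentIndex", function(object) {
  if (!identical(sort(names(object@cutSites)),
                 sort(names(object@chromLengths))))
    return("cutSites and chromLengths must cover the same chromosomes")
  for (chr in names(object@cutSites)) {
    cs <- object@cutSites[[chr]]
    if (is.unsorted(cs, strictly = TRUE))
      return(paste("cut sites not strictly increasing on", chr))
    if (length(cs) && (cs[1] < 0 || cs[length(cs)] >= object@chromLengths[[chr]]))
      return(paste("cut sites outside chromosome on", chr))
  }
  TRUE
})

setMethod("show", "FragmentIndex", function(object) {
  cat("FragmentIndex (motif ", object@motif, ") over ",
      length(object@cutSites), " chromosome(s); ",
      sum(lengths(object@cutSites)), " cut sites\n", sep = "")
})

#' @describeIn FragmentIndex-class Cut-site list accessor.
#' @param x,object A FragmentIndex.
#' @export
setGeneric("cutSites", function(x) standardGeneric("cutSites"))

#' @rdname FragmentIndex-class
#' @export
setMethod("cutSites", "FragmentIndex", function(x) x@cutSites)

#' BinnedContactMatrix: per-chromosome binned cis contacts
#'
#' Symmetric count matrix at a fixed bin size for one chromosome, the
#' substrate for insulation, compartment and pileup statistics. The
#' distance-stratified expected model is computed by
#' \code{\link{expectedCounts}}.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin size in bp.
#' @slot counts symmetric numeric matrix of contact counts.
#' @slot chromLength chromosome length in bp.
#' @export
setClass("BinnedContactMatrix",
         slots = c(chrom = "character", binSize = "numeric",
                   counts = "matrix", chromLength = "numeric"))

setValidity("BinnedContactMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) return("counts must be symmetric")
  if (nrow(m) != ceiling(object@chromLength / object@binSize))
    return("dimension must equal ceiling(chromLength / binSize)")
  TRUE
})

setMethod("show", "BinnedContactMatrix", function(object) {
  cat("BinnedContactMatrix ", object@chrom, ": ", nrow(object@counts),
      " bins @ ", object@binSize, " bp; ", sum(object@counts) / 2,
      " contacts\n", sep = "")
})

#' @describeIn BinnedContactMatrix-class Count matrix accessor.
#' @param x,object A BinnedContactMatrix.
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname BinnedContactMatrix-class
#' @export
setMethod("contactCounts", "BinnedContactMatrix", function(x) x@counts)

#' @describeIn BinnedContactMatrix-class Bin size accessor.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedContactMatrix-class
#' @export
setMethod("binSize", "BinnedContactMatrix", function(x) x@binSize)

#' CoAccessibilityResult: single-molecule dependence test result
#'
#' Holds the paired per-read observation matrix, k-means clustering,
#' the 2x2 open/closed contingency table, the cross-product odds ratio
#' with two-sided Fisher exact p-value, and the co-accessible fraction
#' (both threshold-derived and top-cluster-derived), plus an optional
#' randomized-control counterpart.
#'
#' @slot observations data.frame of paired read observations (one row per
#'   qualifying read pair).
#' @slot clusters integer cluster assignment per observation (labels 1..k
#'   ordered by descending cluster grand mean), or empty if not clustered.
#' @slot clusterMeans matrix of per-cluster (meanA, meanB) centroids.
#' @slot table 2x2 contingency matrix (rows: mate A open/closed, cols:
#'   mate B open/closed).
#' @slot oddsRatio cross-product odds ratio (Haldane-Anscombe corrected
#'   when a cell is zero; NA when a margin is zero).
#' @slot pValue two-sided Fisher exact p-value.
#' @slot coAccessibleFraction percent of observations open/open by the
#'   binarization threshold.
#' @slot coAccessibleFractionCluster percent of observations in the top
#'   k-means cluster.
#' @slot nExcluded observations excluded by the min-calls filter.
#' @slot control a CoAccessibilityResult for the randomized control, or
#'   NULL.
#' @export
setClass("CoAccessibilityResult",
         slots = c(observations = "data.frame", clusters = "integer",
                   clusterMeans = "matrix", table = "matrix",
                   oddsRatio = "numeric", pValue = "numeric",
                   coAccessibleFraction = "numeric",
                   coAccessibleFractionCluster = "numeric",
                   nExcluded = "integer", control = "ANY"))

setValidity("CoAccessibilityResult", function(object) {
  tb <- object@table
  if (!all(dim(tb) == c(2, 2))) return("table must be 2x2")
  if (sum(tb) + object@nExcluded != nrow(object@observations))
    return("contingency cells plus exclusions must sum to the observation count")
  if (length(object@clusters) &&
      length(object@clusters) != nrow(object@observations))
    return("one cluster label per observation required")
  TRUE
})

setMethod("show", "CoAccessibilityResult", function(object) {
  cat("CoAccessibilityResult: ", nrow(object@observations),
      " read-pair observations\n", sep = "")
  cat("  odds ratio ", signif(object@oddsRatio, 4),
      ", Fisher p ", signif(object@pValue, 3), "\n", sep = "")
  cat("  co-accessible: ", round(object@coAccessibleFraction, 1),
      "% (threshold), ", round(object@coAccessibleFractionCluster, 1),
      "% (top cluster)\n", sep = "")
  if (!is.null(object@control))
    cat("  randomized control: ",
        round(object@control@coAccessibleFraction, 1), "% co-accessible\n",
        sep = "")
})

#' @describeIn CoAccessibilityResult-class Odds ratio accessor.
#' @param x,object A CoAccessibilityResult.
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname CoAccessibilityResult-class
#' @export
setMethod("oddsRatio", "CoAccessibilityResult", function(x) x@oddsRatio)

#' @describeIn CoAccessibilityResult-class Fisher p-value accessor.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname CoAccessibilityResult-class
#' @export
setMethod("pValue", "CoAccessibilityResult", function(x) x@pValue)

#' @describeIn CoAccessibilityResult-class 2x2 contingency table accessor.
#' @export
setGeneric("contingencyTable", function(x) standardGeneric("contingencyTable"))

#' @rdname CoAccessibilityResult-class
#' @export
setMethod("contingencyTable", "CoAccessibilityResult", function(x) x@table)

#' @describeIn CoAccessibilityResult-class Observation matrix accessor.
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname CoAccessibilityResult-class
#' @export
setMethod("observations", "CoAccessibilityResult", function(x) x@observations)

#' @describeIn CoAccessibilityResult-class Cluster assignments accessor.
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname CoAccessibilityResult-class
#' @export
setMethod("clusterAssignments", "CoAccessibilityResult",
          function(x) x@clusters)
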