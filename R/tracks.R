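## Bulk-level aggregation: coverage-filtered cytosine pileups, spike-in
## conversion QC, and strand-aware feature-centred metaprofiles.

#' Pile up methylation calls per cytosine with a coverage floor
#'
#' Aggregates genomic calls of one context into per-position counts and
#' methylated fractions. Positions below the coverage floor are absent
#' from the output (the customary floors are 5x for individual replicates
#' and 10x for merged replicates). GCG_ambiguous calls never contribute,
#' and spike-in calls are excluded.
#'
#' @param calls a \linkS4class{MethCallTable}.
#' @param context "GCH" (accessibility) or "HCG" (CpG methylation).
#' @param minCov minimum total calls per position (>= 1).
#' @return data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{context}, \code{n_meth}, \code{n_total}, \code{fraction}.
#' @examples
#' ## a position covered 4x vanishes under the 5x floor
#' @export
pileupCalls <- function(calls, context = c("GCH", "HCG"), minCov = 5L) {
  context <- match.arg(context)
  stopifnot(minCov >= 1)
  df <- methCalls(calls)
  df <- df[df$source == "genomic" & df$context == context, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(chrom = character(), pos = integer(),
                      context = character(), n_meth = integer(),
                      n_total = integer(), fraction = numeric()))
  key <- paste(df$chrom, df$pos)
  meth <- rowsum((df$state == "methylated") + 0L, key)
  tot <- rowsum(rep(1L, nrow(df)), key)
  keyParts <- do.call(rbind, strsplit(rownames(meth), " ", fixed = TRUE))
  out <- data.frame(chrom = keyParts[, 1], pos = as.integer(keyParts[, 2]),
                    context = context, n_meth = as.integer(meth),
                    n_total = as.integer(tot), stringsAsFactors = FALSE)
  out <- out[out$n_total >= minCov, , drop = FALSE]
  out$fraction <- out$n_meth / out$n_total
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bisulfite conversion QC from spike-in controls
#'
#' Conversion efficiency is the percentage of unmethylated calls among
#' CpG (HCG) calls on the unmethylated lambda spike-in: a failed
#' conversion leaves the cytosine reading methylated. The detection rate
#' is the percentage of methylated calls on fully methylated controls
#' (pUC19, and GCH calls on in-situ-GpC-methylated lambda), measuring the
#' false-negative rate of methylation detection.
#'
#' @param calls a \linkS4class{MethCallTable} containing spike-in rows.
#' @return list with \code{conversion_efficiency} and
#'   \code{detection_rate} (percent), and the call counts behind each.
#'   Missing methylated controls give a \code{detection_rate} of NA with
#'   a warning; missing lambda CpG calls are an error.
#' @export
conversionQC <- function(calls) {
  df <- methCalls(calls)
  conv <- df[df$source == "lambda_spikein" & df$context == "HCG", ,
             drop = FALSE]
  if (!nrow(conv))
    stop("conversion QC requires lambda spike-in CpG (HCG) calls")
  convEff <- 100 * mean(conv$state == "unmethylated")
  det <- df[df$source == "puc19_spikein" |
            (df$source == "lambda_spikein" & df$context == "GCH"), ,
            drop = FALSE]
  detRate <- if (nrow(det)) 100 * mean(det$state == "methylated") else {
    warning("no methylated-control calls (puc19_spikein / lambda GCH); ",
            "detection rate is NA")
    NA_real_
  }
  list(conversion_efficiency = convEff, detection_rate = detRate,
       n_conversion_calls = nrow(conv), n_detection_calls = nrow(det))
}

#' Feature-centred metaprofile of a methylation or accessibility track
#'
#' Averages a per-cytosine fraction track in fixed-width bins across
#' windows centred on genomic features. Minus-strand features are
#' column-reversed when \code{flipByStrand}, so profiles read 5' to 3'.
#' Bins with no covered cytosine are missing (NA), not zero: absence of
#' coverage is not a biological zero. The per-bin mean profile ignores
#' missing cells; features are weighted equally.
#'
#' @param x either a pileup data.frame (from \code{\link{pileupCalls}})
#'   or a \linkS4class{MethCallTable} (then piled up with
#'   \code{minCov}).
#' @param features \code{GRanges} of features; strand used for flipping.
#' @param window half-window in bp around each feature midpoint.
#' @param binSize bin width in bp; \code{window} must be a multiple.
#' @param flipByStrand reverse columns of minus-strand features.
#' @param context,minCov used only when \code{x} is a MethCallTable.
#' @return list with \code{matrix} (features x bins), \code{profile}
#'   (per-bin mean) and \code{binCenters} (bp relative to midpoint).
#' @export
metaprofile <- function(x, features, window = 500L, binSize = 5L,
                        flipByStrand = TRUE, context = "GCH",
                        minCov = 1L) {
  if (window %% binSize != 0) stop("window must be a multiple of binSize")
  pile <- if (is(x, "MethCallTable")) pileupCalls(x, context, minCov) else x
  stopifnot(is(features, "GRanges"))
  nb <- as.integer(2 * window / binSize)
  mat <- matrix(NA_real_, nrow = length(features), ncol = nb)
  if (length(features)) {
    mids <- floor((start(features) + end(features)) / 2) - 1L  # 0-based
    chroms <- as.character(seqnames(features))
    strands <- as.character(strand(features))
    for (i in seq_along(features)) {
      sel <- pile$chrom == chroms[i] &
        pile$pos >= mids[i] - window & pile$pos < mids[i] + window
      if (!any(sel)) next
      rel <- pile$pos[sel] - (mids[i] - window)
      b <- floor(rel / binSize) + 1L
      mat[i, ] <- as.numeric(
        tapply(pile$fraction[sel], factor(b, levels = seq_len(nb)),
               mean))
      if (flipByStrand && strands[i] == "-")
        mat[i, ] <- rev(mat[i, ])
    }
  }
  profile <- colMeans(mat, na.rm = TRUE)
  profile[is.nan(profile)] <- NA_real_
  list(matrix = mat, profile = profile,
       binCenters = seq(-window + binSize / 2, window - binSize / 2,
                        by = binSize))
}
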