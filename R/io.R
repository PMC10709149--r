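## Text-format plumbing: 4DN-style .pairs, methylation-call TSV, BED
## features, bedGraph tracks, FASTA genomes, JSON reports.

.SCHEMA_VERSION <- "1.0"

#' Write contact pairs in 4DN-style .pairs text format
#'
#' Tab-separated with the standard \code{## pairs format v1.0} and
#' \code{#columns:} header lines; positions are written 1-based per the
#' pairs convention (internal coordinates are 0-based).
#'
#' @param pairs a \linkS4class{ContactPairs}.
#' @param path output path.
#' @export
writePairs <- function(pairs, path) {
  df <- contactPairs(pairs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("## pairs format v1.0",
               "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2"),
             con)
  out <- data.frame(df$read_id, df$chrom1, df$pos1 + 1L, df$chrom2,
                    df$pos2 + 1L, df$strand1, df$strand2)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a 4DN-style .pairs file
#'
#' @param path input path.
#' @return A \linkS4class{ContactPairs} (positions converted to
#'   0-based; fends unassigned).
#' @export
readPairs <- function(path) {
  lines <- readLines(path, n = 50)
  skip <- sum(startsWith(lines, "#"))
  df <- read.delim(path, header = FALSE, skip = skip,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop("pairs file needs 7 columns: ", path)
  names(df)[1:7] <- c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                      "strand1", "strand2")
  df$pos1 <- df$pos1 - 1L
  df$pos2 <- df$pos2 - 1L
  ContactPairs(df[, c("read_id", "chrom1", "pos1", "strand1",
                      "chrom2", "pos2", "strand2")])
}

#' Write a methylation-call table as TSV
#'
#' Mirrors common methylation-extractor output: a 1-based position
#' column, one row per call, with a \code{#schema_version} header line.
#'
#' @param calls a \linkS4class{MethCallTable}.
#' @param path output path.
#' @export
writeMethCalls <- function(calls, path) {
  df <- methCalls(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema_version=", .SCHEMA_VERSION), con)
  out <- data.frame(read_id = df$read_id, mate = df$mate,
                    chrom = df$chrom, pos_1based = df$pos + 1L,
                    context = df$context, state = df$state,
                    source = df$source)
  suppressWarnings(
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Read a methylation-call TSV
#'
#' Rejects files whose \code{#schema_version} major version is unknown.
#'
#' @param path input path.
#' @return A \linkS4class{MethCallTable}.
#' @export
readMethCalls <- function(path) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (startsWith(first, "#schema_version=")) {
    ver <- sub("#schema_version=", "", first)
    if (strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
        strsplit(.SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1])
      stop("unsupported schema version ", ver, " in ", path)
    skip <- 1L
  }
  df <- read.delim(path, skip = skip, stringsAsFactors = FALSE)
  need <- c("read_id", "mate", "chrom", "pos_1based", "context",
            "state", "source")
  if (!all(need %in% names(df)))
    stop("malformed methylation-call TSV (line ", skip + 1, "): ",
         "missing ", paste(setdiff(need, names(df)), collapse = ", "))
  df$pos <- df$pos_1based - 1L
  MethCallTable(df[, c("read_id", "mate", "chrom", "pos", "context",
                       "state", "source")])
}

#' Write genomic features as BED6
#'
#' @param gr \code{GRanges}; names (or \code{mcols(gr)$label}) become
#'   the BED name column.
#' @param path output path.
#' @export
writeFeaturesBed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$label)) mcols(gr)$label
        else if (!is.null(names(gr))) names(gr)
        else paste0("feature_", seq_along(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  out <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                    nm, 0L, st)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a BED file into GRanges
#'
#' Accepts BED3 to BED6; the strand column, when present, is kept (used
#' by orientation rules).
#'
#' @param path input path.
#' @return \code{GRanges} with a \code{label} metadata column.
#' @export
readFeaturesBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  gr <- GRanges(df[[1]],
                IRanges(start = df[[2]] + 1L, end = df[[3]]),
                strand = if (ncol(df) >= 6) {
                  s <- df[[6]]; s[!s %in% c("+", "-")] <- "*"; s
                } else "*")
  mcols(gr)$label <- if (ncol(df) >= 4) as.character(df[[4]])
                     else paste0("feature_", seq_len(nrow(df)))
  gr
}

#' Write a score track as bedGraph
#'
#' @param track data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and a score column.
#' @param path output path.
#' @param scoreCol name of the score column.
#' @param percent write scores multiplied by 100.
#' @export
writeBedGraph <- function(track, path, scoreCol = "score",
                          percent = FALSE) {
  sc <- track[[scoreCol]]
  if (percent) sc <- 100 * sc
  keep <- is.finite(sc)
  out <- data.frame(track$chrom[keep], track$start[keep],
                    track$end[keep], signif(sc[keep], 7))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a bedGraph track
#'
#' @param path input path.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{score}.
#' @export
readBedGraph <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  setNames(df[, 1:4], c("chrom", "start", "end", "score"))
}

#' Write a fragment index as BED3
#'
#' One record per cut site (the first base of the recognition motif).
#'
#' @param index a \linkS4class{FragmentIndex}.
#' @param path output path.
#' @export
writeFragmentIndexBed <- function(index, path) {
  rows <- lapply(names(cutSites(index)), function(chr) {
    cs <- cutSites(index)[[chr]]
    if (!length(cs)) return(NULL)
    data.frame(chr, cs, cs + nchar(index@motif))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Serialize a CoAccessibilityResult to a stats list / JSON file
#'
#' @param result a \linkS4class{CoAccessibilityResult}.
#' @param path optional JSON output path.
#' @return the stats list, invisibly when writing.
#' @export
coAccessibilityStats <- function(result, path = NULL) {
  asList <- function(r) list(
    n_pairs = nrow(observations(r)),
    table = contingencyTable(r),
    odds_ratio = oddsRatio(r),
    p_value = pValue(r),
    co_accessible_fraction = r@coAccessibleFraction,
    co_accessible_fraction_cluster = r@coAccessibleFractionCluster,
    n_excluded = r@nExcluded)
  out <- asList(result)
  if (!is.null(result@control)) out$control <- asList(result@control)
  if (!is.null(path)) {
    write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}
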