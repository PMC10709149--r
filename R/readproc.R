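## Pre-alignment chimeric-read splitting at bisulfite-converted DpnII
## ligation junctions, fragment-end (fend) transformation, contact
## deduplication and NOMe context classification.

#' Bisulfite-converted DpnII ligation-junction motifs
#'
#' The fill-in ligation junction of two DpnII half-sites (GATCGATC) after
#' bisulfite conversion, for forward- and reverse-strand reads, including
#' the variants where the endogenous C is unmethylated and therefore
#' converted to T.
#' @export
JUNCTION_MOTIFS <- c("GATTGATT", "GATTGATC", "AATCAATC", "GATCAATC")

.checkDNA <- function(seq) {
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains non-ACGTN characters")
  invisible(seq)
}

#' Find ligation-junction motifs in a read
#'
#' Scans an uppercase read sequence for exact (possibly overlapping)
#' occurrences of the converted ligation-junction 8-mers, left to right.
#'
#' @param seq uppercase DNA string (ACGTN).
#' @param motifs character vector of junction 8-mers; defaults to
#'   \code{JUNCTION_MOTIFS}.
#' @return data.frame with columns \code{offset} (0-based) and
#'   \code{motif}, ordered by offset; zero rows when no motif occurs.
#' @examples
#' findJunctionSites("AAGATTGATTCC")  # offset 2
#' @export
findJunctionSites <- function(seq, motifs = JUNCTION_MOTIFS) {
  .checkDNA(seq)
  hits <- lapply(motifs, function(m) {
    st <- start(matchPattern(m, DNAString(seq), fixed = TRUE))
    if (length(st)) data.frame(offset = st - 1L, motif = m,
                               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits))
    return(data.frame(offset = integer(), motif = character()))
  hits[order(hits$offset, hits$motif), , drop = FALSE]
}

#' Split a chimeric read at ligation junctions
#'
#' Cuts the read at the midpoint of every junction 8-mer so that each
#' product retains one 4-bp half-site (mirroring the two ligated DpnII
#' half-sites). Products shorter than \code{minLen} are dropped; a
#' junction-free read is returned unchanged under its original name.
#'
#' @param seq uppercase DNA string.
#' @param id read identifier; split products are named \code{id/s1},
#'   \code{id/s2}, ...
#' @param qual optional quality string of the same length, split in
#'   parallel.
#' @param motifs junction motifs (see \code{\link{findJunctionSites}}).
#' @param minLen minimum retained product length (bp); the default 20
#'   matches the usual adapter-trimming length floor.
#' @return data.frame with columns \code{read_id}, \code{sequence} and
#'   \code{qualities} (NA when \code{qual} is NULL).
#' @export
splitChimericRead <- function(seq, id = "read", qual = NULL,
                              motifs = JUNCTION_MOTIFS, minLen = 20L) {
  sites <- findJunctionSites(seq, motifs)
  if (!is.null(qual) && nchar(qual) != nchar(seq))
    stop("quality string length must equal sequence length")
  if (!nrow(sites))
    return(data.frame(read_id = id, sequence = seq,
                      qualities = if (is.null(qual)) NA_character_ else qual,
                      stringsAsFactors = FALSE))
  cuts <- sort(unique(sites$offset + 4L))         # 0-based first base right of cut
  starts <- c(0L, cuts); ends <- c(cuts, nchar(seq))
  keep <- ends - starts >= minLen
  seg <- function(x) substring(x, starts + 1L, ends)
  data.frame(
    read_id = paste0(id, "/s", seq_along(starts)),
    sequence = seg(seq),
    qualities = if (is.null(qual)) NA_character_ else seg(qual),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Split every read of a FASTQ file at ligation junctions
#'
#' @param infile,outfile FASTQ paths (4-line records).
#' @param motifs,minLen see \code{\link{splitChimericRead}}.
#' @return Invisibly, a named vector with the number of input reads,
#'   output products and dropped short products.
#' @export
splitJunctionsFastq <- function(infile, outfile, motifs = JUNCTION_MOTIFS,
                                minLen = 20L) {
  reads <- readDNAStringSet(infile, format = "fastq", with.qualities = TRUE)
  quals <- as.character(mcols(reads)$qualities)
  ids <- names(reads)
  seqs <- as.character(reads)
  out <- vector("list", length(reads))
  nSegments <- 0L
  for (i in seq_along(seqs)) {
    p <- splitChimericRead(seqs[i], ids[i], quals[i],
                           motifs = motifs, minLen = minLen)
    nSegments <- nSegments +
      length(unique(findJunctionSites(seqs[i], motifs)$offset + 4L)) + 1L
    out[[i]] <- p
  }
  out <- do.call(rbind, out)
  products <- DNAStringSet(out$sequence)
  names(products) <- out$read_id
  writeXStringSet(products, outfile, format = "fastq",
                  qualities = Biostrings::BStringSet(out$qualities))
  invisible(c(n_in = length(reads), n_out = nrow(out),
              n_dropped = nSegments - nrow(out)))
}

#' Build a restriction fragment index from a genome
#'
#' Records the 0-based position of the first base of every occurrence of
#' the restriction motif, per chromosome.
#'
#' @param genome \code{DNAStringSet} (named by chromosome).
#' @param motif recognition motif, default DpnII "GATC".
#' @return A \linkS4class{FragmentIndex}.
#' @export
buildFragmentIndex <- function(genome, motif = "GATC") {
  stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
  cut <- lapply(seq_along(genome), function(i)
    as.integer(start(matchPattern(motif, genome[[i]], fixed = TRUE)) - 1L))
  names(cut) <- names(genome)
  new("FragmentIndex", cutSites = cut, motif = motif,
      chromLengths = setNames(as.numeric(Biostrings::width(genome)),
                              names(genome)))
}

## per-chromosome fend numbering: cut site j (1-based) carries fends
## 2j-1 (upstream side) and 2j (downstream side); pseudo-fends 0 and
## 2n+1 take positions beyond the terminal cut sites. Global fend ids
## offset chromosomes so ids never collide.
.chromFendOffsets <- function(index) {
  n <- lengths(index@cutSites)
  off <- cumsum(c(0, 2 * n + 2))[seq_along(n)]
  setNames(off, names(index@cutSites))
}

#' Assign restriction fragment-end (fend) coordinates
#'
#' Projects read positions onto restriction fragment ends: a + strand
#' read maps to the nearest cut site at or downstream of its position
#' (taking that site's upstream-side fend), a - strand read to the
#' nearest cut site at or upstream (downstream-side fend). Positions
#' beyond the terminal cut site map to a chromosome-terminal pseudo-fend.
#' Fend ids are globally unique across chromosomes.
#'
#' @param chrom,pos,strand vectors describing read positions (0-based).
#' @param index a \linkS4class{FragmentIndex}.
#' @return Integer vector of global fend ids.
#' @examples
#' ## cut sites {100, 200}: (+,150) -> site 200 upstream side,
#' ## (-,150) -> site 100 downstream side
#' @export
assignFend <- function(chrom, pos, strand, index) {
  stopifnot(is(index, "FragmentIndex"))
  chrom <- rep_len(chrom, length(pos))
  strand <- rep_len(strand, length(pos))
  off <- .chromFendOffsets(index)
  out <- integer(length(pos))
  for (chr in unique(chrom)) {
    cs <- index@cutSites[[chr]]
    if (is.null(cs)) stop("chromosome not in fragment index: ", chr)
    sel <- which(chrom == chr)
    n <- length(cs)
    ## j = count of cut sites <= pos
    j <- findInterval(pos[sel], cs)
    plus <- strand[sel] == "+"
    ## + strand: nearest site at or downstream; site exactly at pos counts
    jUp <- findInterval(pos[sel] - 0.5, cs) + 1L   # first site >= pos
    local <- integer(length(sel))
    local[plus] <- ifelse(jUp[plus] > n, 2L * n + 1L, 2L * jUp[plus] - 1L)
    local[!plus] <- ifelse(j[!plus] < 1L, 0L, 2L * j[!plus])
    out[sel] <- as.integer(off[[chr]] + local)
  }
  out
}

#' Assign fends to both sides of a contact-pair table
#'
#' @param pairs a \linkS4class{ContactPairs}.
#' @param index a \linkS4class{FragmentIndex}.
#' @return The pairs with \code{fend1}, \code{fend2} filled in.
#' @export
assignFends <- function(pairs, index) {
  df <- contactPairs(pairs)
  df$fend1 <- assignFend(df$chrom1, df$pos1, df$strand1, index)
  df$fend2 <- assignFend(df$chrom2, df$pos2, df$strand2, index)
  ContactPairs(df)
}

#' Deduplicate contact pairs on unordered fend keys
#'
#' Retains at most one pair per unordered (fend1, fend2) key, keeping the
#' first occurrence in table order. PCR and optical duplicates of the
#' same ligation product collapse onto the same fend pair.
#'
#' @param pairs a \linkS4class{ContactPairs} with fends assigned.
#' @return Deduplicated \linkS4class{ContactPairs}; the number of rows
#'   removed is attached as attribute \code{"nRemoved"}.
#' @export
dedupContactPairs <- function(pairs) {
  df <- contactPairs(pairs)
  if (anyNA(df$fend1) || anyNA(df$fend2))
    stop("assign fends before deduplication")
  key <- paste(pmin(df$fend1, df$fend2), pmax(df$fend1, df$fend2))
  keep <- !duplicated(key)
  out <- ContactPairs(df[keep, , drop = FALSE])
  attr(out, "nRemoved") <- sum(!keep)
  out
}

#' Classify the NOMe context of a cytosine
#'
#' Applies the NOMe partition rule to a cytosine at \code{pos} on the
#' given strand: HCG when the preceding base is not G and the following
#' base is G (endogenous CpG channel); GCH when the preceding base is G
#' and the following is not (GpC accessibility channel); GCG_ambiguous
#' when both flanks are G-side (excluded from both channels); other
#' (HCH) otherwise. Minus-strand cytosines are evaluated on the reverse
#' complement. Chromosome-edge flanks count as non-G.
#'
#' @param genome \code{DNAStringSet}.
#' @param chrom chromosome name (scalar).
#' @param pos 0-based position vector; each must hold a cytosine on
#'   \code{strand}.
#' @param strand "+" or "-" (scalar or vector).
#' @return Character vector of contexts.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTGCATGCGT"))
#' classifyContext(g, "chr1", 1, "+")  # HCG
#' @export
classifyContext <- function(genome, chrom, pos, strand = "+") {
  stopifnot(is(genome, "DNAStringSet"))
  s <- as.character(genome[[chrom]])
  L <- nchar(s)
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  if (any(pos < 0 | pos >= L)) stop("position outside chromosome")
  at <- function(p) ifelse(p >= 0 & p < L, substring(s, p + 1L, p + 1L), "N")
  base <- at(pos)
  isC <- (strand == "+" & base == "C") | (strand == "-" & base == "G")
  if (!all(isC)) stop("position is not a cytosine on the given strand")
  ## flanks read 5'->3' on the cytosine's own strand
  prevG <- ifelse(strand == "+", at(pos - 1L) == "G", at(pos + 1L) == "C")
  nextG <- ifelse(strand == "+", at(pos + 1L) == "G", at(pos - 1L) == "C")
  ifelse(prevG & nextG, "GCG_ambiguous",
         ifelse(prevG, "GCH", ifelse(nextG, "HCG", "other")))
}
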