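## Three-frame ORF enumeration on spliced transcripts and the
## redundancy-reduction rules used during database construction.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

## Scan one spliced sequence; returns a data.frame of transcript-relative
## ORF intervals (0-based half-open, start codon through stop inclusive).
.scanSequence <- function(seqStr, startCodons, minLenAa, maxLenAa) {
  n <- nchar(seqStr)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    cs <- seq(f + 1L, by = 3L, length.out = ncod)
    codons <- substring(seqStr, cs, cs + 2L)
    isStop <- codons %in% .STOP_CODONS
    isStart <- codons %in% startCodons
    hasAmbig <- grepl("[^ACGT]", codons)
    stops <- which(isStop)
    starts <- which(isStart & !hasAmbig)
    if (length(stops) == 0L || length(starts) == 0L) next
    ## first stop strictly after each start
    nxt <- stops[findInterval(starts, stops) + 1L]
    keep <- !is.na(nxt)
    starts <- starts[keep]; nxt <- nxt[keep]
    if (length(starts) == 0L) next
    pepLen <- nxt - starts
    keep <- pepLen >= minLenAa &
      (if (is.null(maxLenAa)) TRUE else pepLen <= maxLenAa)
    starts <- starts[keep]; nxt <- nxt[keep]; pepLen <- pepLen[keep]
    if (length(starts) == 0L) next
    ## disqualify candidates with an ambiguous base in any codon of the span
    ambigPos <- which(hasAmbig)
    if (length(ambigPos) > 0L) {
      ok <- vapply(seq_along(starts), function(k)
        !any(ambigPos >= starts[k] & ambigPos <= nxt[k]), logical(1))
      starts <- starts[ok]; nxt <- nxt[ok]; pepLen <- pepLen[ok]
    }
    if (length(starts) == 0L) next
    pep <- vapply(seq_along(starts), function(k)
      paste(GENETIC_CODE[codons[starts[k]:(nxt[k] - 1L)]], collapse = ""),
      character(1))
    out[[length(out) + 1L]] <- data.frame(
      frame = f,
      txStart = f + (starts - 1L) * 3L,
      txEnd = f + nxt * 3L,
      startCodon = codons[starts],
      peptide = pep,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), txStart = integer(),
                      txEnd = integer(), startCodon = character(),
                      peptide = character()))
  do.call(rbind, out)
}

#' Enumerate ORFs on spliced transcripts (3-frame scan)
#'
#' Every reading from an allowed start codon to the first in-frame stop
#' codon is reported, with optional minimum/maximum peptide length;
#' readings lacking an in-frame stop before the transcript end are
#' excluded, as are candidates whose codons contain ambiguous bases (N).
#' The 100-codon small-ORF convention corresponds to `maxLenAa = 100`
#' (peptide length, stop codon excluded).
#'
#' @param ts a [TranscriptSet-class].
#' @param genome `DNAStringSet` named by chromosome.
#' @param startCodons allowed start codons (default ATG; add near-cognate
#'   NTG starts for TIS-style scans).
#' @param minLenAa minimum peptide length in aa (default 2).
#' @param maxLenAa optional maximum peptide length in aa (e.g. 100 for
#'   sORF mode); `NULL` for no ceiling.
#' @param source source label stored on the records.
#' @return An [OrfSet-class]; empty when nothing is found.
#' @export
scanOrfs <- function(ts, genome, startCodons = "ATG", minLenAa = 2L,
                     maxLenAa = NULL, source = "scan") {
  seqs <- splicedSequence(ts, genome)
  rows <- list()
  blocks <- list()
  for (tid in txIds(ts)) {
    hits <- .scanSequence(as.character(seqs[[tid]]), startCodons,
                          minLenAa, maxLenAa)
    if (nrow(hits) == 0L) next
    ex <- txExons(ts)[[tid]]
    chrom <- as.character(seqnames(ex)[1L])
    strandc <- as.character(strand(ex)[1L])
    stopPos <- .txToGenome(ex, hits$txEnd - 1L)
    ids <- sprintf("%s:%d-%d", tid, hits$txStart, hits$txEnd)
    rows[[tid]] <- DataFrame(
      orfId = ids, txId = tid, frame = hits$frame,
      txStart = hits$txStart, txEnd = hits$txEnd,
      chrom = chrom, strand = strandc, stopPos = as.integer(stopPos),
      startCodon = hits$startCodon, peptide = hits$peptide,
      source = source)
    blocks[[tid]] <- lapply(seq_len(nrow(hits)), function(k)
      .txIntervalToBlocks(ex, hits$txStart[k], hits$txEnd[k]))
  }
  if (length(rows) == 0L) return(.emptyOrfSet())
  od <- do.call(rbind, unname(rows))
  OrfSet(od, GRangesList(setNames(do.call(c, unname(blocks)), od$orfId)))
}

.emptyOrfSet <- function() {
  OrfSet(DataFrame(orfId = character(), txId = character(),
                   frame = integer(), txStart = integer(),
                   txEnd = integer(), chrom = character(),
                   strand = character(), stopPos = integer(),
                   startCodon = character(), peptide = character(),
                   source = character()),
         GRangesList())
}

#' Collapse ORF candidates sharing a genomic stop site
#'
#' Among candidates with the same stop key (chromosome, strand, genomic
#' coordinate of the last base of the stop codon) only the longest is
#' retained, the standard redundancy-reduction rule for nested in-frame
#' starts. Ties are broken by 5'-most transcript start, then lexicographic
#' `orfId`, so the result is deterministic.
#'
#' @param orfs an [OrfSet-class].
#' @return An [OrfSet-class] with one record per distinct stop key.
#' @export
collapseSharedStops <- function(orfs) {
  if (length(orfs) == 0L) return(orfs)
  od <- orfData(orfs)
  key <- paste(od$chrom, od$strand, od$stopPos, sep = "|")
  o <- order(key, -nchar(od$peptide), od$txStart, od$orfId)
  keep <- o[!duplicated(key[o])]
  orfs[sort(keep)]
}

#' Remove ORFs with duplicated peptide sequences
#'
#' One record per distinct peptide string; the first occurrence in input
#' order is retained.
#'
#' @param orfs an [OrfSet-class].
#' @return An [OrfSet-class] with unique peptides.
#' @export
dedupeSequences <- function(orfs) {
  if (length(orfs) == 0L) return(orfs)
  orfs[!duplicated(orfData(orfs)$peptide)]
}
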