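## Transcript <-> genome coordinate arithmetic.
##
## Exons arrive ordered 5'->3' in transcript orientation. Transcript
## coordinates are 0-based; genomic coordinates are 1-based (GRanges).

## Genomic position (1-based) of transcript position(s) `txpos` (0-based).
.txToGenome <- function(exons, txpos) {
  w <- width(exons)
  before <- c(0L, cumsum(w)[-length(w)])
  total <- sum(w)
  if (any(txpos < 0L | txpos >= total))
    stop("transcript position outside spliced length")
  idx <- findInterval(txpos, before)
  off <- txpos - before[idx]
  minus <- as.character(strand(exons))[idx] == "-"
  ifelse(minus, end(exons)[idx] - off, start(exons)[idx] + off)
}

## Transcript position (0-based) of genomic position(s) `gpos` (1-based);
## NA when the position is not exonic.
.genomeToTx <- function(exons, gpos) {
  w <- width(exons)
  before <- c(0L, cumsum(w)[-length(w)])
  res <- rep(NA_integer_, length(gpos))
  st <- as.character(strand(exons))
  for (i in seq_along(exons)) {
    hit <- gpos >= start(exons)[i] & gpos <= end(exons)[i] & is.na(res)
    if (any(hit)) {
      res[hit] <- if (st[i] == "-") before[i] + (end(exons)[i] - gpos[hit])
                  else before[i] + (gpos[hit] - start(exons)[i])
    }
  }
  res
}

## Genome-projected blocks of a transcript-relative interval [s, e)
## (0-based half-open), returned 5'->3' in transcript orientation.
.txIntervalToBlocks <- function(exons, s, e) {
  w <- width(exons)
  before <- c(0L, cumsum(w)[-length(w)])
  st <- as.character(strand(exons))
  chrom <- as.character(seqnames(exons))
  out <- NULL
  for (i in seq_along(exons)) {
    a <- max(s, before[i])
    b <- min(e, before[i] + w[i])
    if (a < b) {
      o1 <- a - before[i]
      o2 <- b - 1L - before[i]
      if (st[i] == "-") {
        gr <- GRanges(chrom[i],
                      IRanges(end(exons)[i] - o2, end(exons)[i] - o1),
                      strand = "-")
      } else {
        gr <- GRanges(chrom[i],
                      IRanges(start(exons)[i] + o1, start(exons)[i] + o2),
                      strand = "+")
      }
      out <- if (is.null(out)) gr else c(out, gr)
    }
  }
  if (is.null(out)) GRanges() else out
}
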