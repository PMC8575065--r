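# Independent brute-force oracles used to pin the vectorized
# implementations. These deliberately take the slow, obvious route.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

randomPeptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

randomDna <- function(n, pN = 0) {
  alphabet <- c("A", "C", "G", "T")
  prob <- rep((1 - pN) / 4, 4)
  if (pN > 0) { alphabet <- c(alphabet, "N"); prob <- c(prob, pN) }
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# Enumerate every substring of p and keep those that are valid cleavage
# products with at most `missed` internal uncut sites.
oracleCleave <- function(p, residues, missed) {
  chars <- strsplit(p, "")[[1L]]
  n <- length(chars)
  # cut after i iff chars[i] is a site residue and chars[i+1] != "P"
  cutAfter <- logical(n)
  if (n > 1L)
    cutAfter[1:(n - 1L)] <- chars[1:(n - 1L)] %in% residues &
      chars[2:n] != "P"
  grid <- expand.grid(a = seq_len(n), b = seq_len(n))
  grid <- grid[grid$a <= grid$b, ]
  leftOk <- grid$a == 1L | cutAfter[pmax(grid$a - 1L, 1L)]
  rightOk <- grid$b == n | cutAfter[grid$b]
  cum0 <- c(0L, cumsum(cutAfter))  # cum0[k + 1] = cuts after positions 1..k
  nInternal <- cum0[grid$b] - cum0[grid$a]
  keep <- leftOk & rightOk & nInternal <= missed
  out <- data.frame(peptide = substring(p, grid$a[keep], grid$b[keep]),
                    nMissed = nInternal[keep],
                    start = grid$a[keep], end = grid$b[keep],
                    stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

# Translate-and-scan brute force ORF finder: for every frame, translate
# codon by codon, and walk from each exact ATG to the next in-frame stop.
oracleScanOrfs <- function(seqStr, startCodons = "ATG", minLen = 2L,
                           maxLen = NULL) {
  n <- nchar(seqStr)
  rows <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    codons <- substring(seqStr, f + 1L + 3L * (0:(ncod - 1L)),
                        f + 3L + 3L * (0:(ncod - 1L)))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    for (s in which(codons %in% startCodons)) {
      j <- s
      pep <- ""
      ok <- TRUE
      found <- FALSE
      while (j <= ncod) {
        if (aa[j] == "*") { found <- TRUE; break }
        if (aa[j] == "X") ok <- FALSE
        pep <- paste0(pep, aa[j])
        j <- j + 1L
      }
      if (!found || !ok) next
      if (nchar(pep) < minLen) next
      if (!is.null(maxLen) && nchar(pep) > maxLen) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, txStart = f + (s - 1L) * 3L, txEnd = f + j * 3L,
        peptide = pep, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(), txStart = integer(),
                      txEnd = integer(), peptide = character()))
  out <- do.call(rbind, rows)
  out[order(out$txStart, out$frame), , drop = FALSE]
}

# Quadratic containment check by explicit substring enumeration.
oracleContained <- function(pred, refs) {
  vapply(pred, function(p) {
    if (nchar(p) < 3L) return(TRUE)  # untestable -> removed
    q <- substr(p, 2L, nchar(p) - 1L)
    nq <- nchar(q)
    for (r in refs) {
      nr <- nchar(r)
      if (nr < nq) next
      for (i in seq_len(nr - nq + 1L))
        if (substr(r, i, i + nq - 1L) == q) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

# Build a one-transcript TranscriptSet directly from a sequence string.
singleTxSet <- function(seqStr, txId = "tx1", strand = "+",
                        cdsStart = NA, cdsEnd = NA, biotype = NULL,
                        chrom = "chr1") {
  n <- nchar(seqStr)
  genomeSeq <- if (strand == "-") revComp(seqStr) else seqStr
  genome <- Biostrings::DNAStringSet(stats::setNames(genomeSeq, chrom))
  ex <- GenomicRanges::GRanges(chrom, IRanges::IRanges(1, n),
                               strand = strand)
  if (is.null(biotype))
    biotype <- if (is.na(cdsStart)) "ncRNA" else "protein_coding"
  ts <- TranscriptSet(GenomicRanges::GRangesList(stats::setNames(list(ex), txId)),
                      S4Vectors::DataFrame(txId = txId, geneId = txId,
                                           biotype = biotype,
                                           cdsStart = cdsStart,
                                           cdsEnd = cdsEnd))
  list(ts = ts, genome = genome)
}

# The printed HiBit tag nucleotide sequence, codon-separated with
# typographic zero-width spaces as in the printed version.
hibitInsertRaw <- function() {
  codons <- c("gtg", "agc", "ggc", "tgg", "cgc", "ctg", "ttt", "aaa",
              "aaa", "att", "agc")
  paste(codons, collapse = "\u200b")
}

# One outfmt-6 style homology row.
.hit <- function(q, s, db, evalue, pident = 50, bits = 100) {
  data.frame(queryId = q, subjectId = s, percentIdentity = pident,
             alnLength = 50, mismatches = 5, gapOpens = 0, qStart = 1,
             qEnd = 50, sStart = 1, sEnd = 50, evalue = evalue,
             bitscore = bits, speciesDb = db, stringsAsFactors = FALSE)
}
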