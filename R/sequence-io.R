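## Sequence and annotation I/O, translation and tag utilities.

#' Read a FASTA file preserving ids, descriptions and order
#'
#' Thin wrapper over [Biostrings::readBStringSet] with two additions the
#' downstream database bookkeeping needs: duplicated ids are reported (not
#' silently merged) and malformed files (sequence data before any header)
#' fail with the offending line number.
#'
#' @param path path to a FASTA file.
#' @return A `DataFrame` with columns `id`, `description`, `sequence`
#'   (uppercase), in file order; zero rows for an empty file.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(DataFrame(id = character(), description = character(),
                     sequence = character()))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: sequence line before any header at line ", first)
  empty <- nonblank[trimws(lines[nonblank]) == ">"]
  if (length(empty) > 0L)
    stop("malformed FASTA: empty header at line ", empty[1L])
  seqs <- readBStringSet(path)
  header <- names(seqs)
  id <- sub("[[:space:]].*$", "", header)
  desc <- ifelse(grepl("[[:space:]]", header),
                 sub("^[^[:space:]]+[[:space:]]+", "", header), "")
  if (anyDuplicated(id))
    warning("duplicate FASTA ids: ",
            paste(unique(id[duplicated(id)]), collapse = ", "))
  DataFrame(id = id, description = desc,
            sequence = toupper(as.character(seqs)))
}

#' Write sequences to FASTA
#'
#' @param x named character vector or `XStringSet`; names become headers.
#' @param path output path.
#' @param description optional per-record description appended after the id.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, description = NULL) {
  if (is.character(x)) x <- BStringSet(x)
  if (!is.null(description)) {
    has <- nzchar(description)
    names(x)[has] <- paste(names(x)[has], description[has])
  }
  writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a genome FASTA as an uppercase DNAStringSet
#'
#' @param path genome FASTA path.
#' @return `DNAStringSet` named by chromosome id; characters outside
#'   A/C/G/T/N are rejected.
#' @export
readGenome <- function(path) {
  rec <- readFasta(path)
  bad <- grepl("[^ACGTN]", rec$sequence)
  if (any(bad))
    stop("genome sequence ", rec$id[bad][1L],
         " contains characters outside A/C/G/T/N")
  setNames(DNAStringSet(rec$sequence), rec$id)
}

#' Read a protein FASTA as an AAStringSet
#'
#' @param path protein FASTA path.
#' @return `AAStringSet` named by accession (header up to first whitespace).
#' @export
readProteins <- function(path) {
  rec <- readFasta(path)
  setNames(AAStringSet(rec$sequence), rec$id)
}

#' Reverse complement of a nucleotide string
#' @param nt nucleotide string (A/C/G/T/N).
#' @return reverse-complemented string.
#' @export
revComp <- function(nt) {
  as.character(reverseComplement(DNAString(toupper(nt))))
}

#' Translate a nucleotide string with the standard genetic code
#'
#' Stop codons render as `"*"`. A codon containing any character outside
#' A/C/G/T (e.g. the ambiguity code N) translates to `"X"` with a warning.
#'
#' @param nt nucleotide string; length must be a multiple of 3.
#' @return amino-acid string.
#' @export
translateNt <- function(nt) {
  nt <- toupper(as.character(nt))
  n <- nchar(nt)
  if (n == 0L) return("")
  if (n %% 3L != 0L)
    stop("nucleotide length ", n, " is not divisible by 3")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(GENETIC_CODE[codons])
  if (anyNA(aa)) {
    warning(sum(is.na(aa)), " codon(s) with ambiguous bases translated to X")
    aa[is.na(aa)] <- "X"
  }
  paste(aa, collapse = "")
}

#' Find restriction-site occurrences on both strands
#'
#' Reports every occurrence of `pattern` on the forward strand and of its
#' reverse complement (i.e. pattern occurrences on the minus strand), with
#' 0-based offsets on the forward strand.
#'
#' @param nt nucleotide string to scan.
#' @param pattern recognition sequence over A/C/G/T.
#' @return data.frame with columns `site`, `strand`, `offset` (0-based
#'   forward-strand offset of the matched window).
#' @export
findRestrictionSites <- function(nt, pattern) {
  stopifnot(nzchar(pattern), !grepl("[^ACGT]", toupper(pattern)))
  subject <- DNAString(toupper(as.character(nt)))
  pattern <- toupper(pattern)
  fwd <- start(matchPattern(pattern, subject)) - 1L
  rcpat <- revComp(pattern)
  rev <- start(matchPattern(rcpat, subject)) - 1L
  ## a palindromic site matches identically on both strands; report once
  if (rcpat == pattern) rev <- integer(0)
  out <- rbind(
    if (length(fwd)) data.frame(site = pattern, strand = "+", offset = fwd),
    if (length(rev)) data.frame(site = pattern, strand = "-", offset = rev))
  if (is.null(out))
    out <- data.frame(site = character(), strand = character(),
                      offset = integer())
  out[order(out$offset), , drop = FALSE]
}

#' Check an in-frame tag insertion before an ORF's stop codon
#'
#' Verifies that a nucleotide insert (e.g. an 11-aa HiBit tag sequence)
#' placed immediately before the stop codon of an ORF keeps the reading
#' frame: the insert length must be divisible by 3 and its translation
#' stop-free, in which case the tagged ORF translates to the original
#' peptide followed by the tag peptide. Non-ACGT characters in the insert
#' (typographic artifacts in printed sequences) are stripped before use.
#' Restriction-site occurrences within the insert are reported so that
#' enzymatic digestion can serve as an integration readout.
#'
#' @param orfNt ORF nucleotide sequence ending in its stop codon, with no
#'   internal stop.
#' @param insertNt tag nucleotide sequence.
#' @param pattern restriction recognition sequence to scan for within the
#'   insert (default the MbiI site CCGCTC).
#' @return A [TagCheckReport-class].
#' @export
checkTagInsert <- function(orfNt, insertNt, pattern = "CCGCTC") {
  orfNt <- toupper(as.character(orfNt))
  insertNt <- gsub("[^ACGT]", "", toupper(as.character(insertNt)))
  orfPep <- translateNt(orfNt)
  if (!endsWith(orfPep, "*") || grepl("\\*.", orfPep))
    stop("orfNt must end in a stop codon and contain no internal stop")
  hits <- findRestrictionSites(insertNt, pattern)
  fail <- function(reason) new("TagCheckReport", insertIsInframe = FALSE,
                               reason = reason, tagPeptide = "",
                               tagLength = 0L, restrictionHits = hits,
                               taggedPeptide = "")
  if (nchar(insertNt) %% 3L != 0L)
    return(fail(sprintf("insert length %d not divisible by 3",
                        nchar(insertNt))))
  tagPep <- translateNt(insertNt)
  if (grepl("*", tagPep, fixed = TRUE))
    return(fail("insert translation contains a stop codon"))
  tagged <- paste0(substr(orfNt, 1L, nchar(orfNt) - 3L), insertNt,
                   substr(orfNt, nchar(orfNt) - 2L, nchar(orfNt)))
  taggedPep <- translateNt(tagged)
  stopifnot(identical(taggedPep,
                      paste0(sub("\\*$", "", orfPep), tagPep, "*")))
  new("TagCheckReport", insertIsInframe = TRUE, reason = "",
      tagPeptide = tagPep, tagLength = nchar(tagPep),
      restrictionHits = hits, taggedPeptide = sub("\\*$", "", taggedPep))
}

#' Read GFF3-style annotation into a TranscriptSet
#'
#' Coordinates are 1-based inclusive on input (the GFF3 convention) and are
#' stored unchanged in `GRanges`. Exons are assembled per transcript and
#' ordered 5' to 3'; the CDS span (expected to include the stop codon) is
#' converted to transcript-relative 0-based half-open coordinates. Biotype
#' is taken from a `biotype` attribute when present, defaulting to
#' `protein_coding` for transcripts with a CDS and `ncRNA` otherwise.
#' A CDS whose length is not divisible by 3 is dropped with a warning.
#'
#' @param path GFF3 file with transcript/mRNA, exon and (optionally) CDS
#'   features linked by `Parent` attributes.
#' @param genome optional `DNAStringSet`; when supplied, exons outside
#'   chromosome bounds raise an error.
#' @return A [TranscriptSet-class].
#' @export
readAnnotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  isTx <- type %in% c("transcript", "mRNA")
  txGr <- gr[isTx]
  txId <- as.character(txGr$ID)
  geneId <- if (!is.null(txGr$Parent) && any(lengths(txGr$Parent) > 0)) {
    vapply(txGr$Parent, function(p)
      if (length(p)) as.character(p[1L]) else NA_character_, character(1))
  } else rep(NA_character_, length(txGr))
  geneId[is.na(geneId)] <- txId[is.na(geneId)]
  parentOf <- function(sub) {
    unlist(lapply(sub$Parent, function(p) as.character(p[1L])))
  }
  exGr <- gr[type == "exon"]
  cdsGr <- gr[type == "CDS"]
  exParent <- parentOf(exGr)
  cdsParent <- if (length(cdsGr)) parentOf(cdsGr) else character(0)

  exons <- vector("list", length(txId))
  cdsStart <- cdsEnd <- rep(NA_integer_, length(txId))
  biotype <- character(length(txId))
  for (i in seq_along(txId)) {
    ex <- exGr[exParent == txId[i]]
    if (length(ex) == 0L) stop("transcript ", txId[i], " has no exons")
    minus <- as.character(strand(ex)[1L]) == "-"
    ex <- ex[order(start(ex), decreasing = minus)]
    ex <- granges(ex)
    if (!is.null(genome)) {
      chrom <- as.character(seqnames(ex))
      if (!all(chrom %in% names(genome)))
        stop("unknown chromosome for transcript ", txId[i])
      if (any(start(ex) < 1L) ||
          any(end(ex) > width(genome)[match(chrom, names(genome))]))
        stop("exon outside chromosome bounds for transcript ", txId[i])
    }
    exons[[i]] <- ex
    cds <- cdsGr[cdsParent == txId[i]]
    if (length(cds) > 0L) {
      if (sum(width(cds)) %% 3L != 0L) {
        warning("CDS length of transcript ", txId[i],
                " not divisible by 3; cds span dropped")
      } else {
        gFirst <- if (minus) max(end(cds)) else min(start(cds))
        gLast <- if (minus) min(start(cds)) else max(end(cds))
        cdsStart[i] <- .genomeToTx(ex, gFirst)
        cdsEnd[i] <- .genomeToTx(ex, gLast) + 1L
      }
    }
    bt <- if (!is.null(txGr$biotype)) as.character(txGr$biotype[i]) else NA
    if (is.na(bt) || !nzchar(bt))
      bt <- if (!is.na(cdsStart[i])) "protein_coding" else "ncRNA"
    biotype[i] <- bt
  }
  TranscriptSet(GRangesList(setNames(exons, txId)),
                DataFrame(txId = txId, geneId = geneId, biotype = biotype,
                          cdsStart = cdsStart, cdsEnd = cdsEnd))
}

#' Write a TranscriptSet as GFF3
#'
#' Emits transcript, exon and CDS features with 1-based inclusive
#' coordinates; [readAnnotation] on the output reproduces the input
#' intervals exactly.
#'
#' @param ts a [TranscriptSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ts, path) {
  td <- txData(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s, e, strandc, attr)
    sprintf("%s\tProteoORF\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s, e, strandc, attr)
  for (i in seq_len(nrow(td))) {
    ex <- txExons(ts)[[i]]
    chrom <- as.character(seqnames(ex)[1L])
    strandc <- as.character(strand(ex)[1L])
    tid <- td$txId[i]
    writeLines(fmt(chrom, "transcript", min(start(ex)), max(end(ex)), strandc,
                   sprintf("ID=%s;Parent=%s;biotype=%s", tid, td$geneId[i],
                           td$biotype[i])), con)
    for (j in seq_along(ex))
      writeLines(fmt(chrom, "exon", start(ex)[j], end(ex)[j], strandc,
                     sprintf("ID=%s.e%d;Parent=%s", tid, j, tid)), con)
    if (!is.na(td$cdsStart[i])) {
      blocks <- .txIntervalToBlocks(ex, td$cdsStart[i], td$cdsEnd[i])
      for (j in seq_along(blocks))
        writeLines(fmt(chrom, "CDS", start(blocks)[j], end(blocks)[j],
                       strandc,
                       sprintf("ID=%s.c%d;Parent=%s", tid, j, tid)), con)
    }
  }
  invisible(path)
}

#' Spliced (mature) transcript sequences
#'
#' Concatenates exon sequences in transcript orientation; minus-strand
#' exons are reverse-complemented.
#'
#' @param ts a [TranscriptSet-class].
#' @param genome `DNAStringSet` named by chromosome.
#' @param tx optional transcript ids to restrict to.
#' @return `DNAStringSet` named by transcript id.
#' @export
splicedSequence <- function(ts, genome, tx = NULL) {
  ids <- if (is.null(tx)) txIds(ts) else tx
  seqs <- vapply(ids, function(tid) {
    ex <- txExons(ts)[[tid]]
    chrom <- as.character(seqnames(ex))
    if (!all(chrom %in% names(genome)))
      stop("chromosome ", setdiff(chrom, names(genome))[1L],
           " missing from genome")
    parts <- vapply(seq_along(ex), function(j) {
      if (end(ex)[j] > width(genome)[match(chrom[j], names(genome))])
        stop("exon outside chromosome bounds in transcript ", tid)
      s <- subseq(genome[[chrom[j]]], start(ex)[j], end(ex)[j])
      if (as.character(strand(ex)[j]) == "-") s <- reverseComplement(s)
      as.character(s)
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  setNames(DNAStringSet(seqs), ids)
}
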