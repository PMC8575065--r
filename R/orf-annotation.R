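## Genomic-context categorization of non-canonical ORFs: isoform, uORF,
## dORF, ncRNA, altORF, intergenic. First matching rule wins, ordered so
## that the least-novel explanation is preferred.

## Phase (0..2) of genomic position g within a block structure treated as
## a mini-transcript (blocks ordered 5'->3'); NA if g not in blocks.
.phaseAt <- function(blocks, g) {
  tp <- .genomeToTx(blocks, g)
  ifelse(is.na(tp), NA_integer_, tp %% 3L)
}

#' Categorize one ORF by genomic context
#'
#' Decision cascade, first match wins:
#' \enumerate{
#'   \item \strong{isoform} — the ORF shares its stop-codon genomic
#'     position (and hence reading frame) with an annotated CDS but is not
#'     that CDS;
#'   \item \strong{uORF} — the ORF lies entirely within the exons of a
#'     coding transcript, 5' of its CDS start;
#'   \item \strong{dORF} — entirely 3' of the CDS stop;
#'   \item \strong{ncRNA} — hosted (same strand, fully exonic) on a
#'     transcript of non-coding biotype;
#'   \item \strong{altORF} — overlaps an annotated transcript otherwise
#'     (typically an annotated CDS in a different frame or with a distinct
#'     stop);
#'   \item \strong{intergenic} — no transcript overlap.
#' }
#' uORF/dORF require full containment in the UTR; an ORF straddling the
#' CDS boundary falls through to altORF. Frame comparison is splice-aware,
#' performed in genomic coordinates through each feature's own blocks.
#'
#' @param blocks `GRanges` of the ORF's genome-projected blocks, ordered
#'   5' to 3'.
#' @param stopPos genomic coordinate (1-based) of the last base of the
#'   ORF's stop codon.
#' @param annotation a [TranscriptSet-class].
#' @param orfId id used in the returned call.
#' @return one-row data.frame: `orfId`, `category`, `frameRelation`
#'   (same/different/not_applicable), `evidence` (";"-joined transcript
#'   ids and the rule that fired; empty only for intergenic).
#' @export
categorizeOrf <- function(blocks, stopPos, annotation, orfId = "orf") {
  td <- txData(annotation)
  exl <- txExons(annotation)
  orfStrand <- as.character(strand(blocks)[1L])
  orfChrom <- as.character(seqnames(blocks)[1L])
  call <- function(category, frameRelation, txids, rule) {
    data.frame(orfId = orfId, category = category,
               frameRelation = frameRelation,
               evidence = if (length(txids))
                 paste0(rule, ":", paste(sort(unique(txids)), collapse = ","))
               else "",
               stringsAsFactors = FALSE)
  }
  coding <- which(!is.na(td$cdsStart))

  ## rule 1: shared annotated CDS stop (implies shared frame at the stop)
  isoHits <- character(0)
  for (i in coding) {
    ex <- exl[[i]]
    if (as.character(seqnames(ex)[1L]) != orfChrom ||
        as.character(strand(ex)[1L]) != orfStrand) next
    cdsStop <- .txToGenome(ex, td$cdsEnd[i] - 1L)
    if (cdsStop == stopPos) {
      cdsBlocks <- .txIntervalToBlocks(ex, td$cdsStart[i], td$cdsEnd[i])
      identicalStructure <- length(cdsBlocks) == length(blocks) &&
        all(start(cdsBlocks) == start(blocks)) &&
        all(end(cdsBlocks) == end(blocks))
      if (!identicalStructure) isoHits <- c(isoHits, td$txId[i])
    }
  }
  if (length(isoHits) > 0L)
    return(call("isoform", "same", isoHits, "shared_cds_stop"))

  ## hosting: same strand, all ORF blocks within a transcript's exons
  hostsOf <- function(idx) {
    Filter(function(i) {
      ex <- exl[[i]]
      as.character(seqnames(ex)[1L]) == orfChrom &&
        as.character(strand(ex)[1L]) == orfStrand &&
        all(overlapsAny(blocks, ex, type = "within", ignore.strand = FALSE))
    }, idx)
  }
  orf5 <- if (orfStrand == "-") max(end(blocks)) else min(start(blocks))
  orf3 <- if (orfStrand == "-") min(start(blocks)) else max(end(blocks))
  uHits <- dHits <- character(0)
  for (i in hostsOf(coding)) {
    ex <- exl[[i]]
    txS <- .genomeToTx(ex, orf5)
    txE <- .genomeToTx(ex, orf3) + 1L
    if (is.na(txS) || is.na(txE)) next
    if (txE <= td$cdsStart[i]) uHits <- c(uHits, td$txId[i])
    else if (txS >= td$cdsEnd[i]) dHits <- c(dHits, td$txId[i])
  }
  if (length(uHits) > 0L)
    return(call("uORF", "not_applicable", uHits, "within_5utr"))
  if (length(dHits) > 0L)
    return(call("dORF", "not_applicable", dHits, "within_3utr"))

  noncoding <- which(is.na(td$cdsStart) &
                     td$biotype %in% c("ncRNA", "pseudogene", "other"))
  ncHits <- td$txId[unlist(hostsOf(noncoding))]
  if (length(ncHits) > 0L)
    return(call("ncRNA", "not_applicable", ncHits, "noncoding_host"))

  ## rule 5: any remaining transcript overlap -> altORF; frame relation is
  ## computed against an overlapping CDS on the same strand when one exists
  spanOverlap <- vapply(seq_len(nrow(td)), function(i) {
    ex <- exl[[i]]
    as.character(seqnames(ex)[1L]) == orfChrom &&
      max(end(ex)) >= min(start(blocks)) &&
      min(start(ex)) <= max(end(blocks))
  }, logical(1))
  if (any(spanOverlap)) {
    frameRel <- "not_applicable"
    for (i in intersect(coding, which(spanOverlap))) {
      ex <- exl[[i]]
      cdsBlocks <- .txIntervalToBlocks(ex, td$cdsStart[i], td$cdsEnd[i])
      ov <- findOverlaps(blocks, cdsBlocks, ignore.strand = TRUE)
      if (length(ov) == 0L) next
      if (as.character(strand(ex)[1L]) != orfStrand) {
        frameRel <- "different"
        next
      }
      ## pick one genomically overlapping base and compare codon phases
      q <- S4Vectors::queryHits(ov)[1L]
      s <- S4Vectors::subjectHits(ov)[1L]
      g <- max(start(blocks)[q], start(cdsBlocks)[s])
      pOrf <- .phaseAt(blocks, g)
      pCds <- .phaseAt(cdsBlocks, g)
      frameRel <- if (!is.na(pOrf) && !is.na(pCds) && pOrf == pCds)
        "same" else "different"
      break
    }
    return(call("altORF", frameRel, td$txId[spanOverlap],
                "transcript_overlap"))
  }
  call("intergenic", "not_applicable", character(0), "no_overlap")
}

#' Categorize a set of ORFs and tabulate the categories
#'
#' @param orfs an [OrfSet-class] whose blocks are genome-projected.
#' @param annotation a [TranscriptSet-class].
#' @return list with `calls` (one row per ORF, ordered by `orfId`) and
#'   `counts` (named integer vector over the six categories).
#' @export
annotateOrfs <- function(orfs, annotation) {
  if (length(orfs) == 0L) {
    calls <- data.frame(orfId = character(), category = character(),
                        frameRelation = character(), evidence = character())
    return(list(calls = calls,
                counts = setNames(integer(length(.CATEGORY_LEVELS)),
                                  .CATEGORY_LEVELS)))
  }
  od <- orfData(orfs)
  calls <- do.call(rbind, lapply(seq_len(length(orfs)), function(k)
    categorizeOrf(orfBlocks(orfs)[[k]], od$stopPos[k], annotation,
                  orfId = od$orfId[k])))
  calls <- calls[order(calls$orfId), , drop = FALSE]
  rownames(calls) <- NULL
  counts <- table(factor(calls$category, levels = .CATEGORY_LEVELS))
  list(calls = calls, counts = setNames(as.integer(counts), names(counts)))
}
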