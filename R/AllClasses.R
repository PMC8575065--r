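## S4 containers shared by all modules.
##
## Conventions: genomic intervals live in GRanges/GRangesList (1-based,
## closed, the native Bioconductor/GFF3 convention); transcript-relative
## coordinates (ORF and CDS spans) are 0-based half-open, so an interval
## [s, e) has length e - s and frame s %% 3.

.SOURCE_LEVELS <- c("reference", "predA", "predB", "contaminant", "host")
.SOURCE_PREFIX <- c(reference = "ref", predA = "predA", predB = "predB",
                    contaminant = "crap", host = "host")
.CATEGORY_LEVELS <- c("isoform", "uORF", "dORF", "ncRNA", "altORF", "intergenic")

#' TranscriptSet: spliced transcript models over a genome
#'
#' Holds one exon `GRanges` per transcript (ordered 5' to 3' in transcript
#' orientation; minus-strand transcripts therefore list exons in decreasing
#' genomic coordinate) together with per-transcript metadata: gene id,
#' biotype, and the transcript-relative CDS span (0-based half-open,
#' including the stop codon) when the transcript is coding.
#'
#' @slot exons `GRangesList` named by transcript id.
#' @slot txData `DataFrame` with columns `txId`, `geneId`, `biotype`
#'   (one of protein_coding, ncRNA, pseudogene, other), `cdsStart`,
#'   `cdsEnd` (integer, `NA` for non-coding transcripts).
#' @export
setClass("TranscriptSet",
         slots = c(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  td <- object@txData
  need <- c("txId", "geneId", "biotype", "cdsStart", "cdsEnd")
  if (!all(need %in% colnames(td)))
    return(paste("txData must have columns", paste(need, collapse = ", ")))
  if (length(object@exons) != nrow(td))
    return("exons and txData lengths differ")
  if (!identical(names(object@exons), as.character(td$txId)))
    return("exons names must equal txData$txId")
  for (i in seq_along(object@exons)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L || sum(width(ex)) < 1L)
      return(sprintf("transcript %s has no exonic sequence", td$txId[i]))
    if (length(unique(as.character(strand(ex)))) != 1L)
      return(sprintf("transcript %s mixes strands", td$txId[i]))
    o <- order(start(ex))
    if (any(head(end(ex)[o], -1L) >= tail(start(ex)[o], -1L)))
      return(sprintf("transcript %s has overlapping exons", td$txId[i]))
    if (!is.na(td$cdsStart[i])) {
      sl <- sum(width(ex))
      if (td$cdsStart[i] < 0L || td$cdsEnd[i] > sl ||
          td$cdsEnd[i] <= td$cdsStart[i])
        return(sprintf("transcript %s CDS span outside spliced length", td$txId[i]))
      if ((td$cdsEnd[i] - td$cdsStart[i]) %% 3L != 0L)
        return(sprintf("transcript %s CDS length not divisible by 3", td$txId[i]))
    }
  }
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons `GRangesList` of exons, one element per transcript, each
#'   ordered 5' to 3' in transcript orientation.
#' @param txData `DataFrame`/data.frame with columns `txId`, `geneId`,
#'   `biotype`, `cdsStart`, `cdsEnd` (transcript-relative, 0-based
#'   half-open, stop codon included; `NA` when non-coding).
#' @return A [TranscriptSet-class] object.
#' @export
TranscriptSet <- function(exons, txData) {
  txData <- as(txData, "DataFrame")
  txData$txId <- as.character(txData$txId)
  txData$cdsStart <- as.integer(txData$cdsStart)
  txData$cdsEnd <- as.integer(txData$cdsEnd)
  if (is.null(names(exons))) names(exons) <- txData$txId
  new("TranscriptSet", exons = exons, txData = txData)
}

#' @describeIn TranscriptSet-class number of transcripts
#' @param x,object a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' Transcript ids of a TranscriptSet
#' @param x a `TranscriptSet`
#' @return character vector of transcript ids.
#' @export
txIds <- function(x) as.character(x@txData$txId)

#' Per-transcript metadata of a TranscriptSet
#' @param x a `TranscriptSet`
#' @return the `DataFrame` of transcript metadata.
#' @export
txData <- function(x) x@txData

#' Exon ranges of a TranscriptSet
#' @param x a `TranscriptSet`
#' @return `GRangesList` of exons, 5' to 3' per transcript.
#' @export
txExons <- function(x) x@exons

#' Spliced (mature) transcript lengths
#' @param x a `TranscriptSet`
#' @return named integer vector of spliced lengths.
#' @export
splicedLength <- function(x) {
  setNames(vapply(x@exons, function(e) sum(width(e)), integer(1)), txIds(x))
}

setMethod("show", "TranscriptSet", function(object) {
  nc <- sum(!is.na(object@txData$cdsStart))
  cat("TranscriptSet with", length(object), "transcripts (",
      nc, "coding )\n")
  cat("  biotypes:", paste(names(table(object@txData$biotype)),
                           table(object@txData$biotype),
                           sep = ":", collapse = " "), "\n")
})

#' OrfSet: predicted or annotated ORFs
#'
#' One row per ORF: transcript-relative interval (`txStart`, `txEnd`,
#' 0-based half-open, start codon through stop codon inclusive), frame
#' relative to the transcript 5' end, the genomic stop key (`chrom`,
#' `strand`, `stopPos` = 1-based genomic coordinate of the last base of the
#' stop codon), peptide (stop excluded), start codon and source label.
#' `blocks` carries the genome-projected exonic intervals of each ORF,
#' ordered 5' to 3'.
#'
#' @slot orfData `DataFrame` with columns `orfId`, `txId`, `frame`,
#'   `txStart`, `txEnd`, `chrom`, `strand`, `stopPos`, `startCodon`,
#'   `peptide`, `source`.
#' @slot blocks `GRangesList` parallel to `orfData`, named by `orfId`.
#' @export
setClass("OrfSet", slots = c(orfData = "DataFrame", blocks = "GRangesList"))

setValidity("OrfSet", function(object) {
  od <- object@orfData
  need <- c("orfId", "txId", "frame", "txStart", "txEnd", "chrom", "strand",
            "stopPos", "startCodon", "peptide", "source")
  if (!all(need %in% colnames(od)))
    return(paste("orfData must have columns", paste(need, collapse = ", ")))
  if (length(object@blocks) != nrow(od))
    return("blocks and orfData lengths differ")
  if (nrow(od) == 0L) return(TRUE)
  if (anyDuplicated(od$orfId)) return("orfId values must be unique")
  if (any(grepl("*", od$peptide, fixed = TRUE)))
    return("peptides must not contain internal stops")
  span <- od$txEnd - od$txStart
  if (any(span != 3L * (nchar(od$peptide) + 1L)))
    return("txEnd - txStart must equal 3*(peptide length + 1)")
  TRUE
})

#' Construct an OrfSet
#' @param orfData per-ORF table (see [OrfSet-class]).
#' @param blocks `GRangesList` of genome-projected blocks, parallel to
#'   `orfData`.
#' @return An [OrfSet-class] object.
#' @export
OrfSet <- function(orfData, blocks = NULL) {
  orfData <- as(orfData, "DataFrame")
  if (is.null(blocks)) {
    blocks <- GRangesList(lapply(seq_len(nrow(orfData)), function(i) GRanges()))
  }
  names(blocks) <- orfData$orfId
  new("OrfSet", orfData = orfData, blocks = blocks)
}

#' @describeIn OrfSet-class number of ORFs
#' @param x,object an `OrfSet`
#' @export
setMethod("length", "OrfSet", function(x) nrow(x@orfData))

#' Per-ORF table of an OrfSet
#' @param x an `OrfSet`
#' @return the `DataFrame` of ORF records.
#' @export
orfData <- function(x) x@orfData

#' Genome-projected blocks of an OrfSet
#' @param x an `OrfSet`
#' @return `GRangesList` of ORF blocks.
#' @export
orfBlocks <- function(x) x@blocks

#' ORF peptides
#' @param x an `OrfSet`
#' @return named character vector of peptide sequences.
#' @export
orfPeptides <- function(x) setNames(as.character(x@orfData$peptide),
                                    x@orfData$orfId)

.subsetOrfSet <- function(x, i) {
  new("OrfSet", orfData = x@orfData[i, , drop = FALSE], blocks = x@blocks[i])
}

#' @export
setMethod("[", "OrfSet", function(x, i, j, ..., drop = FALSE) .subsetOrfSet(x, i))

setMethod("show", "OrfSet", function(object) {
  cat("OrfSet with", length(object), "ORFs\n")
  if (length(object) > 0L) {
    pl <- nchar(object@orfData$peptide)
    cat("  peptide length:", min(pl), "-", max(pl), "aa; sources:",
        paste(unique(object@orfData$source), collapse = ", "), "\n")
  }
})

#' AllOrfDb: an assembled protein search database with provenance
#'
#' The unit of the database is one distinct amino-acid sequence among the
#' non-contaminant inputs (reference and prediction sets are merged by exact
#' peptide identity); contaminant and host entries are appended unmerged and
#' flagged, and are excluded from composition percentages.
#'
#' @slot entries `AAStringSet` named by accession.
#' @slot entryData `DataFrame` with columns `accession`, `sources`
#'   (`CharacterList`, subset of reference/predA/predB/contaminant/host),
#'   `primarySource`, `lengthClass` (small = <= 100 aa, large), `isContaminant`,
#'   `description`.
#' @slot sourceSets named list of input accession vectors per declared source.
#' @export
setClass("AllOrfDb",
         slots = c(entries = "AAStringSet", entryData = "DataFrame",
                   sourceSets = "list"))

setValidity("AllOrfDb", function(object) {
  ed <- object@entryData
  need <- c("accession", "sources", "primarySource", "lengthClass",
            "isContaminant", "description")
  if (!all(need %in% colnames(ed)))
    return(paste("entryData must have columns", paste(need, collapse = ", ")))
  if (length(object@entries) != nrow(ed))
    return("entries and entryData lengths differ")
  if (nrow(ed) == 0L) return(TRUE)
  if (anyDuplicated(ed$accession)) return("accessions must be unique")
  if (any(grepl("[[:space:]]", ed$accession)))
    return("accessions must not contain whitespace")
  if (any(lengths(ed$sources) == 0L)) return("sources must be non-empty")
  bad <- !unlist(ed$sources) %in% .SOURCE_LEVELS
  if (any(bad)) return("unknown source label in sources")
  lc <- ifelse(width(object@entries) <= 100L, "small", "large")
  if (!all(ed$lengthClass == lc))
    return("lengthClass inconsistent with sequence length")
  TRUE
})

#' @describeIn AllOrfDb-class number of entries
#' @param x,object an `AllOrfDb`
#' @export
setMethod("length", "AllOrfDb", function(x) length(x@entries))

#' Database sequences
#' @param x an `AllOrfDb`
#' @return `AAStringSet` of entries, named by accession.
#' @export
dbEntries <- function(x) x@entries

#' Per-entry provenance table
#' @param x an `AllOrfDb`
#' @return the entry `DataFrame`.
#' @export
dbEntryData <- function(x) x@entryData

#' Declared input source sets
#' @param x an `AllOrfDb`
#' @return named list of input accessions per source.
#' @export
dbSourceSets <- function(x) x@sourceSets

setMethod("show", "AllOrfDb", function(object) {
  ed <- object@entryData
  cat("AllOrfDb with", length(object), "entries (",
      sum(ed$isContaminant), "contaminant/host )\n")
  if (nrow(ed) > 0L) {
    cat("  length classes:", sum(ed$lengthClass == "small"), "small /",
        sum(ed$lengthClass == "large"), "large\n")
  }
})

#' DigestConfig: in-silico digestion parameters
#'
#' Defaults follow a typical bottom-up evaluation: trypsin, one missed
#' cleavage, peptide mass window 600-4000 Da (monoisotopic, boundaries
#' inclusive) and length window 7-30 aa.
#'
#' @slot enzyme `"trypsin"` (cleave C-terminal to K/R, not before P) or
#'   `"chymotrypsin"` (C-terminal to F/W/Y/L, not before P by default).
#' @slot missedCleavages maximum internal uncut sites per product.
#' @slot massMin,massMax monoisotopic mass window in Da, inclusive.
#' @slot lenMin,lenMax peptide length window in aa, inclusive.
#' @slot ilEquivalence treat I and L as identical when pooling peptides for
#'   uniqueness (isobaric by MS); off by default.
#' @slot carbamidomethyl add fixed carbamidomethylation (+57.02146 Da) per
#'   cysteine to peptide masses; off by default.
#' @slot chymoResidues cleavage residues used for chymotrypsin.
#' @export
setClass("DigestConfig",
         slots = c(enzyme = "character", missedCleavages = "integer",
                   massMin = "numeric", massMax = "numeric",
                   lenMin = "integer", lenMax = "integer",
                   ilEquivalence = "logical", carbamidomethyl = "logical",
                   chymoResidues = "character"))

setValidity("DigestConfig", function(object) {
  if (!object@enzyme %in% c("trypsin", "chymotrypsin"))
    return("enzyme must be trypsin or chymotrypsin")
  if (object@missedCleavages < 0L) return("missedCleavages must be >= 0")
  if (object@massMin >= object@massMax) return("massMin must be < massMax")
  if (object@lenMin > object@lenMax) return("lenMin must be <= lenMax")
  TRUE
})

#' Construct a DigestConfig
#' @param enzyme,missedCleavages,massMin,massMax,lenMin,lenMax,ilEquivalence,carbamidomethyl,chymoResidues
#'   see [DigestConfig-class].
#' @return A [DigestConfig-class] object.
#' @export
digestConfig <- function(enzyme = "trypsin", missedCleavages = 1L,
                         massMin = 600, massMax = 4000,
                         lenMin = 7L, lenMax = 30L,
                         ilEquivalence = FALSE, carbamidomethyl = FALSE,
                         chymoResidues = "FWYL") {
  new("DigestConfig", enzyme = enzyme,
      missedCleavages = as.integer(missedCleavages),
      massMin = massMin, massMax = massMax,
      lenMin = as.integer(lenMin), lenMax = as.integer(lenMax),
      ilEquivalence = ilEquivalence, carbamidomethyl = carbamidomethyl,
      chymoResidues = chymoResidues)
}

setMethod("show", "DigestConfig", function(object) {
  cat(sprintf("DigestConfig: %s, <= %d missed, mass [%g, %g] Da, length [%d, %d] aa\n",
              object@enzyme, object@missedCleavages, object@massMin,
              object@massMax, object@lenMin, object@lenMax))
})

#' TagCheckReport: in-frame tag insertion check
#'
#' Result of [checkTagInsert]: whether an insert placed immediately before
#' an ORF's stop codon keeps the reading frame, the translated tag peptide,
#' and restriction-site occurrences within the insert (both strands,
#' 0-based forward-strand offsets).
#'
#' @slot insertIsInframe logical.
#' @slot reason explanation when not in frame.
#' @slot tagPeptide translated tag (empty when out of frame).
#' @slot tagLength tag length in aa.
#' @slot restrictionHits data.frame with columns `site`, `strand`, `offset`.
#' @slot taggedPeptide full translation of the tagged ORF without its stop.
#' @export
setClass("TagCheckReport",
         slots = c(insertIsInframe = "logical", reason = "character",
                   tagPeptide = "character", tagLength = "integer",
                   restrictionHits = "data.frame", taggedPeptide = "character"))

setMethod("show", "TagCheckReport", function(object) {
  cat("TagCheckReport: in-frame =", object@insertIsInframe)
  if (!object@insertIsInframe) cat(" (", object@reason, ")", sep = "")
  cat("\n  tag peptide:", object@tagPeptide,
      sprintf("(%d aa)", object@tagLength), "\n")
  cat("  restriction hits:", nrow(object@restrictionHits), "\n")
})

#' FixtureSpec: parameters of the synthetic fixture world
#'
#' Describes a small genome with multi-exon coding genes (5'/3' UTRs),
#' ncRNA genes, planted non-canonical ORFs of every category, and two
#' prediction sets whose length distributions emulate a sORF-style set
#' (median 25 aa) and an altProt-style set (median 45 aa) with a stated
#' shared fraction.
#'
#' @slot seed integer driving all randomness.
#' @slot nCodingGenes,nNcrnaGenes gene counts.
#' @slot plantedOrfs named integer vector over uORF, dORF, ncRNA, altORF,
#'   intergenic, isoform.
#' @slot predAMedian,predBMedian target median peptide lengths (aa) of the
#'   two prediction sets.
#' @slot overlapFraction approximate fraction of predictions shared between
#'   the two sets (the complement of "unique to either set").
#' @slot chromLength maximum chromosome length in nt (layout validated).
#' @slot plantUndetectable plant one prediction with zero unique in-window
#'   tryptic peptides (its every product embedded in a reference protein).
#' @slot nQueries,nConserved homology-fixture sizes: total queries and
#'   planted-conserved queries.
#' @slot idCommon,idUniqueA,idUniqueB planted identification overlap between
#'   two search engines.
#' @export
setClass("FixtureSpec",
         slots = c(seed = "integer", nCodingGenes = "integer",
                   nNcrnaGenes = "integer", plantedOrfs = "integer",
                   predAMedian = "integer", predBMedian = "integer",
                   overlapFraction = "numeric", chromLength = "integer",
                   plantUndetectable = "logical",
                   nQueries = "integer", nConserved = "integer",
                   idCommon = "integer", idUniqueA = "integer",
                   idUniqueB = "integer"))

setValidity("FixtureSpec", function(object) {
  po <- object@plantedOrfs
  if (!all(sort(names(po)) == sort(.CATEGORY_LEVELS)))
    return("plantedOrfs must be named over all six categories")
  if (any(po < 0L)) return("plantedOrfs counts must be >= 0")
  ## one planted feature per coding gene keeps category rules independent
  if (po[["uORF"]] + po[["dORF"]] + po[["altORF"]] + po[["isoform"]] >
      object@nCodingGenes)
    return("not enough coding genes to host planted uORF/dORF/altORF/isoform")
  if (po[["ncRNA"]] > object@nNcrnaGenes)
    return("not enough ncRNA genes for planted ncRNA ORFs")
  if (object@overlapFraction < 0 || object@overlapFraction > 1)
    return("overlapFraction must be in [0, 1]")
  if (object@nConserved > object@nQueries)
    return("nConserved must be <= nQueries")
  TRUE
})

#' Construct a FixtureSpec
#' @param seed,nCodingGenes,nNcrnaGenes,plantedOrfs,predAMedian,predBMedian,overlapFraction,chromLength,plantUndetectable,nQueries,nConserved,idCommon,idUniqueA,idUniqueB
#'   see [FixtureSpec-class].
#' @return A [FixtureSpec-class] object.
#' @export
fixtureSpec <- function(seed = 1L, nCodingGenes = 10L, nNcrnaGenes = 4L,
                        plantedOrfs = c(uORF = 3L, dORF = 1L, ncRNA = 4L,
                                        altORF = 2L, intergenic = 2L,
                                        isoform = 2L),
                        predAMedian = 25L, predBMedian = 45L,
                        overlapFraction = 0.3, chromLength = 60000L,
                        plantUndetectable = TRUE,
                        nQueries = 85L, nConserved = 18L,
                        idCommon = 68L, idUniqueA = 119L, idUniqueB = 87L) {
  po <- setNames(as.integer(plantedOrfs), names(plantedOrfs))
  new("FixtureSpec", seed = as.integer(seed),
      nCodingGenes = as.integer(nCodingGenes),
      nNcrnaGenes = as.integer(nNcrnaGenes), plantedOrfs = po,
      predAMedian = as.integer(predAMedian),
      predBMedian = as.integer(predBMedian),
      overlapFraction = overlapFraction,
      chromLength = as.integer(chromLength),
      plantUndetectable = plantUndetectable,
      nQueries = as.integer(nQueries), nConserved = as.integer(nConserved),
      idCommon = as.integer(idCommon), idUniqueA = as.integer(idUniqueA),
      idUniqueB = as.integer(idUniqueB))
}

setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec: seed", object@seed, "-", object@nCodingGenes,
      "coding +", object@nNcrnaGenes, "ncRNA genes\n")
  cat("  planted ORFs:", paste(names(object@plantedOrfs),
                               object@plantedOrfs, sep = ":",
                               collapse = " "), "\n")
})
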