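## Deterministic synthetic fixtures: a small genome with multi-exon coding
## genes (5'/3' UTRs), ncRNA genes, planted non-canonical ORFs of every
## category, matched prediction sets, reference proteome, homology and
## identification tables — all with recorded ground truth.

.randDna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

.randPeptide <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                  collapse = "")

## reverse-translate a peptide, sampling a codon per residue
.revTranslate <- function(pep) {
  aaCodons <- split(names(GENETIC_CODE), GENETIC_CODE)
  chars <- strsplit(pep, "")[[1L]]
  paste(vapply(chars, function(a) {
    cs <- aaCodons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

## ORF nucleotide sequence (ATG + codons + TAA) for a peptide starting M
.orfNt <- function(pep) {
  stopifnot(startsWith(pep, "M"))
  paste0("ATG", .revTranslate(substr(pep, 2L, nchar(pep))), "TAA")
}

## filler lengths making the combined multiset's median exactly `med`
.balanceToMedian <- function(existing, med, extra = 4L) {
  lb <- sum(existing < med)
  la <- sum(existing > med)
  ne <- sum(existing == med)
  fb <- max(0L, la - lb) + extra
  fa <- max(0L, lb - la) + extra
  fe <- if (ne %% 2L == 1L) 0L else 1L
  c(sample(seq(8L, med - 1L), fb, replace = TRUE),
    sample(seq(med + 1L, med + 40L), fa, replace = TRUE),
    rep(med, fe))
}

#' Plant a protein undetectable by unique tryptic peptides
#'
#' Constructs a prediction whose every tryptic product (at any missed-
#' cleavage count up to the configured allowance) also occurs in a second,
#' longer host protein: the prediction is embedded in the host flanked by
#' a cleavage-compatible context (preceded by R, ending in K, followed by
#' a non-proline residue), so its every digestion product is reproduced
#' from the host and its unique-peptide count is zero. The construction is
#' verified at generation time by running [digestDatabase].
#'
#' @param pepLen length of the planted prediction in aa (default 36).
#' @param cfg [DigestConfig-class] used for verification.
#' @param maxAttempts bounded construction attempts before erroring.
#' @return list with `protein` (the planted prediction) and `host` (the
#'   embedding protein).
#' @export
plantUndetectableProtein <- function(pepLen = 36L, cfg = digestConfig(),
                                     maxAttempts = 50L) {
  for (attempt in seq_len(maxAttempts)) {
    p <- paste0("M", .randPeptide(pepLen - 2L), "K")
    host <- paste0(.randPeptide(11L), "R", p, "A", .randPeptide(11L))
    db <- assembleDatabase(reference = c(HOSTFIX = host),
                           predA = setNames(p, "PLANTFIX"))
    dig <- digestDatabase(db, cfg)
    pp <- dig$perProtein
    if (pp$nUnique[pp$accession == "PLANTFIX"] == 0L)
      return(list(protein = p, host = host))
  }
  stop("failed to construct an undetectable protein in ", maxAttempts,
       " attempts")
}

## ---- gene construction -----------------------------------------------

## Build one coding gene: transcript sequence with UTRs and CDS, optional
## planted feature (uORF/dORF/altORF/isoform), random 1-3 exon structure.
.makeCodingGene <- function(gid, feature = "none", utrLen = 90L) {
  nCod <- sample(40:70, 1L)
  planted <- NULL
  cdsPep <- paste0("M", .randPeptide(nCod - 1L))
  if (feature == "isoform") {
    substr(cdsPep, 15L, 15L) <- "M"
  }
  cdsNt <- paste0(.revTranslate(cdsPep), "TAA")
  if (feature == "altORF") {
    repeat {
      cdsPep <- paste0("M", .randPeptide(nCod - 1L))
      cdsNt <- paste0(.revTranslate(cdsPep), "TAA")
      hits <- .scanSequence(cdsNt, "ATG", 5L, 25L)
      hits <- hits[hits$frame != 0L & hits$txEnd < nchar(cdsNt), ,
                   drop = FALSE]
      if (nrow(hits) > 0L) { altHit <- hits[1L, ]; break }
    }
  }
  utr5 <- .randDna(utrLen)
  utr3 <- .randDna(utrLen)
  if (feature == "uORF") {
    L <- sample(5:20, 1L)
    pep <- paste0("M", .randPeptide(L - 1L))
    nt <- .orfNt(pep)
    utr5 <- paste0(.randDna(6L), nt, .randDna(utrLen - 6L - nchar(nt)))
    planted <- list(category = "uORF", txStart = 6L,
                    txEnd = 6L + nchar(nt), peptide = pep)
  }
  if (feature == "dORF") {
    L <- sample(5:20, 1L)
    pep <- paste0("M", .randPeptide(L - 1L))
    nt <- .orfNt(pep)
    utr3 <- paste0(.randDna(3L), nt, .randDna(utrLen - 3L - nchar(nt)))
    planted <- list(category = "dORF",
                    txStart = utrLen + nchar(cdsNt) + 3L,
                    txEnd = utrLen + nchar(cdsNt) + 3L + nchar(nt),
                    peptide = pep)
  }
  if (feature == "altORF") {
    planted <- list(category = "altORF",
                    txStart = utrLen + altHit$txStart,
                    txEnd = utrLen + altHit$txEnd,
                    peptide = altHit$peptide)
  }
  if (feature == "isoform") {
    planted <- list(category = "isoform",
                    txStart = utrLen + 14L * 3L,
                    txEnd = utrLen + nchar(cdsNt),
                    peptide = substr(cdsPep, 15L, nCod))
  }
  list(txSeq = paste0(utr5, cdsNt, utr3),
       cdsStart = utrLen, cdsEnd = utrLen + nchar(cdsNt),
       cdsPeptide = cdsPep, biotype = "protein_coding", planted = planted)
}

.makeNcrnaGene <- function(gid, plantOrf = FALSE, txLen = 300L) {
  seq <- .randDna(txLen)
  planted <- NULL
  if (plantOrf) {
    L <- sample(5:20, 1L)
    pep <- paste0("M", .randPeptide(L - 1L))
    nt <- .orfNt(pep)
    seq <- paste0(substr(seq, 1L, 30L), nt,
                  substr(seq, 31L + nchar(nt), txLen))
    planted <- list(category = "ncRNA", txStart = 30L,
                    txEnd = 30L + nchar(nt), peptide = pep)
  }
  list(txSeq = seq, cdsStart = NA_integer_, cdsEnd = NA_integer_,
       cdsPeptide = NA_character_, biotype = "ncRNA", planted = planted)
}

## Split a transcript into 1-3 exons and place it on the genome at
## geneStart (1-based), returning the genomic locus sequence and exon
## GRanges ordered 5'->3' in transcript orientation.
.placeGene <- function(txSeq, strandc, geneStart, chrom, protectFrom = 0L) {
  txLen <- nchar(txSeq)
  nEx <- sample(1:3, 1L)
  lo <- max(30L, protectFrom)  # avoid splitting too close to transcript ends
  cutRange <- seq(lo, txLen - 30L)
  cuts <- if (nEx > 1L && length(cutRange) >= nEx - 1L)
    sort(sample(cutRange, nEx - 1L)) else integer(0)
  bounds <- c(0L, cuts, txLen)  # tx-relative exon spans [bounds[i], bounds[i+1])
  exW <- diff(bounds)
  intrW <- if (length(exW) > 1L) sample(50:80, length(exW) - 1L,
                                        replace = TRUE) else integer(0)
  segs <- character(0)
  segOff <- integer(0)  # tx-oriented offset of each exon within the locus
  off <- 0L
  for (i in seq_along(exW)) {
    segOff[i] <- off
    segs <- c(segs, substr(txSeq, bounds[i] + 1L, bounds[i + 1L]))
    off <- off + exW[i]
    if (i < length(exW)) {
      segs <- c(segs, .randDna(intrW[i]))
      off <- off + intrW[i]
    }
  }
  locusTx <- paste(segs, collapse = "")
  L <- nchar(locusTx)
  if (strandc == "+") {
    st <- geneStart + segOff
    en <- st + exW - 1L
  } else {
    en <- geneStart + L - segOff - 1L
    st <- en - exW + 1L
  }
  list(locusSeq = if (strandc == "+") locusTx else revComp(locusTx),
       exons = GRanges(chrom, IRanges(st, en), strand = strandc))
}

## ---- main generator --------------------------------------------------

#' Generate a synthetic fixture world with known ground truth
#'
#' Builds, entirely from the seeded RNG in `spec`, a small genome with
#' annotated multi-exon coding genes and ncRNA genes; plants ORFs of every
#' requested category (uORF, dORF, ncRNA, altORF, isoform on transcripts;
#' intergenic in spacers); derives the reference proteome from the
#' annotated CDSs; builds two prediction sets whose length multisets have
#' exactly the requested medians and share a stated fraction of entries;
#' and emits a homology table with planted conserved queries and
#' identification tables with a planted per-engine overlap structure.
#' Every planted transcript-hosted ORF is verified to be rediscovered by
#' [scanOrfs], spliced sequences are checked against the constructed
#' transcripts, and (when requested) the undetectable protein is verified
#' with [digestDatabase], before any file is written.
#'
#' @param spec a [FixtureSpec-class].
#' @param outdir optional output directory; when given, all fixture files
#'   plus a JSON manifest with md5 checksums are written there.
#' @return A list with in-memory fixtures: `genome` (`DNAStringSet`),
#'   `transcripts` ([TranscriptSet-class]), `reference`, `predA`, `predB`
#'   (`AAStringSet`s), `orfTruth` (an [OrfSet-class] of planted ORFs),
#'   `truthTable` (planted categories and sources), `homology` and
#'   `homologyTruth`, `idTable` and `idTruth`, `undetectableAccession`,
#'   and `files` (written paths, when `outdir` given).
#' @export
generateFixtures <- function(spec, outdir = NULL) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  set.seed(spec@seed)
  chrom <- "chrS"
  po <- spec@plantedOrfs

  ## feature assignment: one planted feature per gene
  feats <- c(rep("uORF", po[["uORF"]]), rep("dORF", po[["dORF"]]),
             rep("altORF", po[["altORF"]]), rep("isoform", po[["isoform"]]))
  feats <- c(feats, rep("none", spec@nCodingGenes - length(feats)))
  ncPlant <- c(rep(TRUE, po[["ncRNA"]]),
               rep(FALSE, spec@nNcrnaGenes - po[["ncRNA"]]))

  genes <- list()
  for (i in seq_len(spec@nCodingGenes))
    genes[[length(genes) + 1L]] <- c(.makeCodingGene(i, feats[i]),
                                     list(gid = sprintf("geneC%02d", i),
                                          tid = sprintf("txC%02d", i)))
  for (i in seq_len(spec@nNcrnaGenes))
    genes[[length(genes) + 1L]] <- c(.makeNcrnaGene(i, ncPlant[i]),
                                     list(gid = sprintf("geneN%02d", i),
                                          tid = sprintf("txN%02d", i)))
  genes <- genes[sample.int(length(genes))]  # shuffle gene order on chromosome

  ## chromosome layout: spacer, gene, spacer, gene ... ; intergenic ORFs
  ## get their own spacers
  segs <- character(0)
  pos <- 1L  # next free 1-based position
  addSeg <- function(s) {
    segs <<- c(segs, s)
    p0 <- pos
    pos <<- pos + nchar(s)
    p0
  }
  interTruth <- list()
  nInter <- po[["intergenic"]]
  if (nInter > length(genes))
    stop("infeasible spec: more intergenic ORFs than gene spacers")
  exonsList <- list()
  txRows <- list()
  plantedRows <- list()

  for (k in seq_along(genes)) {
    g <- genes[[k]]
    if (k <= nInter) {
      L <- sample(5:20, 1L)
      pep <- paste0("M", .randPeptide(L - 1L))
      nt <- .orfNt(pep)
      s0 <- addSeg(paste0(.randDna(60L), nt, .randDna(60L)))
      oStart <- s0 + 60L
      interTruth[[k]] <- list(peptide = pep, start = oStart,
                              end = oStart + nchar(nt) - 1L)
    } else {
      addSeg(.randDna(80L))
    }
    strandc <- sample(c("+", "-"), 1L)
    placed <- .placeGene(g$txSeq, strandc, pos, chrom)
    addSeg(placed$locusSeq)
    exonsList[[g$tid]] <- placed$exons
    txRows[[g$tid]] <- DataFrame(txId = g$tid, geneId = g$gid,
                                 biotype = g$biotype,
                                 cdsStart = g$cdsStart, cdsEnd = g$cdsEnd)
    if (!is.null(g$planted))
      plantedRows[[g$tid]] <- c(g$planted, list(tid = g$tid))
  }
  addSeg(.randDna(80L))
  genomeSeq <- paste(segs, collapse = "")
  if (nchar(genomeSeq) > spec@chromLength)
    stop("infeasible spec: layout needs ", nchar(genomeSeq),
         " nt but chromLength is ", spec@chromLength)
  genome <- setNames(DNAStringSet(genomeSeq), chrom)
  transcripts <- TranscriptSet(GRangesList(exonsList),
                               do.call(rbind, unname(txRows)))

  ## self-check: spliced sequences reproduce the constructed transcripts
  spl <- splicedSequence(transcripts, genome)
  for (g in genes)
    stopifnot(identical(as.character(spl[[g$tid]]), g$txSeq))

  ## planted transcript-hosted ORFs must be rediscovered by scanOrfs
  scan <- scanOrfs(transcripts, genome, maxLenAa = NULL, source = "planted")
  sod <- orfData(scan)
  truthIdx <- integer(0)
  truthCat <- character(0)
  for (p in plantedRows) {
    hit <- which(sod$txId == p$tid & sod$txStart == p$txStart &
                 sod$txEnd == p$txEnd)
    if (length(hit) != 1L || sod$peptide[hit] != p$peptide)
      stop("planted ", p$category, " ORF on ", p$tid,
           " not rediscovered by scanOrfs")
    truthIdx <- c(truthIdx, hit)
    truthCat <- c(truthCat, p$category)
  }
  orfTruth <- scan[truthIdx]
  tod <- orfData(orfTruth)
  tod$orfId <- sprintf("planted_%s_%s", truthCat, tod$txId)
  truthBlocks <- orfBlocks(orfTruth)

  ## intergenic planted ORFs: direct genomic records (plus strand)
  if (nInter > 0L) {
    interRows <- list()
    interBlocks <- list()
    for (k in seq_len(nInter)) {
      it <- interTruth[[k]]
      ntLen <- it$end - it$start + 1L
      pepCheck <- translateNt(substr(genomeSeq, it$start, it$end))
      stopifnot(identical(pepCheck, paste0(it$peptide, "*")))
      oid <- sprintf("planted_intergenic_%02d", k)
      interRows[[k]] <- DataFrame(
        orfId = oid, txId = NA_character_, frame = 0L,
        txStart = 0L, txEnd = ntLen, chrom = chrom, strand = "+",
        stopPos = it$end, startCodon = "ATG", peptide = it$peptide,
        source = "planted")
      interBlocks[[k]] <- GRanges(chrom, IRanges(it$start, it$end),
                                  strand = "+")
      truthCat <- c(truthCat, "intergenic")
    }
    tod <- rbind(tod, do.call(rbind, interRows))
    truthBlocks <- c(truthBlocks, GRangesList(interBlocks))
  }
  names(truthBlocks) <- tod$orfId
  orfTruth <- OrfSet(tod, truthBlocks)
  truthTable <- data.frame(orfId = tod$orfId, category = truthCat,
                           txId = tod$txId, peptide = tod$peptide,
                           stringsAsFactors = FALSE)

  ## reference proteome from annotated CDSs
  refPep <- vapply(genes[vapply(genes, function(g)
    g$biotype == "protein_coding", logical(1))],
    function(g) g$cdsPeptide, character(1))
  refAcc <- sprintf("REF%03d", seq_along(refPep))
  reference <- setNames(refPep, refAcc)

  ## prediction sets: planted peptides split across sets (every third in
  ## both), shared fillers, then per-set fillers pinning the exact median
  planted <- setNames(truthTable$peptide, truthTable$orfId)
  idx <- seq_along(planted)
  inA <- idx %% 3L != 2L   # 1st, 3rd, 4th, 6th ... in A
  inB <- idx %% 3L != 1L   # 2nd, 3rd, 5th, 6th ... in B
  predA <- planted[inA]
  predB <- planted[inB]
  undetAcc <- NULL
  if (spec@plantUndetectable) {
    und <- plantUndetectableProtein()
    undetAcc <- "PRED_UNDET"
    predA <- c(predA, setNames(und$protein, undetAcc))
    reference <- c(reference, REFHOST = und$host)
  }
  nShared <- max(0L, round(spec@overlapFraction * 20))
  if (nShared > 0L) {
    shared <- vapply(sample(seq(8L, 24L), nShared, replace = TRUE),
                     .randPeptide, character(1))
    names(shared) <- sprintf("SHARED%03d", seq_len(nShared))
    predA <- c(predA, shared)
    predB <- c(predB, shared)
  }
  fillA <- .balanceToMedian(nchar(predA), spec@predAMedian)
  fillB <- .balanceToMedian(nchar(predB), spec@predBMedian)
  predA <- c(predA, setNames(vapply(fillA, .randPeptide, character(1)),
                             sprintf("PREDA%03d", seq_along(fillA))))
  predB <- c(predB, setNames(vapply(fillB, .randPeptide, character(1)),
                             sprintf("PREDB%03d", seq_along(fillB))))
  stopifnot(median(nchar(predA)) == spec@predAMedian,
            median(nchar(predB)) == spec@predBMedian)

  ## homology fixture: planted-conserved queries against 4 species dbs
  speciesDbs <- c("human", "mouse", "fly", "zebrafish")
  qids <- sprintf("Q%03d", seq_len(spec@nQueries))
  conserved <- qids[seq_len(spec@nConserved)]
  homRows <- list()
  for (q in qids) {
    if (q %in% conserved) {
      dbs <- sample(speciesDbs, sample(1:4, 1L))
      for (d in dbs)
        homRows[[length(homRows) + 1L]] <- data.frame(
          queryId = q, subjectId = paste0(d, "_", q),
          percentIdentity = round(runif(1, 30, 95), 1), alnLength = 50,
          mismatches = 5, gapOpens = 0, qStart = 1, qEnd = 50, sStart = 1,
          sEnd = 50, evalue = 10^-runif(1, 11, 30),
          bitscore = round(runif(1, 60, 200), 1), speciesDb = d,
          stringsAsFactors = FALSE)
    } else if (runif(1) < 0.5) {
      d <- sample(speciesDbs, 1L)
      homRows[[length(homRows) + 1L]] <- data.frame(
        queryId = q, subjectId = paste0(d, "_", q),
        percentIdentity = round(runif(1, 20, 60), 1), alnLength = 40,
        mismatches = 15, gapOpens = 1, qStart = 1, qEnd = 40, sStart = 1,
        sEnd = 40, evalue = 10^-runif(1, 2, 9),
        bitscore = round(runif(1, 20, 50), 1), speciesDb = d,
        stringsAsFactors = FALSE)
    }
  }
  homology <- do.call(rbind, homRows)
  homologyTruth <- data.frame(queryId = qids,
                              conserved = qids %in% conserved,
                              stringsAsFactors = FALSE)

  ## identification tables with planted per-engine overlap structure
  nAll <- spec@idCommon + spec@idUniqueA + spec@idUniqueB
  idAcc <- sprintf("NCP%04d", seq_len(nAll))
  common <- idAcc[seq_len(spec@idCommon)]
  uniqA <- idAcc[spec@idCommon + seq_len(spec@idUniqueA)]
  uniqB <- idAcc[spec@idCommon + spec@idUniqueA + seq_len(spec@idUniqueB)]
  mkRows <- function(accs, engine) data.frame(
    accession = accs, nUniquePeptides = sample(1:8, length(accs),
                                               replace = TRUE),
    condition = "WL", engine = engine, replicate = "r1",
    stringsAsFactors = FALSE)
  idTable <- rbind(mkRows(c(common, uniqA), "engine1"),
                   mkRows(c(common, uniqB), "engine2"))
  idTruth <- list(common = length(common), uniqueEngine1 = length(uniqA),
                  uniqueEngine2 = length(uniqB))

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    writeFasta(genome, fp("genome.fa"))
    writeAnnotation(transcripts, fp("annotation.gff3"))
    writeFasta(AAStringSet(reference), fp("reference.fa"))
    writeFasta(AAStringSet(predA), fp("predictions_A.fa"))
    writeFasta(AAStringSet(predB), fp("predictions_B.fa"))
    write.table(truthTable, fp("orf_truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(homology[, c(.BLAST6_COLS, "speciesDb")],
                fp("homology.tsv"), sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    write.table(idTable, fp("identifications.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    outFiles <- c("genome.fa", "annotation.gff3", "reference.fa",
                  "predictions_A.fa", "predictions_B.fa", "orf_truth.tsv",
                  "homology.tsv", "identifications.tsv")
    manifest <- list(seed = spec@seed,
                     files = lapply(setNames(outFiles, outFiles), function(f)
                       list(path = f,
                            md5 = unname(tools::md5sum(fp(f))))))
    write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
               pretty = TRUE)
    files <- vapply(c(outFiles, "manifest.json"), fp, character(1))
  }

  list(genome = genome, transcripts = transcripts,
       reference = AAStringSet(reference),
       predA = AAStringSet(predA), predB = AAStringSet(predB),
       orfTruth = orfTruth, truthTable = truthTable,
       homology = homology, homologyTruth = homologyTruth,
       idTable = idTable, idTruth = idTruth,
       undetectableAccession = undetAcc, files = files)
}
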