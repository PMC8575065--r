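test_that("readFasta preserves order, reports duplicates and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  rec <- readFasta(f)
  expect_equal(as.character(rec$id), "a")
  expect_equal(as.character(rec$description), "")
  expect_equal(as.character(rec$sequence), "ACGT")

  writeLines(c(">x first", "AAA", ">x second", "CCC"), f)
  expect_warning(rec <- readFasta(f), "duplicate")
  expect_equal(nrow(rec), 2L)
  expect_equal(as.character(rec$sequence), c("AAA", "CCC"))

  writeLines(character(0), f)
  expect_equal(nrow(readFasta(f)), 0L)

  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(readFasta(f), "line 1")
})

test_that("FASTA write/read round-trips id and sequence pairs", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- setNames(vapply(c(80L, 3L, 150L), randomDna, character(1), pN = 0),
                   c("s1", "s2", "s3"))
  writeFasta(seqs, f)
  rec <- readFasta(f)
  expect_equal(as.character(rec$id), names(seqs))
  expect_equal(as.character(rec$sequence), unname(seqs))
})

test_that("translateNt follows the standard code, stops and ambiguity rules", {
  expect_equal(translateNt("ATG"), "M")
  expect_equal(translateNt("TAA"), "*")
  expect_equal(translateNt("atggcctaa"), "MA*")
  expect_error(translateNt("ATGC"), "divisible by 3")
  expect_warning(pep <- translateNt("ATGANTTAA"), "ambiguous")
  expect_equal(pep, "MX*")
})

test_that("translation is invariant under double reverse complement", {
  set.seed(21)
  for (i in 1:20) {
    nt <- randomDna(3L * sample(2:40, 1))
    expect_identical(translateNt(revComp(revComp(nt))), translateNt(nt))
  }
})

test_that("restriction-site scan covers both strands with forward offsets", {
  expect_equal(findRestrictionSites("CCGCTC", "CCGCTC"),
               data.frame(site = "CCGCTC", strand = "+", offset = 0L))
  expect_equal(nrow(findRestrictionSites("AAAA", "CCGCTC")), 0L)
  # reverse-strand hit: GAGCGG on the forward strand is CCGCTC on the minus
  hits <- findRestrictionSites("TTGAGCGGTT", "CCGCTC")
  expect_equal(hits$strand, "-")
  expect_equal(hits$offset, 2L)
})

test_that("checkTagInsert verifies frame, translation and tagging", {
  set.seed(31)
  # toy ORF of 84 codons + stop, mirroring a C-terminal HiBit knock-in
  orfPep <- paste0("M", randomPeptide(83L))
  orfNt <- paste0(vapply(strsplit(orfPep, "")[[1]], function(a) {
    cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cods[1]
  }, character(1)), collapse = "")
  orfNt <- paste0(orfNt, "TAA")
  rep <- checkTagInsert(orfNt, hibitInsertRaw())
  expect_true(rep@insertIsInframe)
  expect_equal(rep@tagLength, 11L)
  expect_equal(nchar(rep@taggedPeptide), 84L + 11L)
  expect_equal(rep@taggedPeptide, paste0(orfPep, rep@tagPeptide))

  expect_false(checkTagInsert(orfNt, "TAA")@insertIsInframe)
  expect_match(checkTagInsert(orfNt, "TAA")@reason, "stop")
  ins32 <- substr(strrep("GC", 16L), 1L, 32L)
  expect_false(checkTagInsert(orfNt, ins32)@insertIsInframe)
  expect_match(checkTagInsert(orfNt, ins32)@reason, "divisible")
})

test_that("annotation reading converts coordinates and assigns biotypes", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  genome <- Biostrings::DNAStringSet(c(chr1 = randomDna(60L)))
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttranscript\t11\t40\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t11\t40\t.\t+\t.\tID=t1.e1;Parent=t1"), gff)
  ts <- readAnnotation(gff, genome)
  ex <- txExons(ts)[["t1"]]
  expect_equal(start(ex), 11L)
  expect_equal(end(ex), 40L)
  expect_equal(splicedLength(ts)[["t1"]], 30L)
  # no CDS -> ncRNA, no cds span
  expect_equal(txData(ts)$biotype, "ncRNA")
  expect_true(is.na(txData(ts)$cdsStart))
})

test_that("minus-strand multi-exon transcripts splice and map correctly", {
  set.seed(41)
  # 60-nt toy genome; transcript on minus strand with exons 41-55 and 11-25
  g <- randomDna(60L)
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttranscript\t11\t55\t.\t-\t.\tID=tm;Parent=gm",
    "chr1\ttest\texon\t41\t55\t.\t-\t.\tID=tm.e1;Parent=tm",
    "chr1\ttest\texon\t11\t25\t.\t-\t.\tID=tm.e2;Parent=tm"), gff)
  ts <- readAnnotation(gff, genome)
  spl <- splicedSequence(ts, genome)[["tm"]]
  manual <- paste0(revComp(substr(g, 41, 55)), revComp(substr(g, 11, 25)))
  expect_equal(as.character(spl), manual)
  # exons ordered 5'->3' of the transcript: genomically decreasing
  ex <- txExons(ts)[["tm"]]
  expect_equal(start(ex), c(41L, 11L))
})

test_that("out-of-frame CDS is dropped with a warning; out-of-bounds exon errors", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 25L)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttranscript\t1\t30\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t1\t30\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chr1\ttest\tCDS\t4\t11\t.\t+\t.\tID=t1.c1;Parent=t1"), gff)
  expect_warning(ts <- readAnnotation(gff, genome), "divisible by 3")
  expect_true(is.na(txData(ts)$cdsStart))

  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\ttranscript\t90\t130\t.\t+\t.\tID=t2;Parent=g2",
    "chr1\ttest\texon\t90\t130\t.\t+\t.\tID=t2.e1;Parent=t2"), gff)
  expect_error(readAnnotation(gff, genome), "bounds")
})

test_that("annotation round-trips through GFF3 export", {
  fx <- generateFixtures(fixtureSpec(seed = 5, plantUndetectable = FALSE))
  out <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotation(fx$transcripts, out)
  back <- readAnnotation(out, fx$genome)
  expect_identical(txIds(back), txIds(fx$transcripts))
  for (tid in txIds(back)) {
    expect_equal(start(txExons(back)[[tid]]), start(txExons(fx$transcripts)[[tid]]))
    expect_equal(end(txExons(back)[[tid]]), end(txExons(fx$transcripts)[[tid]]))
  }
  expect_equal(txData(back)$cdsStart, txData(fx$transcripts)$cdsStart)
  expect_equal(txData(back)$cdsEnd, txData(fx$transcripts)$cdsEnd)
})

test_that("spliced sequence handles strands and splicing; length invariant holds", {
  one <- singleTxSet("ATGTAA", strand = "+")
  expect_equal(as.character(splicedSequence(one$ts, one$genome)[[1]]), "ATGTAA")
  # one exon [1,6] on the minus strand of genomic ATGTAA
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6), strand = "-")
  ts <- TranscriptSet(GenomicRanges::GRangesList(t1 = ex),
                      S4Vectors::DataFrame(txId = "t1", geneId = "g",
                                           biotype = "ncRNA",
                                           cdsStart = NA, cdsEnd = NA))
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGTAA"))
  expect_equal(as.character(splicedSequence(ts, genome)[[1]]), "TTACAT")
  # two exons [1,3] and [7,9] of ATGxxxTAA splice to ATGTAA
  ex2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 7), c(3, 9)),
                                strand = "+")
  ts2 <- TranscriptSet(GenomicRanges::GRangesList(t2 = ex2),
                       S4Vectors::DataFrame(txId = "t2", geneId = "g",
                                            biotype = "ncRNA",
                                            cdsStart = NA, cdsEnd = NA))
  genome2 <- Biostrings::DNAStringSet(c(chr1 = "ATGCCCTAA"))
  expect_equal(as.character(splicedSequence(ts2, genome2)[[1]]), "ATGTAA")
  expect_equal(unname(nchar(as.character(splicedSequence(ts2, genome2)))),
               unname(splicedLength(ts2)))
})
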