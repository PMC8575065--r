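test_that("scanOrfs finds the worked example ORF with frame and peptide", {
  w <- singleTxSet("AAATGGCCTAAGG")
  orfs <- scanOrfs(w$ts, w$genome)
  expect_equal(length(orfs), 1L)
  od <- orfData(orfs)
  expect_equal(od$peptide, "MA")
  expect_equal(od$frame, 2L)
  expect_equal(od$startCodon, "ATG")
  expect_equal(od$txStart, 2L)
  expect_equal(od$txEnd, 11L)
  # genomic stop key: last base of TAA at 1-based position 11
  expect_equal(od$stopPos, 11L)
})

test_that("length floor and sORF ceiling are enforced at the boundary", {
  w <- singleTxSet("ATGTGA")
  expect_equal(length(scanOrfs(w$ts, w$genome, minLenAa = 2L)), 0L)
  expect_equal(length(scanOrfs(w$ts, w$genome, minLenAa = 1L)), 1L)

  mk <- function(nAa) paste0("ATG", strrep("GCC", nAa - 1L), "TAA")
  w100 <- singleTxSet(mk(100L))
  w101 <- singleTxSet(mk(101L))
  expect_equal(length(scanOrfs(w100$ts, w100$genome, maxLenAa = 100L)), 1L)
  expect_equal(length(scanOrfs(w101$ts, w101$genome, maxLenAa = 100L)), 0L)
  expect_equal(length(scanOrfs(w101$ts, w101$genome)), 1L)
})

test_that("candidates with ambiguous bases in a codon are disqualified", {
  w <- singleTxSet("ATGANTGCCTAA")
  expect_equal(length(scanOrfs(w$ts, w$genome)), 0L)
})

test_that("scanOrfs agrees with the translate-and-walk brute force on random transcripts", {
  set.seed(53)
  for (i in 1:40) {
    seqStr <- randomDna(sample(60:400, 1), pN = 0.01)
    w <- singleTxSet(seqStr)
    got <- orfData(scanOrfs(w$ts, w$genome, minLenAa = 2L))
    got <- got[order(got$txStart, got$frame), , drop = FALSE]
    want <- oracleScanOrfs(seqStr, minLen = 2L)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$txStart, want$txStart)
    expect_equal(got$txEnd, want$txEnd)
    expect_equal(got$peptide, want$peptide)
  }
})

test_that("every ORF re-translates to its recorded peptide (round trip)", {
  fx <- generateFixtures(fixtureSpec(seed = 17, plantUndetectable = FALSE))
  orfs <- scanOrfs(fx$transcripts, fx$genome, maxLenAa = 100L)
  od <- orfData(orfs)
  spl <- splicedSequence(fx$transcripts, fx$genome)
  for (k in sample(length(orfs), min(30L, length(orfs)))) {
    nt <- substr(as.character(spl[[od$txId[k]]]), od$txStart[k] + 1L,
                 od$txEnd[k])
    expect_identical(translateNt(nt), paste0(od$peptide[k], "*"))
  }
})

test_that("raising the length ceiling never removes a retained ORF", {
  fx <- generateFixtures(fixtureSpec(seed = 19, plantUndetectable = FALSE))
  o80 <- orfData(scanOrfs(fx$transcripts, fx$genome, maxLenAa = 80L))$orfId
  o100 <- orfData(scanOrfs(fx$transcripts, fx$genome, maxLenAa = 100L))$orfId
  expect_true(all(o80 %in% o100))
})

.mkOrfRow <- function(orfId, peptide, stopPos, txStart = 0L, chrom = "c",
                      strand = "+", txId = "t") {
  S4Vectors::DataFrame(orfId = orfId, txId = txId, frame = 0L,
                       txStart = txStart,
                       txEnd = txStart + 3L * (nchar(peptide) + 1L),
                       chrom = chrom, strand = strand, stopPos = stopPos,
                       startCodon = "ATG", peptide = peptide,
                       source = "test")
}

test_that("collapseSharedStops keeps the longest candidate per genomic stop", {
  od <- rbind(.mkOrfRow("a", randomPeptide(30L), 900L, txStart = 60L),
              .mkOrfRow("b", randomPeptide(50L), 900L, txStart = 0L),
              .mkOrfRow("c", randomPeptide(10L), 500L))
  got <- collapseSharedStops(OrfSet(od))
  expect_equal(sort(orfData(got)$orfId), c("b", "c"))

  single <- OrfSet(.mkOrfRow("only", "MAK", 42L))
  expect_equal(orfData(collapseSharedStops(single))$orfId, "only")
})

test_that("collapse matches brute-force grouping and leaves no shared keys", {
  set.seed(59)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    stops <- sample(c(100L, 200L, 300L, 400L), n, replace = TRUE)
    od <- do.call(rbind, lapply(seq_len(n), function(i)
      .mkOrfRow(sprintf("o%02d", i), randomPeptide(sample(5:40, 1)),
                stops[i], txStart = sample(0:30, 1) * 3L)))
    got <- orfData(collapseSharedStops(OrfSet(od)))
    key <- paste(got$chrom, got$strand, got$stopPos)
    expect_false(anyDuplicated(key) > 0)
    # brute force: per stop, maximal peptide length
    for (s in unique(stops)) {
      grp <- od[od$stopPos == s, ]
      kept <- got[got$stopPos == s, ]
      expect_equal(nrow(kept), 1L)
      expect_equal(nchar(kept$peptide), max(nchar(grp$peptide)))
    }
  }
})

test_that("dedupeSequences keeps first occurrence per distinct peptide", {
  od <- rbind(.mkOrfRow("a", "MAAAK", 10L), .mkOrfRow("b", "MAAAK", 20L),
              .mkOrfRow("c", "MCCCK", 30L))
  got <- orfData(dedupeSequences(OrfSet(od)))
  expect_equal(got$orfId, c("a", "c"))
  distinct <- OrfSet(rbind(.mkOrfRow("x", "MAK", 1L), .mkOrfRow("y", "MCK", 2L)))
  expect_equal(length(dedupeSequences(distinct)), 2L)
})
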