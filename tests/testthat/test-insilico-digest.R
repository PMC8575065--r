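test_that("tryptic cleavage follows the K/R-not-before-P rule", {
  expect_setequal(cleave("MKRAK", "trypsin", 0L)$peptide, c("MK", "R", "AK"))
  expect_setequal(cleave("MKRPAK", "trypsin", 0L)$peptide, c("MK", "RPAK"))
  p1 <- cleave("MKRAK", "trypsin", 1L)$peptide
  expect_setequal(p1, c("MK", "R", "AK", "MKR", "RAK"))
})

test_that("chymotryptic cleavage uses F/W/Y/L not before P", {
  expect_setequal(cleave("AFGWPL", "chymotrypsin", 0L)$peptide,
                  c("AF", "GWPL"))
})

test_that("monoisotopic masses match the independent elemental-composition oracle", {
  # expected values computed from atomic monoisotopic weights
  expect_equal(monoisotopicMass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(monoisotopicMass("PEPTIDE"), 799.35996, tolerance = 1e-4)
  expect_equal(monoisotopicMass("MKRAK"), 632.37920, tolerance = 1e-4)
  expect_equal(monoisotopicMass("ACDEFGHIKLMNPQRSTVWY"), 2394.12491,
               tolerance = 1e-4)
  # permutation invariance
  expect_equal(monoisotopicMass("AAAAAAK"), monoisotopicMass("AAAKAAA"))
  expect_error(monoisotopicMass(""), "empty")
  expect_error(monoisotopicMass("ABZ"), "nonstandard")
})

test_that("cleave matches the substring-enumeration oracle across enzymes and missed counts", {
  set.seed(83)
  for (rep in 1:30) {
    p <- randomPeptide(sample(5:100, 1))
    for (enz in c("trypsin", "chymotrypsin")) {
      residues <- if (enz == "trypsin") c("K", "R") else c("F", "W", "Y", "L")
      for (m in 0:2) {
        got <- cleave(p, enz, m)
        got <- got[order(got$start, got$end), , drop = FALSE]
        want <- oracleCleave(p, residues, m)
        expect_equal(got$peptide, want$peptide)
        expect_equal(got$nMissed, want$nMissed)
      }
    }
  }
})

test_that("zero-missed products tile the parent protein", {
  set.seed(89)
  for (rep in 1:20) {
    p <- randomPeptide(sample(10:80, 1))
    prod <- cleave(p, "trypsin", 0L)
    expect_identical(paste(prod$peptide[order(prod$start)], collapse = ""), p)
  }
})

test_that("shared tryptic peptides are non-unique after pooling", {
  db <- assembleDatabase(reference = c(P1 = "MWWKAAAAAAKDDDR",
                                       P2 = "MCCKAAAAAAK"))
  dig <- digestDatabase(db, digestConfig(massMin = 1, massMax = 1e6,
                                         lenMin = 1L, lenMax = 100L,
                                         missedCleavages = 0L))
  pep <- dig$peptides
  expect_false(pep$unique[pep$peptide == "AAAAAAK"])
  expect_equal(pep$parents[pep$peptide == "AAAAAAK"], "P1;P2")
  expect_true(pep$unique[pep$peptide == "MWWK"])
})

test_that("length and mass windows are inclusive at their boundaries", {
  # products of lengths 6, 7, 30, 31 from one protein
  p <- paste0(strrep("A", 5), "K", strrep("C", 6), "K", strrep("D", 29), "K",
              strrep("E", 31))
  db <- assembleDatabase(reference = setNames(p, "PX"))
  dig <- digestDatabase(db, digestConfig(missedCleavages = 0L,
                                         massMin = 1, massMax = 1e6))
  lens <- nchar(dig$peptides$peptide)
  expect_setequal(lens, c(7L, 30L))

  # mass boundary pinned exactly: window edges set to a product's mass
  pep <- "CCCCCCK"  # the 7-residue product
  m <- monoisotopicMass(pep)
  inWin <- digestDatabase(db, digestConfig(missedCleavages = 0L,
                                           massMin = m, massMax = m + 0.5))
  expect_equal(inWin$peptides$peptide, pep)
  outWin <- digestDatabase(db, digestConfig(missedCleavages = 0L,
                                            massMin = m + 1e-3,
                                            massMax = 4000))
  expect_false(pep %in% outWin$peptides$peptide)
  # defaults: 600-4000 Da excludes light/heavy products
  defaultWin <- digestDatabase(db, digestConfig(missedCleavages = 0L))
  expect_true(all(defaultWin$peptides$mass >= 600 &
                    defaultWin$peptides$mass <= 4000))
})

test_that("widening the windows never decreases a protein's unique count", {
  set.seed(97)
  refs <- setNames(vapply(rep(60L, 8), randomPeptide, character(1)),
                   sprintf("P%d", 1:8))
  db <- assembleDatabase(reference = refs)
  narrow <- digestDatabase(db, digestConfig(massMin = 700, massMax = 3000,
                                            lenMin = 8L, lenMax = 25L))
  wide <- digestDatabase(db, digestConfig(massMin = 600, massMax = 4000,
                                          lenMin = 7L, lenMax = 30L))
  expect_true(all(wide$perProtein$nUnique >= narrow$perProtein$nUnique))
})

test_that("digest output is invariant to protein input order", {
  set.seed(101)
  refs <- setNames(vapply(rep(50L, 6), randomPeptide, character(1)),
                   sprintf("P%d", 1:6))
  db1 <- assembleDatabase(reference = refs)
  db2 <- assembleDatabase(reference = refs[sample(length(refs))])
  d1 <- digestDatabase(db1)
  d2 <- digestDatabase(db2)
  expect_equal(d1$peptides$peptide, d2$peptides$peptide)
  expect_equal(d1$peptides$parents, d2$peptides$parents)
  pp1 <- d1$perProtein[order(d1$perProtein$accession), ]
  pp2 <- d2$perProtein[order(d2$perProtein$accession), ]
  expect_equal(pp1$nUnique, pp2$nUnique)
})

test_that("I/L equivalence pools isobaric peptides for uniqueness", {
  db <- assembleDatabase(reference = c(P1 = "MIIIIIIKDDDR",
                                       P2 = "MLLLLLLKEEER"))
  cfg0 <- digestConfig(massMin = 1, massMax = 1e6, lenMin = 1L,
                       lenMax = 100L, missedCleavages = 0L)
  expect_true(all(digestDatabase(db, cfg0)$peptides$unique))
  cfgIL <- digestConfig(massMin = 1, massMax = 1e6, lenMin = 1L,
                        lenMax = 100L, missedCleavages = 0L,
                        ilEquivalence = TRUE)
  pepIL <- digestDatabase(db, cfgIL)$peptides
  shared <- pepIL[grepl("^M[IL]+K$", pepIL$peptide), ]
  expect_false(any(shared$unique))
})
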