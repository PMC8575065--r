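.idRow <- function(acc, n, engine = "e1", cond = "WL", sub = FALSE) {
  data.frame(accession = acc, nUniquePeptides = n, condition = cond,
             engine = engine, replicate = "r1", isSubgroup = sub,
             stringsAsFactors = FALSE)
}

.toyDb <- function() {
  assembleDatabase(reference = c(R1 = "MAAAWWWK", R2 = "MCCCWWWK"),
                   predA = c(A1 = "MDDDWWWK", A2 = "MEEEWWWK"),
                   contaminants = c(C1 = "MFFFWWWK"),
                   host = c(H1 = "MGGGWWWK"))
}

test_that("identification filters drop contaminants, zero-unique and subgroup rows", {
  db <- .toyDb()
  tab <- rbind(.idRow("R1", 3), .idRow("R2", 0), .idRow("A1", 2),
               .idRow("C1", 5), .idRow("H1", 4), .idRow("A2", 1, sub = TRUE))
  out <- loadAndFilter(tab, db)
  expect_setequal(out$accession, c("R1", "A1"))
  # 10-row toy table with 3 rows failing the filters
  tab10 <- rbind(.idRow(sprintf("R%d", c(1, 2)), c(2, 3)),
                 .idRow(sprintf("A%d", c(1, 2)), c(1, 2)),
                 .idRow("R1", 0), .idRow("C1", 2), .idRow("H1", 1),
                 .idRow(c("R2", "A1", "A2"), c(5, 6, 7), engine = "e2"))
  expect_equal(nrow(loadAndFilter(tab10, db)), 7L)
})

test_that("contaminant and min-unique filters commute", {
  db <- .toyDb()
  tab <- rbind(.idRow("R1", 3), .idRow("C1", 0), .idRow("H1", 3),
               .idRow("A1", 0), .idRow("A2", 2))
  ab <- loadAndFilter(loadAndFilter(tab, db, minUnique = 0L,
                                    dropContaminants = TRUE),
                      db, minUnique = 1L, dropContaminants = FALSE)
  ba <- loadAndFilter(loadAndFilter(tab, db, minUnique = 1L,
                                    dropContaminants = FALSE),
                      db, minUnique = 0L, dropContaminants = TRUE)
  expect_equal(ab$accession, ba$accession)
})

test_that("unknown accessions warn and are kept unless strict", {
  db <- .toyDb()
  tab <- .idRow("NOVEL9", 2)
  expect_warning(out <- loadAndFilter(tab, db), "absent")
  expect_equal(nrow(out), 1L)
  expect_error(suppressWarnings(loadAndFilter(tab, db, strict = TRUE)),
               "absent")
})

test_that("classification splits canonical, isoform and novel identifications", {
  db <- .toyDb()
  cats <- data.frame(accession = c("A1", "A2"),
                     category = c("uORF", "isoform"))
  tab <- rbind(.idRow("R1", 3), .idRow("A1", 2), .idRow("A2", 2))
  out <- classifyNoncanonical(tab, db, cats)
  expect_equal(out$class, c("canonical", "novel", "isoform"))
  # prediction accession without category: novel-uncategorized with warning
  expect_warning(
    out2 <- classifyNoncanonical(.idRow("A1", 1), db, NULL),
    "uncategorized")
  expect_equal(out2$class, "novel-uncategorized")
  # merged reference+prediction entries count as canonical
  db2 <- assembleDatabase(reference = c(R1 = "MAAAWWWK"),
                          predA = c(A9 = "MAAAWWWK"))
  out3 <- classifyNoncanonical(.idRow("R1", 2), db2, NULL)
  expect_equal(out3$class, "canonical")
})

test_that("overlap summaries compute exact intersections and unique counts", {
  tab <- rbind(.idRow(c("a", "b", "c"), 1, engine = "e1"),
               .idRow(c("b", "c", "d"), 1, engine = "e2"))
  ov <- overlapSummary(tab, "engine")
  expect_equal(ov$n[ov$type == "intersection"], 2L)
  expect_equal(ov$n[ov$type == "unique"], c(1L, 1L))
  # three identical sets: all mass in the triple intersection
  tab3 <- do.call(rbind, lapply(c("e1", "e2", "e3"), function(e)
    .idRow(c("x", "y"), 1, engine = e)))
  ov3 <- overlapSummary(tab3, "engine")
  expect_equal(ov3$n[ov3$groups == "e1+e2+e3" & ov3$type == "intersection"], 2L)
  expect_true(all(ov3$n[ov3$type == "unique"] == 0L))
})

test_that("inclusion-exclusion holds on random and planted fixtures", {
  set.seed(113)
  for (rep in 1:5) {
    accPool <- sprintf("P%03d", 1:60)
    tab <- do.call(rbind, lapply(c("e1", "e2", "e3"), function(e)
      .idRow(sample(accPool, sample(20:50, 1)), 1, engine = e)))
    ov <- overlapSummary(tab, "engine")
    g <- function(groups, type) ov$n[ov$groups == groups & ov$type == type]
    ie <- g("e1", "size") + g("e2", "size") + g("e3", "size") -
      g("e1+e2", "intersection") - g("e1+e3", "intersection") -
      g("e2+e3", "intersection") + g("e1+e2+e3", "intersection")
    expect_equal(g("e1+e2+e3", "union"), ie)
  }
})

test_that("the planted per-engine overlap structure is recovered exactly", {
  fx <- generateFixtures(fixtureSpec(seed = 43, plantUndetectable = FALSE))
  ov <- overlapSummary(fx$idTable, "engine")
  expect_equal(ov$n[ov$groups == "engine1+engine2" &
                      ov$type == "intersection"],
               fx$idTruth$common)
  expect_equal(ov$n[ov$groups == "engine1" & ov$type == "unique"],
               fx$idTruth$uniqueEngine1)
  expect_equal(ov$n[ov$groups == "engine2" & ov$type == "unique"],
               fx$idTruth$uniqueEngine2)
})
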