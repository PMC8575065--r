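## Best-hit filtering of tabular protein homology searches against
## multiple species databases, and per-query conservation summaries.

.BLAST6_COLS <- c("queryId", "subjectId", "percentIdentity", "alnLength",
                  "mismatches", "gapOpens", "qStart", "qEnd", "sStart",
                  "sEnd", "evalue", "bitscore")

#' Read a 12-column tabular homology result (outfmt-6 style)
#'
#' Rows with non-numeric values in numeric fields are skipped with a
#' warning naming the line numbers. A 13th column, when present, is used
#' as the species database label; otherwise `speciesDb` is applied.
#'
#' @param path TSV path.
#' @param speciesDb species-database label for all rows (default: file
#'   base name) when the table has no 13th column.
#' @return data.frame with the 12 standard columns plus `speciesDb`.
#' @export
readHomologyTable <- function(path, speciesDb = NULL) {
  if (is.null(speciesDb))
    speciesDb <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), .BLAST6_COLS))
    out$speciesDb <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  numIdx <- c(3:12)
  rows <- vector("list", length(parts))
  bad <- integer(0)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 12L) { bad <- c(bad, i); next }
    num <- suppressWarnings(as.numeric(f[numIdx]))
    if (anyNA(num)) { bad <- c(bad, i); next }
    rows[[i]] <- data.frame(
      queryId = f[1L], subjectId = f[2L], percentIdentity = num[1L],
      alnLength = num[2L], mismatches = num[3L], gapOpens = num[4L],
      qStart = num[5L], qEnd = num[6L], sStart = num[7L], sEnd = num[8L],
      evalue = num[9L], bitscore = num[10L],
      speciesDb = if (length(f) >= 13L) f[13L] else speciesDb,
      stringsAsFactors = FALSE)
  }
  if (length(bad) > 0L)
    warning("skipped ", length(bad), " malformed row(s) at line(s) ",
            paste(bad, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), .BLAST6_COLS))
    out$speciesDb <- character(0)
  }
  out
}

#' Retain the single best homology hit per query and species database
#'
#' Hits with E-value above `eThreshold` are discarded; among the
#' survivors, the hit with the lowest E-value is kept per (query, species
#' database) pair, ties broken by highest percent identity, then highest
#' bitscore, then lexicographic subject id — a deterministic stand-in for
#' manual inspection.
#'
#' @param hits data.frame from [readHomologyTable] (columns `queryId`,
#'   `subjectId`, `percentIdentity`, `evalue`, `bitscore`, `speciesDb`).
#' @param eThreshold E-value cutoff, inclusive (default 1e-10).
#' @return data.frame of retained hits, one row per (query, speciesDb).
#' @export
bestHits <- function(hits, eThreshold = 1e-10) {
  stopifnot(all(c("queryId", "subjectId", "percentIdentity", "evalue",
                  "bitscore", "speciesDb") %in% colnames(hits)))
  hits <- hits[hits$evalue <= eThreshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$queryId, hits$speciesDb, sep = "\r")
  o <- order(key, hits$evalue, -hits$percentIdentity, -hits$bitscore,
             hits$subjectId)
  out <- hits[o[!duplicated(key[o])], , drop = FALSE]
  out <- out[order(out$queryId, out$speciesDb), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-query conservation summary over species databases
#'
#' @param best data.frame of retained hits from [bestHits].
#' @param nSpeciesMin minimum number of species databases with a retained
#'   hit for a query to be flagged conserved (default 1).
#' @param queries optional character vector of all query ids, so that
#'   queries without any surviving hit appear with count 0.
#' @return data.frame with columns `queryId`, `nSpecies`, `conserved`.
#' @export
conservationSummary <- function(best, nSpeciesMin = 1L, queries = NULL) {
  counts <- if (nrow(best) > 0L)
    tapply(best$speciesDb, best$queryId,
           function(x) length(unique(x)))
  else integer(0)
  ids <- union(queries, names(counts))
  n <- setNames(integer(length(ids)), ids)
  n[names(counts)] <- as.integer(counts)
  out <- data.frame(queryId = ids, nSpecies = unname(n),
                    conserved = unname(n) >= nSpeciesMin,
                    stringsAsFactors = FALSE)
  out[order(out$queryId), , drop = FALSE]
}
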