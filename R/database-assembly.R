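## Assembly of the final searchable database: reference proteome,
## prediction sets, contaminant and host proteomes, with provenance and
## composition/length reporting.

.asAAChar <- function(x, what) {
  if (is.null(x)) return(setNames(character(0), character(0)))
  v <- setNames(as.character(x), names(x))
  if (length(v) > 0L && is.null(names(v)))
    stop(what, " sequences must be named by accession")
  if (anyDuplicated(names(v)))
    stop(what, " contains duplicated accessions: ",
         paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
  toupper(v)
}

#' Assemble a provenance-aware protein search database
#'
#' Reference and prediction entries with identical amino-acid sequence are
#' merged into one entry with the union of source labels (overlap
#' categories are meaningful at sequence level, not accession level); the
#' merged entry keeps the accession of its highest-priority source
#' (reference > predA > predB) and records the other member accessions in
#' its description. Contaminant and host entries are appended unmerged,
#' flagged, and excluded from composition percentages. Length class is
#' assigned at the 100-aa boundary (small = <= 100 aa).
#'
#' @param reference,predA,predB,contaminants,host named character vectors
#'   or `AAStringSet`s of protein sequences keyed by accession; any may be
#'   `NULL`/empty.
#' @param mergeIdentical merge identical sequences across non-contaminant
#'   sources (default). `FALSE` keeps the literal concatenation (every
#'   input entry becomes its own record).
#' @return An [AllOrfDb-class].
#' @export
assembleDatabase <- function(reference = NULL, predA = NULL, predB = NULL,
                             contaminants = NULL, host = NULL,
                             mergeIdentical = TRUE) {
  inputs <- list(reference = .asAAChar(reference, "reference"),
                 predA = .asAAChar(predA, "predA"),
                 predB = .asAAChar(predB, "predB"),
                 contaminant = .asAAChar(contaminants, "contaminants"),
                 host = .asAAChar(host, "host"))
  ## accession collision with differing sequences is an input error
  allAcc <- unlist(lapply(inputs, names), use.names = FALSE)
  allSeq <- unlist(inputs, use.names = FALSE)
  dup <- allAcc[duplicated(allAcc)]
  for (a in unique(dup)) {
    s <- unique(allSeq[allAcc == a])
    if (length(s) > 1L)
      stop("accession collision with differing sequences: ", a, " (",
           paste(substr(s, 1L, 20L), collapse = " vs "), ")")
  }

  prio <- c("reference", "predA", "predB")
  pool <- do.call(rbind, lapply(prio, function(src) {
    v <- inputs[[src]]
    if (length(v) == 0L) return(NULL)
    data.frame(accession = names(v), sequence = unname(v), source = src,
               stringsAsFactors = FALSE)
  }))
  entries <- list()
  if (!is.null(pool) && nrow(pool) > 0L) {
    groupKey <- if (mergeIdentical) pool$sequence
                else paste(pool$source, pool$accession)
    for (g in unique(groupKey)) {
      rows <- pool[groupKey == g, , drop = FALSE]
      src <- unique(rows$source)
      prim <- prio[prio %in% src][1L]
      acc <- rows$accession[rows$source == prim][1L]
      others <- setdiff(rows$accession, acc)
      desc <- paste0("sources=", paste(src, collapse = "+"),
                     if (length(others))
                       paste0(";members=", paste(others, collapse = ",")))
      entries[[length(entries) + 1L]] <- list(
        accession = acc, sequence = rows$sequence[1L], sources = src,
        primarySource = prim, isContaminant = FALSE, description = desc)
    }
  }
  for (src in c("contaminant", "host")) {
    v <- inputs[[src]]
    for (i in seq_along(v)) {
      entries[[length(entries) + 1L]] <- list(
        accession = names(v)[i], sequence = unname(v[i]), sources = src,
        primarySource = src, isContaminant = TRUE,
        description = paste0("sources=", src))
    }
  }
  .buildDb(entries, lapply(inputs, names))
}

.buildDb <- function(entries, sourceSets) {
  if (length(entries) == 0L) {
    return(new("AllOrfDb", entries = AAStringSet(),
               entryData = DataFrame(accession = character(),
                                     sources = CharacterList(),
                                     primarySource = character(),
                                     lengthClass = character(),
                                     isContaminant = logical(),
                                     description = character()),
               sourceSets = sourceSets))
  }
  acc <- vapply(entries, `[[`, character(1), "accession")
  seqs <- vapply(entries, `[[`, character(1), "sequence")
  ed <- DataFrame(
    accession = acc,
    sources = CharacterList(lapply(entries, `[[`, "sources")),
    primarySource = vapply(entries, `[[`, character(1), "primarySource"),
    lengthClass = ifelse(nchar(seqs) <= 100L, "small", "large"),
    isContaminant = vapply(entries, `[[`, logical(1), "isContaminant"),
    description = vapply(entries, `[[`, character(1), "description"))
  new("AllOrfDb", entries = setNames(AAStringSet(seqs), acc),
      entryData = ed, sourceSets = sourceSets)
}

#' Write an AllOrfDb as a search-ready FASTA
#'
#' Headers follow the dialect `>{source}|{accession} {description}` with
#' source one of ref, predA, predB, crap, host (the entry's primary
#' source), so contaminant filtering downstream can key on the prefix.
#' The description carries the full source membership, making
#' [readDatabase] a faithful round-trip.
#'
#' @param db an [AllOrfDb-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeDatabase <- function(db, path) {
  ed <- dbEntryData(db)
  hdr <- sprintf("%s|%s %s", .SOURCE_PREFIX[ed$primarySource],
                 ed$accession, ed$description)
  seqs <- setNames(dbEntries(db), hdr)
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a dialected database FASTA back into an AllOrfDb
#'
#' @param path FASTA written by [writeDatabase].
#' @return An [AllOrfDb-class]; source membership is reconstructed from
#'   the `sources=` description tag.
#' @export
readDatabase <- function(path) {
  rec <- readFasta(path)
  if (nrow(rec) > 0L && !all(grepl("^(ref|predA|predB|crap|host)\\|", rec$id)))
    stop("not a dialected database FASTA: headers must start with ",
         "ref|/predA|/predB|/crap|/host|")
  prefix <- sub("\\|.*$", "", rec$id)
  revmap <- setNames(names(.SOURCE_PREFIX), .SOURCE_PREFIX)
  acc <- sub("^[^|]*\\|", "", rec$id)
  entries <- lapply(seq_len(nrow(rec)), function(i) {
    srcTag <- sub("^sources=([^;[:space:]]+).*$", "\\1", rec$description[i])
    src <- strsplit(srcTag, "+", fixed = TRUE)[[1L]]
    if (length(src) == 0L || !all(src %in% .SOURCE_LEVELS))
      src <- unname(revmap[prefix[i]])
    list(accession = acc[i], sequence = rec$sequence[i], sources = src,
         primarySource = unname(revmap[prefix[i]]),
         isContaminant = unname(revmap[prefix[i]]) %in%
           c("contaminant", "host"),
         description = rec$description[i])
  })
  sourceSets <- lapply(setNames(.SOURCE_LEVELS, .SOURCE_LEVELS), function(s)
    acc[vapply(entries, function(e) s %in% e$sources, logical(1))])
  .buildDb(entries, sourceSets)
}

#' Database composition by source combination
#'
#' One row per non-empty source combination among non-contaminant entries
#' with counts, percentages of the non-contaminant total, and small/large
#' splits, followed by small/large marginal rows.
#'
#' @param db an [AllOrfDb-class].
#' @return data.frame with columns `combination`, `count`, `percent`,
#'   `small`, `large`.
#' @export
compositionReport <- function(db) {
  ed <- dbEntryData(db)
  ed <- ed[!ed$isContaminant, , drop = FALSE]
  if (nrow(ed) == 0L)
    return(data.frame(combination = character(), count = integer(),
                      percent = numeric(), small = integer(),
                      large = integer()))
  combo <- vapply(ed$sources, function(s)
    paste(sort(unname(s)), collapse = "+"), character(1))
  total <- nrow(ed)
  rows <- lapply(sort(unique(combo)), function(cb) {
    sel <- combo == cb
    data.frame(combination = cb, count = sum(sel),
               percent = 100 * sum(sel) / total,
               small = sum(sel & ed$lengthClass == "small"),
               large = sum(sel & ed$lengthClass == "large"))
  })
  marg <- lapply(c("small", "large"), function(lc) {
    sel <- ed$lengthClass == lc
    data.frame(combination = paste0("all_", lc), count = sum(sel),
               percent = 100 * sum(sel) / total,
               small = sum(sel & lc == "small"),
               large = sum(sel & lc == "large"))
  })
  do.call(rbind, c(rows, marg))
}

#' Per-source peptide length summaries
#'
#' Median and quartiles of entry length (aa) per source label; entries
#' belonging to several sources count once under each. The midpoint
#' convention for even counts (R's default `median`) and type-7 quantiles
#' are used and recorded in the output metadata.
#'
#' @param db an [AllOrfDb-class].
#' @return data.frame with columns `source`, `n`, `median`, `q1`, `q3`
#'   (NA for empty sources); attribute `medianConvention` = "midpoint".
#' @export
lengthSummary <- function(db) {
  ed <- dbEntryData(db)
  len <- width(dbEntries(db))
  rows <- lapply(.SOURCE_LEVELS, function(src) {
    sel <- vapply(ed$sources, function(s) src %in% s, logical(1))
    l <- len[sel]
    data.frame(source = src, n = length(l),
               median = if (length(l)) median(l) else NA_real_,
               q1 = if (length(l)) unname(quantile(l, 0.25)) else NA_real_,
               q3 = if (length(l)) unname(quantile(l, 0.75)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "medianConvention") <- "midpoint"
  out
}
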