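## Merging of protein-identification tables across conditions and search
## engines: contaminant and minimum-unique-peptide filtering, canonical /
## isoform / novel classification, and set-overlap statistics.

#' Load and filter a protein-identification table
#'
#' Input tables are assumed pre-thresholded by the search engine (e.g. at
#' 1% FDR); this function only applies the declared row filters:
#' contaminant/host accessions, rows below the minimum unique-peptide
#' count, and rows pre-flagged as subgroup (non-razor) proteins — the
#' subgroup flag is consumed from the input, protein inference itself is
#' the search engine's job. The filters commute.
#'
#' @param table data.frame (or TSV/CSV path) with columns `accession`,
#'   `nUniquePeptides`, and optionally `condition`, `engine`, `replicate`,
#'   `isSubgroup`.
#' @param db optional [AllOrfDb-class]; used to resolve contaminant status
#'   from source membership. Without it, contaminant status falls back to
#'   the `crap|`/`host|` header prefix.
#' @param minUnique minimum unique-peptide count (default 1).
#' @param dropContaminants remove contaminant/host accessions (default TRUE).
#' @param topGroupOnly remove rows with `isSubgroup == TRUE` (default TRUE).
#' @param strict error (rather than warn) on accessions absent from `db`.
#' @return the filtered data.frame, with an added `isContaminant` column.
#' @export
loadAndFilter <- function(table, db = NULL, minUnique = 1L,
                          dropContaminants = TRUE, topGroupOnly = TRUE,
                          strict = FALSE) {
  if (is.character(table) && length(table) == 1L) {
    sep <- if (grepl("\\.csv$", table)) "," else "\t"
    table <- read.delim(table, sep = sep, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("accession", "nUniquePeptides") %in% colnames(table)))
  acc <- as.character(table$accession)
  if (!is.null(db)) {
    ed <- dbEntryData(db)
    idx <- match(acc, ed$accession)
    unknown <- is.na(idx)
    if (any(unknown)) {
      msg <- paste0(sum(unknown), " accession(s) absent from database: ",
                    paste(head(unique(acc[unknown]), 5L), collapse = ", "))
      if (strict) stop(msg) else warning(msg, " (rows kept as novel)")
    }
    isContam <- !unknown & ed$isContaminant[ifelse(unknown, 1L, idx)]
  } else {
    isContam <- grepl("^(crap|host)\\|", acc)
  }
  table$isContaminant <- isContam
  keep <- rep(TRUE, nrow(table))
  if (dropContaminants) keep <- keep & !isContam
  keep <- keep & table$nUniquePeptides >= minUnique
  if (topGroupOnly && "isSubgroup" %in% colnames(table))
    keep <- keep & !isTRUE2(table$isSubgroup)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## vectorized isTRUE tolerant of NA
isTRUE2 <- function(x) !is.na(x) & as.logical(x)

#' Classify identifications as canonical, isoform or novel
#'
#' Reference-source entries are canonical (reference evidence wins over a
#' co-occurring prediction source); prediction-only entries are
#' non-canonical and are split by their genomic-context category into
#' `isoform` versus `novel` (uORF/dORF/ncRNA/altORF/intergenic).
#' Prediction-only accessions without a category are classed
#' `novel-uncategorized` with a warning.
#'
#' @param table filtered identification data.frame (from [loadAndFilter]).
#' @param db an [AllOrfDb-class] carrying source membership.
#' @param categories optional data.frame mapping `accession` to `category`
#'   (e.g. built from [annotateOrfs] calls).
#' @return `table` with an added `class` column.
#' @export
classifyNoncanonical <- function(table, db, categories = NULL) {
  ed <- dbEntryData(db)
  idx <- match(as.character(table$accession), ed$accession)
  cls <- character(nrow(table))
  catMap <- if (!is.null(categories))
    setNames(as.character(categories$category),
             as.character(categories$accession))
  else character(0)
  nUncat <- 0L
  for (i in seq_len(nrow(table))) {
    if (is.na(idx[i])) { cls[i] <- "novel-uncategorized"; nUncat <- nUncat + 1L; next }
    src <- ed$sources[[idx[i]]]
    if ("reference" %in% src) { cls[i] <- "canonical"; next }
    if (ed$isContaminant[idx[i]]) { cls[i] <- "contaminant"; next }
    cat <- unname(catMap[as.character(table$accession[i])])
    if (length(cat) == 0L || is.na(cat)) {
      cls[i] <- "novel-uncategorized"; nUncat <- nUncat + 1L
    } else if (cat == "isoform") cls[i] <- "isoform"
    else cls[i] <- "novel"
  }
  if (nUncat > 0L)
    warning(nUncat, " prediction-only accession(s) without a category; ",
            "classed novel-uncategorized")
  table$class <- cls
  table
}

#' Set-overlap summary across groups of identifications
#'
#' Computes per-group accession-set sizes, per-group unique counts
#' (accessions seen in that group only) and all pairwise and higher-order
#' intersection sizes, in long format suitable for upset/Venn plotting.
#' When a `class` column is present (see [classifyNoncanonical]), the same
#' summary is also emitted restricted to the non-canonical subset
#' (`class != "canonical"`).
#'
#' @param table identification data.frame with an `accession` column and
#'   the grouping column.
#' @param groupBy name of the grouping column (e.g. `"engine"` or
#'   `"condition"`).
#' @return data.frame with columns `scope` (total/noncanonical), `groups`
#'   ("+"-joined group labels), `type` (size/unique/intersection), `n`.
#' @export
overlapSummary <- function(table, groupBy = "engine") {
  stopifnot(groupBy %in% colnames(table))
  groups <- sort(unique(as.character(table[[groupBy]])))
  if (length(groups) < 2L) stop("overlapSummary needs >= 2 groups")
  summarize <- function(tab, scope) {
    sets <- lapply(groups, function(g)
      unique(as.character(tab$accession[tab[[groupBy]] == g])))
    names(sets) <- groups
    rows <- list()
    for (g in groups) {
      others <- unique(unlist(sets[setdiff(groups, g)]))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, groups = g, type = "size", n = length(sets[[g]]))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, groups = g, type = "unique",
        n = length(setdiff(sets[[g]], others)))
    }
    for (k in 2:length(groups)) {
      for (combo in utils::combn(groups, k, simplify = FALSE)) {
        inter <- Reduce(intersect, sets[combo])
        rows[[length(rows) + 1L]] <- data.frame(
          scope = scope, groups = paste(combo, collapse = "+"),
          type = "intersection", n = length(inter))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scope = scope, groups = paste(groups, collapse = "+"),
      type = "union", n = length(unique(unlist(sets))))
    do.call(rbind, rows)
  }
  out <- summarize(table, "total")
  if ("class" %in% colnames(table)) {
    nc <- table[table$class != "canonical", , drop = FALSE]
    if (nrow(nc) > 0L) out <- rbind(out, summarize(nc, "noncanonical"))
  }
  rownames(out) <- NULL
  out
}
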