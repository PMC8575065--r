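## Interior-sequence containment filter: predictions already represented
## inside known/longer proteins are removed before database assembly.

#' Interior sequence of a peptide
#'
#' The peptide without its first and last residue — the portion tested for
#' identical overlap with known proteins, so that alternative start/stop
#' choices at the termini do not mask containment.
#'
#' @param p peptide string(s), each of length >= 3.
#' @return character vector of interior sequences.
#' @export
interiorSequence <- function(p) {
  if (any(nchar(p) < 3L))
    stop("peptide of length < 3 has no interior sequence")
  substr(p, 2L, nchar(p) - 1L)
}

#' Remove predictions contained in reference proteins
#'
#' A prediction is removed iff its interior sequence (first and last
#' residue excluded) occurs as an exact substring of any reference
#' protein; containment is exact, with no alignment, mismatches, or I/L
#' equating. Predictions shorter than 3 aa cannot be tested and are
#' removed with reason `"too short to test"`.
#'
#' @param predictions an [OrfSet-class], or a named character vector /
#'   `AAStringSet` of peptides.
#' @param references named character vector or `AAStringSet` of reference
#'   proteins (typically reference proteome plus long predicted proteins).
#' @return A list with elements `kept` (same type as `predictions`) and
#'   `removed` (data.frame with columns `id`, `peptide`, `reason`,
#'   `matchedAccession` — the first matching reference in input order).
#' @export
filterContained <- function(predictions, references) {
  refs <- setNames(as.character(references), names(references))
  if (length(refs) == 0L) stop("references must be non-empty")
  if (is.null(names(refs))) names(refs) <- paste0("REF", seq_along(refs))
  isOrfSet <- is(predictions, "OrfSet")
  peps <- if (isOrfSet) orfPeptides(predictions)
          else setNames(as.character(predictions),
                        if (is.null(names(predictions)))
                          paste0("Q", seq_along(predictions))
                        else names(predictions))
  n <- length(peps)
  removedIdx <- integer(0)
  reason <- character(0)
  matched <- character(0)
  for (i in seq_len(n)) {
    if (nchar(peps[i]) < 3L) {
      removedIdx <- c(removedIdx, i)
      reason <- c(reason, "too short to test")
      matched <- c(matched, NA_character_)
      next
    }
    q <- substr(peps[i], 2L, nchar(peps[i]) - 1L)
    hit <- which(grepl(q, refs, fixed = TRUE))
    if (length(hit) > 0L) {
      removedIdx <- c(removedIdx, i)
      reason <- c(reason, "interior contained in reference")
      matched <- c(matched, names(refs)[hit[1L]])
    }
  }
  removed <- data.frame(id = names(peps)[removedIdx],
                        peptide = unname(peps[removedIdx]),
                        reason = reason,
                        matchedAccession = matched,
                        stringsAsFactors = FALSE)
  if (nrow(removed) > 0L && any(removed$reason == "too short to test"))
    message(sum(removed$reason == "too short to test"),
            " prediction(s) too short to test; removed")
  keptIdx <- setdiff(seq_len(n), removedIdx)
  kept <- if (isOrfSet) predictions[keptIdx] else peps[keptIdx]
  list(kept = kept, removed = removed)
}
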