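## In-silico protease digestion, monoisotopic peptide mass, and
## unique-peptide detectability accounting over an assembled database.

## Monoisotopic residue masses (Da), standard 20 amino acids, derived from
## elemental composition with monoisotopic atomic weights.
.AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.WATER_MONO <- 18.0105646
.CAM_MONO <- 57.02146  # carbamidomethyl on C

.cleaveResidues <- function(cfg) {
  if (is.character(cfg)) {
    switch(cfg, trypsin = "KR", chymotrypsin = "FWYL",
           stop("unknown enzyme: ", cfg))
  } else if (cfg@enzyme == "trypsin") "KR" else cfg@chymoResidues
}

#' Cleave a protein sequence in silico
#'
#' Trypsin cleaves C-terminal to K or R, chymotrypsin C-terminal to
#' F, W, Y or L (configurable), both suppressed when the next residue is
#' proline. All products with up to `missedCleavages` internal uncut
#' sites are returned; with zero missed cleavages the products tile the
#' input.
#'
#' @param p protein sequence (standard residues).
#' @param enzyme `"trypsin"` or `"chymotrypsin"`, or a
#'   [DigestConfig-class] (whose enzyme/missed settings are used).
#' @param missedCleavages maximum internal uncut sites (default 0).
#' @return data.frame with columns `peptide`, `nMissed`, `start`, `end`
#'   (1-based positions in `p`), ordered by position.
#' @export
cleave <- function(p, enzyme = "trypsin", missedCleavages = 0L) {
  if (is(enzyme, "DigestConfig")) {
    missedCleavages <- enzyme@missedCleavages
  }
  residues <- strsplit(.cleaveResidues(enzyme), "")[[1L]]
  p <- as.character(p)
  n <- nchar(p)
  stopifnot(n > 0L)
  chars <- strsplit(p, "")[[1L]]
  ## cut after position i when chars[i] is a cleavage residue not followed by P
  cuts <- which(chars[-n] %in% residues & chars[-1L] != "P")
  bounds <- c(0L, cuts, n)
  nf <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + missedCleavages)
    for (j in i:jmax) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j + 1L], j - i)
    }
  }
  m <- do.call(rbind, out)
  data.frame(peptide = substring(p, m[, 1L], m[, 2L]),
             nMissed = m[, 3L], start = m[, 1L], end = m[, 2L],
             stringsAsFactors = FALSE)
}

#' Monoisotopic peptide mass
#'
#' Sum of standard monoisotopic residue masses plus one water; no
#' modifications unless fixed carbamidomethylation of cysteine is
#' requested.
#'
#' @param p character vector of peptides over the 20 standard residues.
#' @param carbamidomethyl add +57.02146 Da per cysteine.
#' @return numeric vector of masses in Da.
#' @export
monoisotopicMass <- function(p, carbamidomethyl = FALSE) {
  vapply(as.character(p), function(pep) {
    if (!nzchar(pep)) stop("cannot compute the mass of an empty peptide")
    chars <- strsplit(pep, "")[[1L]]
    m <- .AA_MONO[chars]
    if (anyNA(m))
      stop("nonstandard residue in peptide: ",
           paste(unique(chars[is.na(m)]), collapse = ""))
    s <- sum(m) + .WATER_MONO
    if (carbamidomethyl) s <- s + .CAM_MONO * sum(chars == "C")
    s
  }, numeric(1), USE.NAMES = FALSE)
}

#' Digest a database and account for unique-peptide detectability
#'
#' Every entry is cleaved with the configured enzyme and missed-cleavage
#' allowance; products outside the length or mass windows (boundaries
#' inclusive) are discarded; identical peptide strings are pooled into one
#' record with the union of parent accessions (redundancy clearance), and
#' uniqueness — exactly one parent — is computed after pooling, optionally
#' under I/L equivalence. The report aggregates unique-peptide counts per
#' protein and the fraction of proteins with zero unique peptides, overall
#' and per source and length class.
#'
#' @param db an [AllOrfDb-class].
#' @param cfg a [DigestConfig-class].
#' @return list with elements:
#'   \describe{
#'     \item{peptides}{data.frame `peptide`, `mass`, `nMissed` (minimum
#'       over occurrences), `nParents`, `parents` (";"-joined accessions),
#'       `unique`.}
#'     \item{perProtein}{data.frame `accession`, `nPeptides` (in-window
#'       products), `nUnique`, plus entry provenance columns.}
#'     \item{report}{list `zeroUniqueFraction` (overall), `bySource` and
#'       `byLengthClass` data.frames of zero-unique fractions.}
#'   }
#' @export
digestDatabase <- function(db, cfg = digestConfig()) {
  ed <- dbEntryData(db)
  seqs <- as.character(dbEntries(db))
  acc <- ed$accession
  pepList <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    prod <- cleave(seqs[i], cfg@enzyme, cfg@missedCleavages)
    len <- nchar(prod$peptide)
    prod <- prod[len >= cfg@lenMin & len <= cfg@lenMax, , drop = FALSE]
    prod <- prod[!duplicated(prod$peptide), , drop = FALSE]
    pepList[[i]] <- prod
  }
  allPep <- unlist(lapply(pepList, `[[`, "peptide"), use.names = FALSE)
  allMissed <- unlist(lapply(pepList, `[[`, "nMissed"), use.names = FALSE)
  parent <- rep(acc, vapply(pepList, nrow, integer(1)))

  uniqPep <- unique(allPep)
  mass <- monoisotopicMass(uniqPep, carbamidomethyl = cfg@carbamidomethyl)
  inWindow <- mass >= cfg@massMin & mass <= cfg@massMax
  keepPep <- uniqPep[inWindow]
  keep <- allPep %in% keepPep
  allPep <- allPep[keep]; allMissed <- allMissed[keep]
  parent <- parent[keep]

  poolKey <- if (cfg@ilEquivalence) chartr("I", "L", allPep) else allPep
  sp <- split(seq_along(allPep), poolKey)
  recs <- lapply(names(sp), function(k) {
    idx <- sp[[k]]
    par <- sort(unique(parent[idx]))
    list(peptide = allPep[idx[1L]], nMissed = min(allMissed[idx]),
         parents = par)
  })
  peptides <- data.frame(
    peptide = vapply(recs, `[[`, character(1), "peptide"),
    mass = monoisotopicMass(vapply(recs, `[[`, character(1), "peptide"),
                            carbamidomethyl = cfg@carbamidomethyl),
    nMissed = vapply(recs, `[[`, integer(1), "nMissed"),
    nParents = vapply(recs, function(r) length(r$parents), integer(1)),
    parents = vapply(recs, function(r) paste(r$parents, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  peptides$unique <- peptides$nParents == 1L
  peptides <- peptides[order(peptides$peptide), , drop = FALSE]
  rownames(peptides) <- NULL

  uniqueParents <- unlist(lapply(recs[vapply(recs, function(r)
    length(r$parents) == 1L, logical(1))], `[[`, "parents"))
  nUnique <- as.integer(table(factor(uniqueParents, levels = acc)))
  allParents <- unlist(lapply(recs, `[[`, "parents"))
  nPeptides <- as.integer(table(factor(allParents, levels = acc)))
  perProtein <- data.frame(accession = acc, nPeptides = nPeptides,
                           nUnique = nUnique,
                           primarySource = ed$primarySource,
                           lengthClass = ed$lengthClass,
                           isContaminant = ed$isContaminant,
                           stringsAsFactors = FALSE)

  zero <- perProtein$nUnique == 0L
  bySource <- do.call(rbind, lapply(.SOURCE_LEVELS, function(src) {
    sel <- vapply(ed$sources, function(s) src %in% s, logical(1))
    data.frame(source = src, n = sum(sel),
               zeroUniqueFraction = if (any(sel)) mean(zero[sel]) else NA_real_)
  }))
  byLen <- do.call(rbind, lapply(c("small", "large"), function(lc) {
    sel <- ed$lengthClass == lc & !ed$isContaminant
    data.frame(lengthClass = lc, n = sum(sel),
               zeroUniqueFraction = if (any(sel)) mean(zero[sel]) else NA_real_)
  }))
  list(peptides = peptides, perProtein = perProtein,
       report = list(zeroUniqueFraction = mean(zero),
                     bySource = bySource, byLengthClass = byLen))
}
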