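---
title: "Building and evaluating non-canonical ORF search databases"
author: "ProteoORF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating non-canonical ORF search databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoORF)
```

## The problem

Bottom-up (shotgun) proteomics identifies proteins by matching fragment
spectra against an in-silico digest of a sequence database. A protein
absent from the database is invisible, however abundant. Genome
annotations systematically exclude several classes of real translation
products: small ORFs under the historical 100-codon annotation cutoff,
ORFs in 5' and 3' UTRs (uORFs, dORFs), translation from transcripts
annotated as non-coding, and alternative-frame ORFs nested in coding
genes. ProteoORF implements the database-construction side of a
proteogenomic workflow for these products: predict, de-redundify and
concatenate candidate ORFs into a searchable database; quantify how much
of that database is even *detectable* by standard tryptic bottom-up
proteomics; and post-process identification lists (genomic-context
annotation, conservation screening, engine/condition overlaps).

## The procedure and its assumptions

### ORF enumeration

`scanOrfs()` enumerates, on each spliced transcript, every reading from
an allowed start codon to the first in-frame stop, in all three frames.
Assumptions worth stating:

* **Starts are sequence-derived.** Ribosome-profiling pipelines call
  translation initiation sites from elongating-ribosome coverage; this
  package deliberately does not process ribo-seq, so starts come from the
  sequence alone (AUG by default; `startCodons` accepts near-cognate NUG
  starts). A pure sequence scan therefore predicts a *superset* of a
  TIS-informed prediction set. This is a semantic difference, not a bug.
* **"100 codons"** is interpreted as peptide length ≤ 100 aa with the
  stop codon excluded from the count; the boundary is pinned by tests
  (100 aa kept, 101 aa excluded in sORF mode).
* Codons containing the ambiguity base N disqualify a candidate
  (conservative prediction); N is allowed in genomes and translates to X
  elsewhere.
* `minLenAa` defaults to 2, the shortest peptide with a residue beyond
  the initiator; no biological floor is assumed.

`collapseSharedStops()` keys redundancy on the *genomic* coordinate of
the stop codon's last base (chromosome, strand, position), so the same
physical ORF reached through different transcripts collapses to one
record — the longest; ties break deterministically (5'-most start, then
lexicographic id). `dedupeSequences()` then removes duplicated peptides,
keeping first occurrence.

### Redundancy against known proteins

`filterContained()` removes a prediction when its interior sequence —
the peptide minus its first and last residue, so that alternative
start/stop choices at the termini do not mask a match — occurs as an
exact substring of any supplied reference protein. Exact means exact: no
alignment, no mismatches, and no I/L equating (the rule is sequence-level,
not mass-spectrometric). Containment is tested against whatever the
caller supplies (typically reference proteome plus long predicted
proteins); contaminant databases are not included by default.

### Database assembly

`assembleDatabase()` merges reference and prediction entries *by exact
peptide identity*, because source-overlap composition ("prediction set A
+ reference", etc.) is only meaningful at sequence level. A merged entry
keeps the accession of its highest-priority source (reference > predA >
predB) — keeping reference accessions stable for downstream matching —
and records the other member accessions in its description. Contaminant
and host entries are appended unmerged, flagged, and excluded from
composition percentages, so adding a contaminant set never changes the
reported composition. `--keep-duplicates`-style literal concatenation is
available via `mergeIdentical = FALSE`, since whether identical
sequences should be merged across sources is a genuine modelling choice.
The FASTA header dialect `>{source}|{accession} {description}` is
bit-stable so contaminant filtering can key on the prefix, and
`readDatabase()` round-trips it.

`lengthSummary()` uses R's midpoint convention for even-count medians and
type-7 quantiles; the convention is recorded in the output because no
single convention is universal.

### In-silico digestion and detectability

`cleave()` implements trypsin (C-terminal to K/R, suppressed before P)
and chymotrypsin. For chymotrypsin the commonly used low-specificity set
minus methionine, {F, W, Y, L} not-before-P, is the default; the residue
set is configurable (`chymoResidues`) because the rule set is a
convention, not a fact about the enzyme.

Masses are **monoisotopic and unmodified** (residue masses derived from
elemental monoisotopic weights, plus one water). The mass window
(600–4000 Da) and length window (7–30 aa) are inclusive at both ends.
Whether such windows should be monoisotopic or average mass is usually
unstated in methods sections; monoisotopic is chosen here and stated. A
fixed carbamidomethyl (+57.02146 Da per C) can be switched on.

Uniqueness is computed after pooling identical peptide strings across the
whole database (redundancy clearance): a peptide is unique iff it has
exactly one parent entry. I/L equivalence for pooling is off by default
(sequence-exact, matching common redundancy-clearance tools) but
available, since isobaric I/L are indistinguishable by MS. No N-terminal
Met clipping and no semi-tryptic forms are generated. The detectability
report gives each protein's unique-peptide count and the zero-unique
fraction — the share of the database invisible to unique-peptide-based
identification — overall and per source and length class.

### Genomic-context categories

`annotateOrfs()` assigns exactly one category per ORF by a fixed-priority
cascade: **isoform** (shares an annotated CDS stop position, differing in
sequence/structure) → **uORF** (entirely within a coding transcript's
exons, 5' of the CDS start) → **dORF** (3' of the CDS stop) → **ncRNA**
(hosted on a non-coding transcript) → **altORF** (any remaining
transcript overlap, typically CDS overlap in a shifted frame or with a
distinct stop) → **intergenic** (no overlap). The priority order puts the
least-novel explanation first; published category counts are disjoint but
rarely state a precedence, so the order here is an explicit design
choice. uORF/dORF require full containment in the UTR — an ORF straddling
the CDS start falls through to altORF. Frame comparison is performed in
genomic coordinates through each feature's own exonic blocks
(splice-aware), because transcript-relative frames are meaningless across
isoforms. The sORF-vs-altORF distinction within alternative translation
products is not imposed; the database's `lengthClass` (≤ 100 aa) is
exposed alongside the category so either reading can be reproduced.

### Conservation screening

`bestHits()` consumes standard 12-column tabular homology results; it
filters, it does not run the search. Hits with E > 10⁻¹⁰ are discarded;
per (query, species database) the lowest-E hit is retained, ties broken
by highest percent identity, then bitscore, then subject id. Published
workflows often describe this retention as manual inspection; the
deterministic tiebreak replaces that and is documented as such. A query
is "conserved" with retained hits in ≥ `nSpeciesMin` species databases.

### Identification-table merging

`loadAndFilter()` consumes tables already thresholded by the search
engine (e.g. 1% FDR) — FDR is never recomputed here, because decoy-based
FDR belongs to the engine. Contaminant/host rows, rows below the
unique-peptide minimum, and rows pre-flagged as subgroup (non-razor)
proteins are dropped; the subgroup flag is consumed from the input, since
protein grouping is engine-specific. The filters commute.
`overlapSummary()` emits exact per-group sizes, unique counts and all
intersection orders in long format; significance testing of intersections
is out of scope — the output is the count table such tests consume.

## The synthetic world

`generateFixtures()` builds, from a single integer seed driving one RNG,
a chromosome of interleaved coding genes (5'UTR–CDS–3'UTR, 1–3 exons with
50–80 nt introns, random strand, CDSs of 40–70 codons), ncRNA genes, and
≥ 50 nt spacers, with planted ORFs of every category: uORFs/dORFs inside
UTRs, ncRNA-hosted ORFs, frame-shifted altORFs embedded inside CDS
sequence (found by bounded seeded retry), N-terminally truncated isoforms
starting at an in-frame internal Met, and intergenic ORFs in spacers. The
two prediction sets emulate the length structure of a sORF-style set
(median 25 aa) versus an altProt-style set (median 45 aa): planted and
shared peptides are complemented with filler peptides balanced so the
length multisets hit those medians *exactly*, and roughly 30% of entries
are shared between the sets (the complement of "unique to either set").
`plantUndetectableProtein()` constructs a prediction whose every tryptic
product is reproduced from a host protein that embeds it behind a
cleavage-compatible context, giving a guaranteed zero-unique entry that
is verified by actually digesting a two-entry database at generation
time.

Self-checks run before any file is written: spliced sequences must
reproduce the constructed transcripts, every transcript-hosted planted
ORF must be rediscovered by `scanOrfs()` with matching start/stop/frame,
intergenic ORFs must re-translate from the genome, and infeasible specs
(too few genes for the planted counts, layout exceeding the chromosome
length) error out first.

What the generator does **not** emulate: realistic codon usage or GC
content, splice-site dinucleotides, ribo-seq signal, spectra, retention
times, or engine-specific protein inference. A green fixture test
therefore establishes that the *rules* are implemented correctly — that
planted categories are recovered, planted medians are measured, planted
undetectability is detected — not that the package reproduces any
particular organism's database statistics, which depend on external
sequencing and MS data.

## Numerical and convention choices

* Genomic intervals are stored 1-based inclusive in `GRanges` (the
  native Bioconductor and GFF3 convention, eliminating I/O conversion);
  transcript-relative ORF/CDS coordinates are 0-based half-open, so
  `txEnd - txStart` is a length and `txStart %% 3` a frame. The boundary
  between the two conventions is crossed only inside the coordinate
  helpers.
* CDS spans include the stop codon, both in GFF3 input and in the
  transcript-relative representation.
* The genetic code is fixed to the standard nuclear table; stops render
  as `*`, ambiguous codons as `X` with a warning.
* All window boundaries (mass, length, E-value) are inclusive.
* Restriction-site scanning reports 0-based forward-strand offsets for
  both strands; palindromic sites are reported once. Printed tag
  sequences are stripped of non-ACGT characters (typographic zero-width
  artifacts) before use.
* Every tie in the toolkit breaks deterministically (documented per
  function), so all outputs are order-invariant and reproducible.

## Known limitations

* The ORF scanner predicts from sequence alone; without ribo-seq TIS
  evidence it over-predicts relative to translation-evidence pipelines.
* Containment filtering is exact-substring only; homology-aware
  redundancy reduction (CD-HIT-style clustering) is out of scope.
* Decoy generation for FDR is left to search engines.
* The homology module never executes a search binary; it consumes
  tabular results.
* Chromosome-scale genomes are handled, but the toolkit is tuned for the
  transcript counts of model-organism annotations, not metagenomes.
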