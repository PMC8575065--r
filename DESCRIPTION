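Package: ProteoORF
Title: Non-Canonical ORF Search Databases for Bottom-Up Proteogenomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds custom "all-ORF" protein search databases for the
    discovery of non-canonical translation products (small ORFs, uORFs,
    dORFs, ncRNA-encoded and alternative-frame proteins) by bottom-up mass
    spectrometry. Enumerates ORFs on spliced transcripts, collapses
    stop-site-redundant candidates, removes predictions contained in known
    proteins, concatenates prediction sets with reference and contaminant
    proteomes with full provenance, evaluates detectability by in-silico
    protease digestion with mass and length windows and unique-peptide
    accounting, assigns identified ORFs to genomic-context categories, and
    screens candidates for cross-species conservation by best-hit filtering
    of tabular homology searches. Ships a deterministic synthetic-fixture
    generator so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Proteogenomics, MassSpectrometry, Annotation
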