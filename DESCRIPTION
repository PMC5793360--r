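Package: peptrack
Title: Map Peptide-Spectrum Matches to Genome Coordinates as proBAM and proBed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects peptide-spectrum matches (PSMs) from shotgun proteomics
    onto genome coordinates through spliced, stranded gene models and encodes
    them in the proBAM (SAM dialect, 11 mandatory columns plus 21 proteomics
    tags) and proBed (25-column BED dialect) proteogenomics formats. Provides
    readers, writers and validators for both formats, interconversion between
    them, target-decoy q-value estimation, FDR filtering, aggregation of PSMs
    to peptides, gene-level inference and spectral counting, plus a fully
    synthetic genome/annotation/proteome/PSM simulator so the whole pipeline
    can be exercised with known ground truth. A command-line interface wraps
    the pipeline for shell use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
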