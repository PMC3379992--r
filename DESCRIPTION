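Package: glandscope
Title: Reference-Free Comparative Transcriptomics of a Tissue Versus a
    Whole-Body Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing a tissue transcriptome against a whole-body
    transcriptome when no reference genome exists. Discovers near-identical
    ortholog pairs between two de novo assemblies by seed-and-extend
    alignment, clips the shared aligned regions, counts reads on them,
    normalizes to RPKM and calls differential expression with the
    Audic-Claverie read-count statistic under FDR control. Also provides
    hypergeometric term enrichment of a study set against a background,
    signal-peptide plus transmembrane-domain triage of candidate secreted
    proteins, 2^-ddCt qPCR quantification with direction-concordance
    scoring, and a seeded synthetic-data generator with known ground truth
    so the whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
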