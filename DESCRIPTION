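Package: noszpipe
Title: Clade-Aware Identification of Nitrous Oxide Reductase Genes in
    Annotated Genomes, Primer Design, and Long-Read Amplicon Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the genetic potential for nitrous oxide
    (N2O) reduction in annotated genome assemblies. Detects nosZ genes and
    assigns them to the two major NosZ clades by normalized local-alignment
    scoring against curated reference panels, screens gene length, calls the
    tat/sec secretion pathway from N-terminal signal features, and verifies
    the clade-typical accessory genes nosB and nosR by gene-neighborhood
    proximity. Labels each genome's denitrification, DNRA and assimilatory
    nitrate reduction potential from KEGG-style module completeness and a
    genotype-to-phenotype decision table. Designs clade-specific degenerate
    long-fragment primer pairs under melting-temperature, GC, degeneracy and
    mismatch constraints, validates them with a mismatch-tolerant IUPAC-aware
    in-silico PCR, and processes long amplicon reads (filtering, UNOISE-style
    denoising into OTUs, consensus taxonomy against a lineage-annotated nosZ
    database). A synthetic-data module generates genomes, reference panels
    and error-bearing reads with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
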