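Package: nanotu
Title: OTU-Level Analysis of Oxford Nanopore Amplicon Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters error-prone Oxford Nanopore amplicon reads into
    operational taxonomic units (OTUs) and assembles a quality-weighted
    consensus sequence per cluster, for amplicons of any length. Reads are
    primer-checked, oriented and filtered, embedded by the centred log-ratio
    transform of their homopolymer-compressed k-mer signatures, reduced by
    PCA and UMAP, and clustered with HDBSCAN; each cluster's length- and
    GC-filtered reads are multiply aligned and a positional consensus is
    called from per-column base frequencies and mean Phred qualities.
    Supports per-sample ("single") and joint ("pool") clustering with
    per-sample composition restoration, BLAST-based taxonomy assignment of
    the resulting OTUs, and a ground-truth amplicon read simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: python (with umap-learn and scikit-learn) for UMAP and
    HDBSCAN; MAFFT (optional, internal aligner used as fallback); BLAST+
    (optional, for taxonomy); medaka (optional, for consensus polishing)
Config/testthat/edition: 3
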