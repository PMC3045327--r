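Package: dsxSplice
Title: Splice-Site Strength, Regulatory Motifs and Molecular Evolution
    of an Alternatively Spliced doublesex Locus
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence analysis toolkit for alternatively spliced insect
    doublesex (dsx) loci, built around the Aedes aegypti gene as the
    motivating case. Derives introns and exon-intron junction windows from
    gene models, scores splice-site strength (polypyrimidine-tract
    pyrimidine counts, GTRAGT donor consensus matches) and calls weak
    sites against a genome-wide acceptor consensus, scans for degenerate
    IUPAC splicing cis-elements (dsxRE, NvdsxRE, RBP1 sites, TRA-2-ISS)
    and purine-rich elements with bipartite region summaries, computes
    per-intron repeat-element densities (NoRE/kb, REbp), microsynteny
    quality, and partitioned pairwise dN/dS by the Nei-Gojobori method
    with Jukes-Cantor correction. Includes ground-truth synthetic data
    generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, SequenceMatching, Genetics, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
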