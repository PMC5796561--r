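Package: phageome
Title: Gut Phageome Profiling from Whole-Community Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies large phage scaffolds (>= 10 kb) in assembled gut
    metagenomes by three evidence strategies (CRISPR spacer probing, breadth
    of coverage by virus-like-particle reads, and homology to known phage
    genes), assigns phage family and bacterial genus labels by a weighted
    vote over homology hits (phage family ratio / bacterial genus ratio),
    profiles phage operational taxonomic units (pOTUs) normalized by 16S
    rRNA gene reads, infers phage-host links from CRISPR spacers, builds
    compositional co-occurrence networks between bacterial genera and
    pOTUs, and tests group-wise differential abundance with incidence-based
    richness estimation. Ships a fully specified synthetic-community
    generator with ground-truth tables so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
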