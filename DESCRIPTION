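Package: paleobov
Title: Ancient Cattle Mitogenome and Y-Marker Haplotyping Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for degraded (ancient) bovine
    sequencing data. Generates synthetic circular mitogenome references,
    haplotypes carrying diagnostic variant panels, and damaged short reads
    under a two-rate single-strand/double-strand cytosine deamination model;
    maps reads back to the circular reference with a seed-and-extend aligner;
    applies mapping-quality, mismatch and gap filters, duplicate removal and
    75 percent-threshold consensus calling; profiles terminal C-to-T / G-to-A
    misincorporations for ancient-DNA authentication; assigns mitochondrial
    haplogroups from hierarchical diagnostic-SNP panels and Y haplogroups from
    a five-intron SNP/microsatellite/indel marker matrix; and summarises
    cohorts with median-joining haplotype networks, haplotype diversity and
    haplogroup frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    xml2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
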