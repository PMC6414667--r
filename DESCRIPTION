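Package: phagedyn
Title: Read-Recruitment Analysis of Active Viral Infections in Marine
    Picoplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to track active viral infections in marine picoplankton
    communities from metagenomic (DNA) and metatranscriptomic (RNA) read
    recruitment to viral contigs and reference phage genomes. Implements
    trimmed-coverage abundance that is robust to conserved high-identity
    islands, persistence/ephemerality classification across a multi-site,
    multi-date sampling design, percent-identity recruitment spectra with
    population-structure classification (clonal, genomic continuum,
    discrete clouds), marker-gene (psbA / PS-II D1, Gp23) partitioning of
    expression into cyanobacterial and cyanophage origin with an
    infected-fraction estimator, and co-occurrence phage-host matching.
    Includes a synthetic community generator with controlled microdiversity
    and full ground truth, and a built-in seed-and-extend local aligner
    validated against exhaustive dynamic programming.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
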