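Package: hybridsip
Title: Hybrid DNA-SIP Metagenomics of Low-GC Populations and Their Viruses
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for hybrid DNA stable-isotope
    probing (SIP) metagenomics. Models isopycnic CsCl gradient migration of
    DNA as a function of GC content and 13C atom fraction, pools low and
    high buoyant-density (LBD/HBD) gradient fractions, samples replicate
    read libraries, recovers contigs from LBD libraries with a surrogate
    assembler, maps reads by exact k-mer assignment, identifies
    virus-derived contigs through hallmark-gene homology (capsid,
    terminase, portal, integrase), and tests per-feature 13C enrichment
    with replicate-wise Student/Welch t-tests. A synthetic two-soil
    community generator with known ground truth exercises the full
    pipeline end to end, including the co-migration of isotopically
    enriched low-GC genomes with unlabeled high-GC background DNA that
    motivates the LBD/HBD hybrid design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
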