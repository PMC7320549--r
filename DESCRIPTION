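Package: satjunction
Title: Screening for Transposase-Derived Satellite DNA Array Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects junctions between deletion derivatives of CACTA-like
    transposase (tnp2) domains and the satellite DNA arrays they seed, as found
    in Chenopodium genomes for the CficCl-61-40 satellite family. Provides
    mismatch-tolerant motif scanning on both strands, a native tandem-array
    detector with fractional copy number and majority-rule consensus calling,
    classification of complete (tnp2A) versus derivative (tnp2B) transposase
    fragments, junction validation with global-alignment percent identity,
    anchored monomer alignment with p-distances and a neighbor-joining tree,
    self-dot-plot tandem detection for ultralong reads, in silico PCR with
    outward-facing primers, and a ground-truth synthetic genome generator used
    as the test substrate for the whole screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
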