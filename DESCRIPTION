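Package: mitovir
Title: Genomic and Small-RNA Signatures for Host Assignment of Mitoviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize capsidless RNA viruses (mitoviruses and
    relatives) and assign their most likely host from sequence signatures and
    virus-host interaction data. Implements open-reading-frame discovery under
    alternative (mitochondrial) genetic codes, dinucleotide odds-ratio and
    codon-usage signatures with UPGMA correlation clustering, UGA(Trp) codon
    statistics, strand-resolved small-RNA size profiling with 5'-base
    enrichment and Kolmogorov-Smirnov comparison, a seed-driven progressive
    assembler, reads-per-million abundance with an endogenous-viral-element
    check, and an integrated multi-criterion host-evidence report. A synthetic
    data module generates genomes, coding sequences and read libraries with
    known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
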