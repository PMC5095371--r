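Package: pedimut
Title: De Novo Mutation Detection and Rate Estimation in Selfed Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects germline de novo mutations in parent/selfed-progeny
    sequencing designs (an F1 tree and its selfed F2 seedlings) and estimates
    per-site per-generation mutation rates.  Implements high-confidence
    genotype classification from stranded allele depths, rare-variant
    candidate screening with strand-aware read support and soft-masking,
    cluster (contamination) masking, two-caller consensus bookkeeping,
    callable-site estimation by mutation-injection simulation, exact Poisson
    confidence intervals on rates, mutation-spectrum and trinucleotide-context
    statistics, selection checks on coding annotation, heterozygous/homozygous
    compartment assignment with parental haplotype of origin, and a
    heterozygosity-versus-distance window profile around new mutations.  A
    pedigree simulator with known ground truth (segregating markers, injected
    mutations, stranded read counts, two emulated variant callers) makes the
    whole chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
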