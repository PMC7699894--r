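Package: mirsitemut
Title: Somatic Mutations in Predicted miRNA-Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts miRNA-binding sites in 3' UTR (and other transcript)
    regions by canonical seed-match classification (8mer, 7mer-m8, 7mer-A1,
    6mer), seed-weighted local duplex alignment and a nearest-neighbor duplex
    free-energy model; intersects somatic variants with predicted sites and
    scores the change in binding between wildtype and mutant alleles; and
    implements the validation-cohort filtering ledger used in amplicon
    resequencing studies (coverage/VAF thresholds, healthy control-pool
    subtraction, homopolymer and tandem-repeat artifact masking, patient-level
    recurrence and group-exclusivity summaries), together with a
    hypergeometric gene-set overrepresentation test and a fully synthetic
    cohort generator with a truth table for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
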