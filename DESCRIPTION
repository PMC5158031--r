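Package: triorecess
Title: Trio Exome Variant Prioritization for Recessive Retinal Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable pipeline, the trio
    whole-exome inference chain used to identify a homozygous nonsense
    variant underlying autosomal recessive rod-cone dystrophy:
    consequence-class and multi-database allele-frequency filtering under
    strict-trio and proband-only recessive inheritance models,
    depth-of-coverage copy-number screening against a reference sample
    pool, runs-of-homozygosity mapping, Mendelian-inconsistency and
    Y-marker statistics for parentage assessment, and truncating-variant
    protein-consequence annotation including nonsense-mediated-decay
    escape and per-domain retention. A synthetic-data generator with
    planted ground truth makes every stage testable end to end without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
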