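Package: trioscreen
Title: Recessive Trio Exome Filtering and Candidate Variant Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering candidate causal variants of
    autosomal recessive Mendelian disease from small trio/cohort exome designs.
    Implements the stepwise variant filtering funnel (coverage, gene and exon
    region classes, homozygous-affected/heterozygous-parent segregation,
    control exclusion, missense restriction), triage of ingested
    PolyPhen-2/PROVEAN/SIFT pathogenicity scores with disease-homolog gene
    rescue, genotype calling from endpoint allelic-discrimination fluorescence
    with recessive genotype-phenotype concordance testing, and mapping of
    cDNA-level substitutions to protein coordinates with pairwise and
    per-domain identity and alignment-column conservation reports. A seeded
    synthetic-cohort generator (toy reference, gene models, cohort VCF/PED
    with a planted recessive causal variant, simulated fluorescence wells)
    makes every stage testable without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
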