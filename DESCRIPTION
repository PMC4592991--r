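Package: snpconsensus
Title: Prioritizing Candidate Causal SNPs in Fine-Mapped QTL Intervals
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to prioritize candidate causal variants inside a
    fine-mapped quantitative trait locus (QTL) interval from targeted
    resequencing of two homozygous genotype groups. Detects "consensus
    SNPs" whose genotypes are concordant with one group and absent from
    the other, classifies them by gene-related functional context (UTR,
    splice site, CpG island, promoter, coding), computes codon-level
    effects of coding variants, and ranks nonsynonymous substitutions
    with a two-component effect score combining physicochemical change
    (normalized Grantham distance) and ortholog sequence conservation.
    Includes a fully self-contained synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
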