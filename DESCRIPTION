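Package: spliceshift
Title: Modular Sequence Models for Predicting Variant Effects on RNA Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the effect of genetic variants (SNVs and indels) on RNA
    splicing by composing five sequence-scoring neural modules (donor,
    acceptor, exon, 5' intron, 3' intron) through small interpretable linear
    and logistic models. Predicts changes in percent spliced-in (delta PSI,
    on the logit scale), competition between alternative splice sites
    (delta PSI5 / delta PSI3), splicing-efficiency changes (allelic
    log-ratio), and variant pathogenicity, directly from VCF, GTF and FASTA
    inputs. Includes indel-aware construction of reference and alternative
    region sequences, training of the scoring modules from labelled sequence
    tables, bootstrap machinery for model comparison, and generators for
    fully synthetic genomes, MPRA-like sequence libraries and variant truth
    sets used for testing and calibration.
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
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
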