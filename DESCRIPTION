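Package: exovar
Title: Exome SNP and INDEL Calling with Trainable Logistic Regression Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Variant calling for whole-exome capture sequencing data. Extracts
    per-site evidence from coordinate-sorted SAM/BAM alignments (read depth
    ratios, variant and neighboring base qualities, distance to the 3' read
    end, strand direction, per-read variation rate, read-end proximity),
    scores SNP and INDEL candidates with trainable logistic regression
    models, applies heuristic filters and adjusted-variant-ratio genotyping,
    and writes single-sample VCF output. Includes population-level VCF
    merging with missing-coverage fill, target-region splitting, model
    training with stepwise selection, significance-guided term dropping,
    bootstrap confidence intervals and repeated split-half cross-validation,
    call-set quality metrics (Ts/Tv, known-site rediscovery, SNP density,
    in-frame rate, concordance, precision/sensitivity and ROC curves), and a
    synthetic read/training-data simulator so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    boot,
    stats,
    utils,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
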