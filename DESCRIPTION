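Package: gtaudit
Title: Molecular Audit of Gene-Targeted Plant Lines from Simulated Resequencing and Tiling-Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize gene-targeted (GT) plant lines at the molecular
    level: a Mendelian selfing-fixation model that back-estimates the mutation
    load of the regenerated T0 plant from homozygous variant counts, coverage
    fractions and generation number; depth/quality variant filtering with
    sibling-aware subtraction of shared background polymorphisms; mutation
    spectrum and transition/transversion summaries; snpEff-style variant effect
    classification against gene models; k-mer screening of short reads for
    vector backbone and Agrobacterium-derived sequences; two-channel tiling-array
    CGH normalization, smoothing and copy-state calling; in-silico CAPS
    (PCR + restriction digest) genotyping; and a quality-ranked partial-validation
    extrapolator. A seeded synthetic-data generator emulates the full study
    design (diploid host genome with gene models, GT vector, T0 mutation
    induction, selfing segregation, per-line calls with callable masks, short
    reads, array intensities) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
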