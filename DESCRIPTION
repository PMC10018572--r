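Package: karyoscope
Title: Karyotype and Epigenome Characterization of Immortalized Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-chromosome and segmental ploidy states of cultured
    cell lines from whole-genome sequencing evidence (binned read depth and
    the allele-support ratio at heterozygous SNPs), detects segmental
    aneuploidy, loss-of-heterozygosity deserts and large deletions, applies
    the H3K27ac/H3K4me3 distance rule for enhancer identification, measures
    ChIP-seq replicate concordance, contrasts RRBS and WGBS cytosine
    coverage to find RRBS-exclusive regions, and correlates expression,
    promoter methylation and histone-mark peak scores per gene. Includes a
    truth-labelled synthetic karyotype and epigenome generator used to
    validate every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
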