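Package: switchtome
Title: Transcriptome Topography of a Bacterial Metabolic Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-scale analysis of strand-specific time-course RNA-seq
    across the metabolic switch of Saccharopolyspora erythraea and related
    actinomycetes. Provides pervasive-transcription and saturation metrics,
    leading/lagging strand preference on a circular chromosome, core/non-core
    macro-region enrichment with switch detection, transposon border-induction
    tests, antisense quantification, intergenic ncRNA candidate calling,
    upper-quartile RPKM normalization, phase-program clustering and Fisher
    category enrichment, transcriptional bottleneck concentration statistics,
    ribonuclease induction tests, and a fragment-library degradation index
    with stability-class enrichment. A fully parameterised synthetic-data
    generator with ground truth supports recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
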