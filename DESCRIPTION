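Package: zfx
Title: C2H2 Zinc-Finger Protein Family Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, classification and downstream analysis of C2H2-type
    zinc-finger proteins (ZFPs) in plant proteomes. Provides a configurable
    spacing grammar for canonical and degenerate
    Cys-X(1-4)-Cys-X(12-20)-His/Cys-X(3-7)-His/Cys fingers, grouping of
    fingers into tandem arrays by linker length, and a hierarchical
    structural classifier (sets A/B/C, subgroups A1/A2/A4 and C1/C2/C3,
    subsets A1a-A1d, C1-1..C1-5 and C1C2mixed) driven by finger architecture
    and diagnostic motifs (QALGGH, SATALLQKAAQMGS, PCYCC). Also includes
    ExPASy-style physicochemical profiling (molecular weight, theoretical
    pI, instability index, GRAVY, composition), chromosome-order gene
    nomenclature, tandem-duplication detection from gene models, FPKM
    expression filtering and profile clustering, 2^-ddCt fold changes,
    water-stress enzyme-panel statistics (ANOVA with Tukey letter groups,
    percent change, Pearson correlation), and a synthetic-data generator
    that plants known finger architectures, expression profile groups and
    enzyme effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
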