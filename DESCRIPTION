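Package: chromosort
Title: Proteomic, Morphometric and Accessibility Analysis of Flow-Sorted
    Mitotic Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studies of native mitotic chromosomes
    purified by flow cytometry. Implements label-free quantitative (LFQ)
    proteomic enrichment analysis with an S0-moderated t statistic and
    permutation-based false-discovery control, morphometry of isolated
    chromosomes in DAPI fluorescence images (total chromosome and
    DAPI-high pericentric areas, group comparisons by Student's t-test),
    and ATAC-seq accessibility transforms (Tn5 insertion-centre
    extraction with +4/-5 offsets, 25 kb windowed log2 enrichment, and
    summit-centred accessibility trend profiles). Seeded synthetic-data
    generators with ground truth make every stage testable without
    access to deposited raw data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
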