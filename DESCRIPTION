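Package: panrenal
Title: Cross-Mission Pan-Omic Integration and Renal Phenotyping of Spaceflight Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate heterogeneous differential-omics results
    (transcriptome, proteome, phosphoproteome, epigenome, metabolome,
    metagenome) across missions, species and tissues into gene-level
    consensus calls; a multi-dataset consensus product score with ranking
    and plotting filters; gene-set over-representation analysis with an
    enrichment-ratio statistic and cross-dataset term ranking; kinase- and
    phosphatase-substrate enrichment z-scores; derived renal
    clinical-chemistry indices (fractional excretion, TmP/GFR, TTKG,
    aldosterone:renin, eGFR) with repeated-measures comparison helpers;
    label-mask kidney morphometry (tubule counts and areas, regional dot
    densities, fractional areas, normalised organ weights); and seeded
    synthetic-data generators with exported ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    fgsea,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
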