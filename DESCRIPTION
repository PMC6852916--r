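Package: eqtlzone
Title: eQTL Enrichment Across GWAS Significance Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates a SNP's cis-eQTL status, its tissue breadth, and the eQTL
    density of its +/- 5 kb neighborhood to its statistical significance in a
    genome-wide association study (GWAS). Provides per-tissue rank comparisons
    of -log10 p between eQTL and non-eQTL SNPs (Mann-Whitney U with
    tie-corrected signed Z), stratification of SNPs into significance zones
    (white noise, light gray, dark gray, genome-wide) and 0.5-increment
    -log10 p bins with eQTL proportions, regulatory co-localization by eQTL
    density class, and a non-overlapping 5 kb genome-chopping control that
    correlates per-fragment eQTL counts with mean -log10 p. A seeded
    synthetic-data generator emulates GWAS summary statistics, a multi-tissue
    eQTL catalog, and regulatory features with known ground truth for
    calibration and enrichment-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
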