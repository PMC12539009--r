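Package: staygreen
Title: Stay-Green Senescence Phenotyping and Haplotype Discovery for Wheat Field Trials
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the stay-green trait (delayed leaf senescence)
    in cereal diversity panels from multispectral plot reflectance, and for
    tracing it to haplotypes. Covers vegetation-index computation (PSRI, NDVI,
    NDRE) with empirical-line calibration and plot-median extraction, thermal
    time (growing degree days), split-plot variance components and reliability
    of genotype means, genotype effects, a principal-component-corrected
    single- and multi-locus association scan with Bonferroni and
    Benjamini-Hochberg control, LD-guided k-means haplotype calling with
    major/minor-allele naming, haplotype effect and stacking tests, and
    allele-frequency trends by decade of cultivar release. A synthetic-trial
    generator with known causal loci makes the whole pipeline testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    tiff,
    jsonlite,
    yaml,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
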