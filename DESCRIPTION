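Package: envgxe
Title: Environmental GWAS and Genotype-by-Environment Analysis for
    Clonal Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting incidental selection for local
    adaptation and genotype-by-environment interaction (GxE) in clonal,
    autotetraploid multi-environment trials such as the US National Chip
    Processing Trial.  Implements environmental genome-wide association
    (envGWAS) by reverse regression of allele dosage on descriptors of
    the selection environment, reaction-norm regression GWAS for yield,
    generation-proxy selection mapping (GPSM), and REML decomposition of
    genetic variance into genotype, genotype-by-year,
    genotype-by-location and genotype-by-year-by-location components.
    Includes growing-season weather summaries with nearest-station
    fallback imputation, a mixed-model marker scan for tetraploid dosages
    with an effective-marker significance threshold, percent variance
    explained by backward elimination, and a synthetic-data generator
    with planted environmental clines, slope QTL and allele-frequency
    trends so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
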