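Package: resilnorm
Title: Weather Resilience Phenotypes for Growth from Random-Regression
    Reaction Norms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives individual weather-resilience phenotypes for longitudinal
    growth data using random-regression reaction norms on weekly weather
    covariates (second-degree Legendre polynomial bases fitted by EM-REML),
    and analyses their genetic architecture with genomic tools: genotype
    quality control, genomic relatedness matrices, GREML heritability with
    likelihood-ratio tests, and linear mixed model genome-wide association
    with genomic-control diagnostics. Includes a synthetic-data generator
    emulating a tropical free-range chicken growth study (daily weather,
    SNP genotypes and weekly body weights with known reaction-norm and
    polygenic architecture) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
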