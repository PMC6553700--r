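Package: famcoseg
Title: Rare-Variant Co-Segregation Analysis in Multi-Incident Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes rare coding variants in families with several
    affected members under an autosomal dominant model with reduced
    penetrance and phenocopies. Provides PED pedigree parsing with
    relationship queries, obligate-carrier and genotype inference assuming
    a single founder introduction, rare-variant filtering of annotated
    VCFs (autosomal heterozygous missense/nonsense below a frequency
    threshold in every database), per-family co-segregation evaluation,
    cohort mining, carrier-frequency and odds-ratio statistics with Woolf
    confidence intervals, microsatellite haplotype-sharing comparison, and
    a Mendelian family and cohort simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
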