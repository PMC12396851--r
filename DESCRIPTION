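Package: noapanel
Title: Virtual Gene-Panel Diagnostics for Non-Obstructive Azoospermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monogenic diagnosis of non-obstructive azoospermia
    (NOA) from gene-panel sequencing data. Implements virtual-panel variant
    filtration (consequence, population-frequency, sequencing-QC,
    inheritance-consistency and copy-number deletion rules), a two-profile
    ACMG/AMP evidence engine with a point-based five-tier classification,
    per-gene aggregation of testicular sperm extraction (TESE) outcomes into
    retrieval predictions, and cohort-level genotype-phenotype association
    statistics (diagnostic yields, Wald odds ratios, exact binomial and
    Bonferroni-adjusted chi-square tests). A seeded synthetic-cohort
    generator with planted causal variants allows every pipeline stage to be
    exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
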