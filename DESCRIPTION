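Package: clozapgx
Title: Cost-Effectiveness of Pharmacogenomic-Guided Clozapine Administration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model for the cost-effectiveness
    of pharmacogenomic (PGx) screening before clozapine treatment, where a
    panel of risk variants (HLA-DQB1 126Q / HLA-B 158T haplotypes and the
    SLCO1B3-SLCO1B7 intronic variant rs149104283) flags patients at elevated
    risk of clozapine-induced agranulocytosis or granulocytopenia (CIAG).
    Provides panel sensitivity/specificity aggregation, number needed to
    genotype, discounted cost and QALY projection over a 10-year horizon,
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, one-way deterministic sensitivity analysis, genetic association
    power calculations with an "undetected risk variant" scenario engine, and
    an individual-level microsimulation that serves as a brute-force oracle
    for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
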