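Package: bariGRS
Title: Genetic Risk Scores for Long-Term Weight Response After Bariatric Surgery
Version: 0.1.0
Authors@R:
    person("bariGRS", "Maintainers", email = "barigrs@example.org", role = c("aut", "cre"))
Description: Candidate-SNP association analysis of long-term weight response
    after bariatric surgery. Derives weight-response phenotypes (percentage of
    total weight lost at nadir and at the end of follow-up, percentage of excess
    weight lost relative to the weight at BMI 25 kg/m2, and weight regain as a
    percentage of maximum weight lost) from longitudinal weight records; tests
    genotype-phenotype association under five inheritance models (codominant,
    dominant, recessive, over-dominant, log-additive) with covariate adjustment,
    Hardy-Weinberg exact testing, call-rate QC and AIC model selection; builds
    unweighted phenotype-specific genetic risk scores (2 points for the
    risk-allele homozygote, 1 for the heterozygote) categorized at the cohort
    75th percentile; and quantifies score-outcome associations. Includes a
    synthetic-cohort generator with plantable genetic effects for calibration
    and parameter-recovery studies, plus VCF/TSV/CSV/JSON readers and writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
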