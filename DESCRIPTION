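Package: rohqc
Title: Genotype Quality Control with Runs of Homozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control of SNP-array genotype data using runs of
    homozygosity (ROH) as a per-sample diagnostic. Detects ROH with a
    PLINK-compatible overlapping-window scan or an exact per-segment
    allowance scan under configurable presets, summarises them into
    N_ROH, S_ROH, L_ROH and the genomic inbreeding coefficient F_ROH,
    derives F1-anchored lower bounds to flag samples whose heterozygous
    calls are artifactually inflated, computes replicate-pair genotype
    concordance restricted to calls present in both datasets, classifies
    SNP performance from call patterns, and re-runs the analysis after
    excluding flagged samples. Includes a synthetic genotype generator
    with breed-structured allele frequencies, planted identity-by-descent
    segments, F1 outcrosses, batch-specific error models and full truth
    records, plus PLINK text (PED/MAP) input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
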