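Package: strpopgen
Title: Population Genetics and Forensic Match Statistics for Microsatellite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for codominant microsatellite (STR) genotype tables in
    wildlife forensic genetics: per-locus polymorphism summaries (allele
    frequencies, observed and unbiased expected heterozygosity, effective
    allele number, polymorphism information content), Monte-Carlo exact tests
    of Hardy-Weinberg equilibrium with Bonferroni correction, null-allele
    estimators with a homozygote-excess scan, Weir-Cockerham F-statistics,
    one-level AMOVA with permutation testing, a leave-one-out frequency-based
    population assignment test, theta-corrected (subdivision-aware) genotype
    match probabilities, a locus triage cascade for forensic panel design, and
    a Balding-Nichols simulator of differentiated populations for validating
    the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
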