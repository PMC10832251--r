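Package: kdrscreen
Title: Knockdown-Resistance Genotyping and Bioassay Screening for House Flies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening house fly (Musca domestica) populations for
    knockdown resistance (kdr) to pyrethroid insecticides. Calls SS/RS/RR
    genotypes at four voltage-sensitive sodium channel (VSSC) mutations
    (M918T, T929I, L1014F, L1014H) from Sanger consensus sequences with IUPAC
    ambiguity codes, simulates the PASA allele-specific PCR assay and
    interprets gel band patterns, computes per-location allele frequencies
    and Hardy-Weinberg equilibrium chi-square tests, classifies CDC bottle
    bioassay mortality series against a diagnostic dose and time, and
    generates seeded synthetic populations, sequences and mortality curves
    for validation. Ships a worked example: a 19-location genotype survey
    and a 16-location deltamethrin bioassay from Abu Dhabi, UAE (2023).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
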