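Package: hlacc
Title: HLA Case-Control Allele Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control association analysis of HLA allele
    frequencies against reference population frequency panels, as used in
    small typed-cohort immunogenetics studies. Parses and
    resolution-collapses HLA allele names (HLA-A, -B, -C, -DRB1, -DQB1),
    counts alleles and within-locus genotype pairs, and tests associations
    with chi-square (with a Yates policy for rare alleles), odds ratios
    with Haldane-Anscombe zero-cell correction and Woolf confidence
    intervals, one-sample proportion Z tests against national frequencies,
    and per-locus Benjamini-Hochberg correction. Includes Hardy-Weinberg
    equilibrium tests on multi-allelic genotype-pair tables, a within-locus
    linkage-disequilibrium coefficient, carrier-phenotype comparison,
    seeded synthetic cohort generators, and a study pipeline with TSV
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
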