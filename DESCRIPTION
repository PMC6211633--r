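Package: chimerapop
Title: Chimeric-Gene Genotyping, Breakpoint Mapping and Selective-Sweep
    Scans for Tandem Paralogs
Version: 0.1.0
Authors@R:
    person("chimerapop", "developers", email = "dev@chimerapop.org",
           role = c("aut", "cre"))
Description: Tools for studying chimeric genes formed by unequal
    crossing-over between tandem paralogs, motivated by the
    insecticide-resistance P450 gene CYP337B3 of Helicoverpa armigera
    (a fusion of the parental genes CYP337B2 and CYP337B1).  The package
    provides in-silico PCR genotyping of diploid templates,
    informative-site mapping of crossover breakpoint intervals against
    aligned parental alleles, exact-sequence allele typing, regional
    genotype and allele frequency tables, a from-scratch sliding-window
    nucleotide diversity (pi) and Tajima's D selective-sweep scan over a
    minimal VCF genotype matrix, distance-based (neighbor-joining)
    monophyly assessment of chimeric-allele introns with column
    bootstrap, and a divergence-rate feasibility calculation.  A
    fully-seeded synthetic-data generator emulates parental allele
    pools, single-crossover chimeras, regional diploid populations and
    planted selective-sweep footprints so every stage is testable
    against planted truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
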