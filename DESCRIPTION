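Package: scaffcheck
Title: Quality Control for Hi-C Scaffolded, Diploid-Phased Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembly quality-control toolkit for low-input hybrid genome
    assembly workflows: insulation-score misjoin detection from Hi-C contact
    pairs with an empirical false-join null, AGP scaffold-layout handling
    with coordinate lifting and break application, library QC statistics
    (PCR duplication rate, depth overdispersion, predicted coverage),
    annotation-class assembly-completeness scoring from per-base coverage
    tracks, and switch/mismatch evaluation of phased haplotype blocks
    against parental truth for an F1 individual.  Includes seeded synthetic
    generators (F1 diploid genomes, distance-decay contacts with planted
    misjoins and PCR duplicates, overdispersed depth, phased blocks with
    planted error rates) so every analysis is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
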