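Package: ctsim
Title: Probabilistic Simulation and Analysis of Chromosome Territories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully probabilistic 3-D simulation of chromosome territory
    formation in an interphase nucleus. Chromosomes are grown as chains of
    1 Mbp chromatin-domain beads inside a spherical nucleus containing an
    excluded-volume nucleolus: centromeres are seeded first, condensed
    chromosome chains grow bidirectionally from them, and a decondensation
    phase adds domains along the whole chromosome length, every placement
    screened by collision-detection rules with restart logic. Downstream
    analysis classifies homologous territory arrangements (complete
    separation, top:top, bottom:bottom, both-arm and top:bottom
    association by a border-to-border distance threshold), tabulates
    arrangement frequencies over replicate nuclei and compares frequency
    tables with Pearson's chi-squared goodness-of-fit test. Includes
    karyotype presets (Brachypodium distachyon, human-like,
    Miscanthus-like), a text model format, static 3-D scene rendering and
    coordinate export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
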