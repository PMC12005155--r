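Package: mnassp
Title: Fragment-Length-Resolved Analysis of MNase Chromatin Protections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing micrococcal-nuclease footprinting data in
    which protected fragments of all sizes are retained (MNase with
    single-stranded library preparation). Provides fragment-length-resolved
    normalized coverage, dyad-anchored V-plots and metagene profiles,
    occupancy difference heatmaps, a rotational-position Z-score statistic
    with Wilcoxon rank-sum validation for quantifying nucleosome and
    subnucleosome positioning shifts, gene-group quartile enrichment, and a
    seeded simulator of MNase digestion of promoter/gene-body chromatin for
    testing the whole pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
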