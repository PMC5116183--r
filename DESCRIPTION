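Package: csabref
Title: Ten-Cysteine Reference Array Annotation for CS-Alpha-Beta Defensive Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cysteine-rich defensive peptides of the CS-alpha-beta
    (scorpion-toxin-like) superfamily against a ten-cysteine reference array.
    Maps observed cysteines to reference slots C1-C10, detects the gamma-core
    motif (GXC/CXG), renders the compact box/spacer notation, classifies
    cysteine-spacing families (insect-type defensins, nematode ABFs,
    mollusk defensins, drosomycin/plant defensins, long-chain scorpion
    toxins, macins, CSH-only peptides), infers disulfide connectivity from
    family templates, builds cysteine-anchored multiple alignments, and
    exports partitioned NEXUS matrices (protein + indel + propeptide
    characters) suitable for Bayesian phylogenetics. Includes a seeded
    generator of family-faithful synthetic peptides so the whole pipeline
    can be exercised without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    seqinr,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
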