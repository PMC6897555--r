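Package: catperc
Title: Texture Category Learning, Categorical Perception and ERP Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying learned categorical perception with
    black-and-white micro-feature textures. Generates binary-feature
    texture stimuli and training schedules, classifies learning curves
    against a sustained 80 percent criterion, computes pre/post
    dissimilarity-judgement statistics (between-category separation,
    within-category compression, Global CP), measures N1 and LPC
    event-related-potential window amplitudes around detected learning
    points, and fits a two-phase (autoencoder then supervised)
    neural-network model of the category-boundary effect. A synthetic
    cohort generator with known injected effects makes every analysis
    stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
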