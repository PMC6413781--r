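Package: melaquant
Title: Quantification of Iris, Skin, and Hair Pigmentation Outcomes in
    Ocular Albinism Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying melanin pigmentation outcomes in
    clinical studies of oculocutaneous albinism. Implements
    semiquantitative scoring of iris transillumination photographs
    (geometric sampling-site layout, masked Gaussian smoothing, and
    red-channel measurement mapped to a 0-8 scale), aggregation of
    8-point human grader panels with two-way random-effects intraclass
    correlation coefficients, the melanin (M) index from diffuse
    reflectance spectra, eumelanin/pheomelanin hair marker summaries
    (PTCA, 4-AHP), and longitudinal change-from-baseline analyses with
    random intercept/slope mixed models and eyes nested within
    participants. A synthetic-cohort generator with known ground truth
    supports validation and parameter-recovery studies, and a pipeline
    driver ties all stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    nlme,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
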