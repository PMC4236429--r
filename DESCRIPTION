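Package: probimmune
Title: Probabilistic Model of Innate-Adaptive Immune Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic closed forms and Monte-Carlo simulation for a
    probabilistic model of communication between the innate and adaptive
    immune systems via antigen presentation. Models central tolerance as
    stochastic negative selection over a normalized antigenic
    microenvironment, peripheral tolerance as an efficient-presentation
    threshold on MHC-peptide complex counts, and derives the correct
    targeting ratio for pathogen versus self antigens, the risk of
    bystander autoimmunity, and the detectability of over-expressed
    (tumor-associated) self antigens through the minimum detectable
    increment and the discrimination ability. A seeded Monte-Carlo layer
    simulates repertoire maturation, antigen-presenting-cell sampling and
    response decisions, serving both as a scenario engine and as a
    brute-force check of every closed form.
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
    optparse,
    withr
Config/testthat/edition: 3
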