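Package: chemodyn
Title: Dynamic MWC Modelling of Chemotaxis Signalling and Adaptation in
    Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the signalling activity of cooperative Tar/Tsr
    chemoreceptor complexes in Escherichia coli with a dynamic
    Monod-Wyman-Changeux (MWC) model: a two-state free-energy description of
    mixed receptor complexes coupled to methylation/demethylation adaptation
    kinetics and to exponential attractant flow in a FRET flow chamber.
    Provides a family of adaptation models (cooperative, linear and absent
    CheB feedback, Michaelis-Menten kinetics, a non-regulatable CheB mutant,
    and imprecise adaptation with methylation-site saturation), dose-response
    and data-collapse analyses of activity time courses, one-parameter
    least-squares model comparison, a binned permutation significance test,
    and a synthetic FRET-experiment generator for end-to-end pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
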