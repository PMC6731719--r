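Package: malaisecatch
Title: Catch Modelling for Malaise-Trap Insect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models counts of insects caught by Malaise traps serviced at
    irregular intervals, as developed for a year-long survey of the
    parasitoid wasp subfamily Rhyssinae in Kibale National Park, Uganda.
    Per-species negative-binomial regressions with a log sampling-effort
    offset relate catches to date, rainfall, decaying wood near the trap
    and forest successional type.  Significance of each ecological
    variable, for single species and for the whole assemblage (sum of
    species-wise likelihood ratios), is assessed against a null
    distribution built by resampling trap sites; forest types are also
    contrasted pairwise.  A synthetic-campaign generator reproduces the
    statistical structure of the field data so the whole pipeline can be
    exercised and validated without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
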