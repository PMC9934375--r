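Package: dietcomp
Title: Diet Composition Analysis from Stomach Contents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trophic ecology from predator stomach
    contents: a validated tabular data model for per-stomach prey records with
    haul and fish covariates; laboratory-protocol processing rules (minimum
    numbers from paired hard parts, net-feeding and secondary-prey exclusions,
    prey-size summaries); relative measures of prey quantity (%F, %N, %W) and
    the combined importance indices GII, IRI and prey-specific IRI; rarefaction
    (cumulative prey curves) with an asymptote slope test; bootstrap
    comparisons of dietary importance between strata; chord-transformed
    redundancy analysis with permutation tests; and a seeded negative-binomial
    stomach-content simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
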