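Package: gutbp
Title: Gut Microbiome and 24-Hour Ambulatory Blood Pressure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for population-scale association analysis of
    gut metagenomic species composition with 24-hour ambulatory and office
    blood pressure. Implements compositional preprocessing (prevalence
    filtering, pseudo-count centred log-ratio transform with a per-species
    zero-replacement policy, rarefaction, alpha diversity), distance-based
    multivariate analysis of variance with permutation pseudo-F tests on
    Bray-Curtis dissimilarities, per-species multivariable linear models
    with Benjamini-Hochberg false discovery rate control, preranked set
    enrichment over genera and gut metabolic modules, partial Spearman
    metabolite profiling, dfbeta influence diagnostics with exclusion and
    adjustment sensitivity scenarios, and a seeded synthetic cohort
    generator that emulates the cohort structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
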