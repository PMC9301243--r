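Package: flavomics
Title: Suspect Screening and Differential Analysis of Flavonoid
    Glycoconjugates from LC-ESI(+)-QTOF Data
Version: 0.1.0
Authors@R:
    person("flavomics", "developers", email = "flavomics@example.org",
           role = c("aut", "cre"))
Description: Rule-based annotation of flavonoid aglycones and their
    glycosyl/acyl conjugates from high-resolution MS1 features and MS/MS
    spectra: exact molecular-formula arithmetic, combinatorial
    decomposition of precursor masses against a packaged suspect library
    of Medicago truncatula flavonoids, consecutive neutral-loss chain
    walking with diagnostic product ions, and a downstream statistics
    layer (family and glycosylation-degree accumulation profiles,
    t-test plus fold-change differential calling, complete-linkage
    Pearson clustering, autoscaled principal component analysis).
    Includes a synthetic-data generator that emulates positive-mode
    [M+H]+ spectra and log-normal intensity matrices with a multi-factor
    cultivar x tissue x treatment design so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    xml2,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
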