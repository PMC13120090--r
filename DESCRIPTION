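Package: aluPBTK
Title: Physiologically-Based Toxicokinetic Simulation of Aluminium Exposure
    from Vaccinations and Diet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates lifetime aluminium exposure in a virtual female
    population from birth to age 50 with a linear, age-dependent
    physiologically-based toxicokinetic (PBTK) compartment model: zero-order
    intramuscular release from vaccine adjuvant depots (aluminium hydroxide,
    aluminium phosphate and amorphous aluminium hydroxyphosphate sulfate),
    continuous age-staged dietary intake, glomerular filtration rate
    maturation, calcium-coupled bone kinetics and a brain sink compartment.
    Provides the German 2025 vaccination schedule and variants as built-in
    scenarios, lognormal inter-individual variability with paired virtual
    populations across scenarios, and exposure risk-assessment summaries:
    quantile bands, windowed maximum-median-difference statistics, body
    burdens, and comparisons against tissue reference levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
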