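Package: fraxbuildr
Title: Build Country-Specific FRAX-Style Hip Fracture Probability Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for constructing country-specific FRAX-style
    fracture probability models from routinely collected data: hip fracture
    admission line lists are deduplicated into incident cases, combined with
    population denominators into age- and sex-specific incidence rates with
    exact (Garwood) Poisson confidence intervals, compared across population
    strata by direct age standardization with Fay-Feuer gamma intervals,
    smoothed into continuous per-age hazards by Poisson regression, augmented
    with major osteoporotic fracture hazards via hip-to-MOF ratio tables, and
    integrated against a competing mortality hazard to yield 10-year and
    remaining-lifetime fracture probabilities. A synthetic registry generator
    with Gompertz fracture and Gompertz-Makeham death hazards makes every
    stage testable without access to hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
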