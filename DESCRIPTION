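Package: ttishelf
Title: Shelf-Life Kinetics and Time-Temperature Integrator Matching for
    Chilled Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive-microbiology toolkit for chilled, modified-atmosphere
    packed foods. Fits the Baranyi-Roberts primary growth model to microbial
    count curves, models the temperature dependence of growth rate and lag via
    the Arrhenius equation, and estimates microbial shelf-life from an
    acceptability limit. Models enzymatic time-temperature integrator (TTI)
    smart labels with logistic response kinetics and a global
    concentration-temperature model, matches TTI response to product
    shelf-life across the cold chain, and validates predictions under
    non-isothermal temperature profiles via effective temperature and
    relative-error metrics. Includes seeded synthetic-data generators and
    bundled reference kinetic tables for gilthead seabream fillets.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
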