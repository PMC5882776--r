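Package: pcpredox
Title: Competitive Anaerobic Redox Kinetics and Reductive Dechlorination of
    Pentachlorophenol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of competing terminal-electron-accepting
    processes in anaerobic soil microcosms. Fits the three-parameter logistic
    model to cumulative reduction and accumulation time series (nitrate,
    sulfate, Fe(II), pentachlorophenol) and derives the maximum reaction rate
    (0.25*a*k) and its timing (ln(b)/k); balances electron equivalents between
    a lactate donor and nitrate, Fe(III), sulfate reduction and reductive
    dechlorination; represents chlorophenol congeners as chlorine ring-position
    sets and classifies sequential dechlorination pathways (ortho/meta/para);
    simulates sequential first-order (Bateman) dechlorination chains with
    chlorine mass balance; and generates complete seeded synthetic microcosm
    datasets with recorded ground truth for end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
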