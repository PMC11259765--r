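Package: ovushift
Title: Ovulation Detection from Sleep-Time Temperature via Heat-Flux Core
    Body Temperature Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying ovulatory menstrual cycles from wearable
    temperature recordings. Estimates core body temperature from paired chest
    skin and ambient temperature with a single-coefficient heat-flux model,
    reduces each night of minute-level data to one representative temperature
    (first-hour discard, four-hour analysis window, ambient and artifact
    exclusions), detects biphasic temperature shifts in day-level series with
    the three-over-six rule and its exceptions, and evaluates diagnostic
    accuracy against a urinary luteinizing-hormone reference (sensitivity,
    specificity, predictive values, F1, paired McNemar comparison,
    two-proportion chi-square, repeated-measures correlation). A synthetic-data
    module generates minute-level nights and day-level cycles with the
    statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
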