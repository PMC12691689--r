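Package: alarmkin
Title: Competitive Multi-Substrate Kinetics of Exported Alarmone Synthetases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the pyrophosphokinase kinetics of exported
    alarmone synthetases: a shared-donor-site, competing-acceptor velocity
    model for (p)pp(A/G)pp synthesis from ATP, reduction of NADH-coupled
    plate-reader A340 traces to synthesis velocities, stepwise inference of
    Michaelis constants and maximal velocities (donor-site fit, ATP-acceptor
    fit, product-ratio specificity constants, fractional-saturation
    deconvolution of competitor Km, saturation-corrected kcat), and a
    seeded synthetic-data generator reproducing the titration and
    competition designs so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
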