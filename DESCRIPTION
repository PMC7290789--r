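Package: microkin
Title: Microdosimetric-Kinetic Modelling of Cell Survival Under
    Time-Varying Dose Rate and Radiation Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts clonogenic cell survival, mean inactivation dose and
    relative biological effectiveness for irradiations whose dose rate and
    radiation quality change during delivery, as in boron neutron capture
    therapy where the cellular 10B concentration varies over the
    dose-delivery period.  Implements microdosimetric functionals
    (dose-mean and saturation-corrected lineal energy) on user-supplied
    spectra, a time-sectioned microdosimetric-kinetic survival model with
    first-order sub-lethal damage repair, random-walk Metropolis estimation
    of the radiosensitivity parameters with sequential Bayesian prior
    updating, and a treatment-schedule simulator that converts a boron
    concentration timeline into a piecewise-constant irradiation schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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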