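Package: persistdyn
Title: Population Dynamics of Bacterial Persistence and Phenotype Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-phenotype (normal/persister) linear model of
    bacterial persistence: exact propagation of the switching dynamics, a
    carrying-capacity extension for the transition to stationary phase,
    small-switching-rate asymptotics (logistic reduction of the subpopulation
    ratio, effective and time-averaged growth rates, double-exponential total
    population), observables of medium-shift experiments (biphasic kill and
    regrowth curves, transition and equilibration times, switching-rate
    inference from fitted count tables), and long-time growth in periodically
    alternating environments including optimal switching rates. Includes a
    synthetic CFU count-table generator with configurable measurement noise
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
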