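Package: nfkbdecoy
Title: Systems Pharmacology of NF-kB Synthetic Decoy Oligonucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of a minimal NF-kB/IkBa
    negative-feedback circuit dosed with synthetic decoy oligodeoxynucleotides
    (ODNs). The reaction network couples the IkBa transcriptional feedback
    loop to sequestration of nuclear NF-kB by genomic decoy sites (with a
    log-normal spectrum of unbinding rates), synthetic decoy ODNs subject to
    nuclease degradation, and IkBa-induced molecular stripping of NF-kB from
    bound sites. Provides a stiff mass-action ODE integrator and an exact
    Gillespie simulation of the chemical master equation over the same
    reaction set, pharmacodynamic observables (peak nuclear NF-kB amplitude,
    duration of action, oscillation dephasing time from the autocorrelation
    envelope), and tidy parameter-scan drivers for dose, unbinding-rate and
    degradation-rate response surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
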