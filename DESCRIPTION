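Package: ribocharge
Title: Stochastic Whole-Cell Simulation of Ribosome Traffic and tRNA Charging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mRNA translation in a growing yeast cell as a totally
    asymmetric simple exclusion process (TASEP) over a coarse-grained virtual
    transcriptome, coupled to aminoacyl-tRNA synthetase recharging kinetics with
    Michaelis-Menten competitive inhibition among isoacceptor tRNAs, a finite
    shared ribosome pool, and growth-coupled initiation feedback. A companion
    three-state (empty/bound/charged) Gillespie model of synthetase sequestration
    of uncharged tRNA resolves how a starvation kinase can detect uncharged tRNA
    even when bulk charging levels are maintained. Includes calibration to
    physiological targets, synthetase-depletion dose-response experiments,
    ribosome density profiles and queueing statistics, and synthetic desk-scale
    fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
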