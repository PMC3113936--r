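Package: txtlsim
Title: Delayed Stochastic Simulation of Coupled Transcription and
    Translation in Prokaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-level stochastic simulator of prokaryotic gene
    expression in which transcription is modeled one nucleotide at a time
    and translation one codon at a time, coupled through the nascent mRNA.
    The transcription model includes the promoter open-complex delay,
    ubiquitous and sequence-specific pausing, arrests, editing, premature
    termination, pyrophosphorolysis, polymerase traffic and footprint
    exclusion; the translation model includes ribosome-binding-site
    occlusion, stepwise translocation with codon-specific activation rates,
    back-translocation, drop-off, trans-translation and ribosome traffic.
    Dynamics follow the delayed stochastic simulation algorithm with
    reaction channels created and destroyed at run time, one compartment
    per RNA strand. Analysis tools quantify expression noise (squared
    coefficient of variation), normalized cross-correlation between mRNA
    and protein time series, interval and burst statistics, and
    methionine-incorporation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
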