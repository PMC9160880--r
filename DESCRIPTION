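Package: emuflux
Title: EMU-Based 13C Metabolic Flux Analysis with Culture Rates and
    Gene-Set Expression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state 13C metabolic flux analysis of small
    carbon-atom-mapped networks using the elementary metabolite unit
    (EMU) framework: parsing and validation of atom-transition models,
    EMU decomposition and mass-isotopomer distribution (MID) simulation
    with an exhaustive isotopomer oracle, natural-abundance correction of
    GC-MS amino-acid fragment measurements, weighted least-squares flux
    fitting with chi-square goodness of fit and grid-search
    (profile-likelihood) confidence intervals, specific-rate estimation
    from culture time courses by regression against integrated biomass,
    and gene-set transcriptome statistics (signal normalization,
    one-sided Mann-Whitney tests, volcano and fold-change
    classification). A synthetic-data generator produces labeling
    experiments, culture time courses and expression tables with known
    ground truth so that every stage of the pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
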