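Package: mitolevel
Title: Multilevel Selection Dynamics of a Selfish Mitochondrial Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation and estimation of multilevel selection on a
    heteroplasmic deletion-bearing mitochondrial genome in Caenorhabditis
    elegans populations. Provides a generative model of within-host (germline)
    proliferation with a transmission bottleneck, frequency-dependent host
    fitness costs, copy-number hitchhiking, and the two experimental designs
    used to separate selection levels: isolated parent-progeny lineages for
    sub-organismal selection and replicate competition lines for organismal
    selection. Includes a duplex droplet digital PCR measurement model with
    Poisson correction, resampling-based estimators of the within-host shift
    function and its equilibrium, odds-based organismal selection
    coefficients, and mean-field predictions that integrate the two levels
    across diet and host-genotype condition presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
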