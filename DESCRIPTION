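Package: salmodyn
Title: Adaptive Dynamics of Atlantic Salmon Body Size Under River Regulation
Version: 0.1.0
Authors@R:
    person("Eira", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing rapid adaptation of Atlantic salmon body size
    to reduced waterflow. Implements a temporal Wright-Fisher drift null model
    for allele-frequency change at neutral SNP panels (Metropolis-within-Gibbs
    estimation of the drift intensity zeta = g/2Ne, beta-binomial posteriors for
    focal loci, drift envelopes and drift probabilities), a sex-specific
    two-locus natural genetic effect model for log body mass (vgll3 and six6),
    a moving-optimum state-space quantitative-genetic model fitted by penalized
    maximum likelihood with overlapping generations, rates-of-evolution metrics
    (darwins, haldanes, evolvability, genetic load), and a synthetic-data
    generator that emulates the study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    numDeriv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
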