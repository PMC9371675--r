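Package: multiplexdrive
Title: Stochastic Wright-Fisher Simulation of Resistance to Multiplexed
    CRISPR Suppression Gene Drive
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of resistance
    evolution against a multiplexed CRISPR-Cas9 homing suppression gene
    drive with separate sexes and density-dependent Beverton-Holt
    population regulation. Haplotypes at m multiplexed gRNA target sites
    carry wild-type, functional-resistant, nonfunctional-resistant or
    drive alleles; resistance can arise from NHEJ repair, de novo
    single-nucleotide mutation, or standing variation equilibrated at
    mutation-selection balance before release. A hybrid Poisson-Gaussian
    approximation to multinomial sampling makes the per-generation cost
    independent of population size, so very large effective population
    sizes can be simulated. A companion analytic layer provides the
    critical population size for resistance, sigmoid fits of resistance
    probability, minimal gRNA-number calculators (including a Lambert-W
    closed form), and the standing-variation amplification ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'genetics.R'
    'reproduction.R'
    'demography.R'
    'sampling.R'
    'simulate.R'
    'theory.R'
    'config.R'
    'utils.R'
    'multiplexdrive-package.R'
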