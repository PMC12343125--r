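Package: fbdstrata
Title: Stratigraphic Evaluation of Fossilized Birth-Death Posterior Tree Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and comparison machinery for dated phylogenies of
    extinct clades sampled under the fossilized birth-death (FBD) process.
    Provides a forward FBD simulator with sampled ancestors, fossil occurrence
    cleaning and genus-level constraint building, stratigraphic congruence
    metrics (minimum implied gap, stratigraphic consistency index, gap excess
    ratio) with exact enumeration oracles, treespace embedding of posterior
    tree samples with congruence landscapes and density maps, consensus and
    maximum-clade-credibility summaries with splitwise information content and
    rogue-taxon detection, and highest-posterior-density interval comparison of
    node ages between paired analyses (for example, taxon sets with morphology
    alone versus morphology plus occurrence-only taxa placed by taxonomic
    constraints).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    mgcv,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    phangorn,
    phytools,
    vegan,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
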