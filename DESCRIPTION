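Package: kgate
Title: Ion-Binding Kinetics and Allosteric Gating Analysis for Elevator Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying cation coupling in glutamate-transporter
    homologues from molecular-simulation and binding-assay data. Converts per-site
    ion-distance trajectories into discrete occupancy states, estimates
    maximum-likelihood transition rates and dissociation constants with bootstrap
    errors, performs transition-path analysis (stationary occupancy, committors,
    reactive flux and highest-flux pathway decomposition) on the resulting kinetic
    models, estimates free-energy differences from non-equilibrium work
    distributions by Crooks Gaussian intersection, reconstructs gate-opening free
    energy profiles from umbrella-sampling windows by WHAM with closed-state
    probabilities and K-type allosteric efficacies, fits the linear voltage-charge
    capacitor model used in computational electrophysiology, and fits microscale
    thermophoresis binding curves by kernel regression with bootstrap confidence
    bands. A synthetic-data module generates inputs with known ground truth
    (continuous-time Markov binding traces, Crooks-consistent work samples,
    Boltzmann umbrella windows, capacitor series and binding curves) for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
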