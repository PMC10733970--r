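Package: ca1pyr
Title: Comparative Biophysical Modelling of Rodent CA1 Pyramidal Neurons
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale workflow for comparative conductance-based modelling
    of mouse and rat hippocampal CA1 pyramidal neurons. Provides declarative
    ion-channel kinetics in the Borg-Graham formalism (including
    species-specific h-current presets), reduced branched-cable morphologies
    with distance-dependent conductance distributions, a deterministic
    compartmental simulator with conductance synapses, electrophysiological
    feature extraction from voltage traces, two-stage model fitting (h-current
    plus passive prefit followed by multi-objective evolutionary optimization
    of peak conductances), parameter-degeneracy analysis via normalized
    heatmaps and PCA species clustering, and theta/gamma synaptic-drive
    experiments analyzed through inverse-interspike-interval distributions and
    the sharp-wave-ripple band. A synthetic-data module generates surrogate
    recordings and parameter ensembles so the full pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
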