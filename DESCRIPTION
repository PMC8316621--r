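Package: gainsweep
Title: Whole-Brain Jansen-Rit Simulation and Connectome-Guided Gain Neuromodulation
Version: 0.1.0
Authors@R: person("gainsweep", "developers", role = c("aut", "cre"),
    email = "gainsweep@example.org")
Description: Simulates a stochastic Jansen-Rit neural mass network on a
    weighted human-style connectome, transforms pyramidal firing rates into
    band-pass-filtered BOLD-like signals with a generalized hemodynamic
    model, and quantifies how noradrenergic-like gain modulation (the slope
    of the pyramidal sigmoid) switches the network between functionally
    segregated and integrated states. Includes weighted-graph structural
    analysis (node strength, nodal efficiency, clustering, normalized
    rich-club coefficient against degree- and strength-preserving
    surrogates, s-core decomposition), functional measures (Kuramoto phase
    synchrony, Fourier-surrogate-thresholded functional connectivity,
    global efficiency, consensus Louvain modularity, functional
    connectivity dynamics), a synthetic connectome generator with planted
    modular and rich-club organization, and the sweep, incremental and
    subset neuromodulation protocols with AUC summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
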