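Package: wavecomm
Title: Two-Area Spiking Cortical Circuits, Propagating Wave Packets, and
    Interareal Communication Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a conductance-based leaky integrate-and-fire network of
    two reciprocally connected cortical areas on periodic 2D lattices, with
    distance-dependent connectivity, spike-frequency adaptation, and Poisson
    external drive. Localized wave packets of spiking activity emerge and
    propagate as superdiffusive Levy motion; the package tracks them and
    derives the standard population observables (multi-unit activity, a
    synaptic-current LFP proxy, spectra with aperiodic 1/f separation, gamma
    bursts, narrowband phases). Analysis tools cover On/Off state segmentation
    of population activity, theta-gamma phase-amplitude coupling,
    state-conditioned phase-locking values, Kraskov-estimator transfer
    entropy, reduced-rank-regression communication subspaces, and spiking
    variability statistics (CV of ISI, Fano factors including the mean-matched
    variant, and noise correlations). A reduced stochastic model -- a Levy
    walker with momentum in a potential-well landscape driving a Gaussian rate
    field -- reproduces the attention-related reductions in variability and
    correlation at full scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Config/testthat/start-first: geometry, connectivity, simulate, observables,
    spectral, states, coupling, subspace, variability, levy, analytics,
    workflows
NeedsCompilation: yes
RoxygenNote: 7.3.3
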