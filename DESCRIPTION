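Package: riboFRET
Title: Single-Molecule FRET Analysis of Ribosome Translocation Intermediates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-colour single-molecule FRET
    trajectories of tRNA translocation on the ribosome. Provides a
    continuous-time Markov simulator of conformational dynamics with
    photobleaching and donor-to-acceptor bleed-through, trace quality control
    (bleed-through correction, bleach-step detection, anti-correlation
    selection, truncation), per-trace Gaussian hidden Markov model
    idealization with automatic state-number selection, transition filtering
    and post-synchronization, FRET population histograms with Gaussian
    mixture fits, equilibrium constants and free-energy differences in kBT,
    and dwell-time kinetics with photobleaching-corrected transition rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
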