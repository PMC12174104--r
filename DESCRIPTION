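Package: errpBandit
Type: Package
Title: ErrP-Rewarded Contextual Bandits for Adaptive Motor-Imagery BCIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying adaptive brain-computer interfaces in which
    contextual-bandit agents (LinUCB, NeuralUCB) learn to map motor-imagery
    EEG features to actions from rewards derived from error-related
    potentials (ErrPs). Provides an epoched-trial data model with windowed-sinc
    FIR preprocessing, a synthetic-EEG simulator of a fast-paced snake-game
    protocol (contralateral mu/beta event-related desynchronization, 1/f
    background activity, a stereotyped ErrP difference waveform), a Morlet
    continuous-wavelet band-power feature pipeline, trial-streaming bandit
    evaluation with exact Wilcoxon signed-rank statistics, and ERP/ERSP
    verification analyses with permutation testing and false-discovery-rate
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
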