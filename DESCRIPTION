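Package: chordaffect
Title: Affective EEG Responses to Consonant and Dissonant Chords
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying affective responses to consonant, dissonant
    and neutral auditory stimuli with electroencephalography (EEG). Builds
    equal-temperament piano-chord stimulus inventories and randomised
    presentation schedules; simulates seeded multichannel EEG recordings with
    event-related potential (ERP) components, narrowband oscillations with
    long-range temporal correlations and 1/f background noise, together with
    matched behavioural trial tables; implements a standard preprocessing
    chain (zero-phase Butterworth filtering, downsampling, common average
    reference, bad-channel detection, FastICA ocular cleaning, epoching and
    baseline correction); computes global field power (GFP) with data-driven
    peak windows and cluster-based permutation contrasts across electrodes;
    estimates band-limited Hilbert-envelope amplitudes and detrended
    fluctuation analysis (DFA) exponents; and links oscillatory measures to
    trial-level categorisation accuracy with behavioural tests and
    mixed-effects logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
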