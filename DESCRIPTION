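Package: pupilstate
Title: Belief-State Signals in Task-Evoked Pupil Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal detection theory models of decision confidence, uncertainty
    and reward prediction error under internal belief states, together with a
    complete pupillometry analysis pipeline: synthetic two-alternative
    forced-choice experiments with model-driven behavior and forward-simulated
    pupil traces, pupil preprocessing (blink interpolation, zero-phase
    band-pass filtering, nuisance deconvolution, percent-signal-change
    conversion), impulse-response estimation by FIR deconvolution,
    event-locked epoch extraction with baseline correction and window
    summaries, and the inferential layer (repeated-measures ANOVA,
    cluster-based permutation tests on time courses, paired sign-flip
    permutation tests, reaction-time residualization, evidence-strength
    regressions, and model-pupil correlation analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
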