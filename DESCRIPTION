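Package: thetawave
Title: Simulation and Analysis of Hippocampal Theta Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing hippocampal local field
    potentials with coexisting type 1 (movement-related) and type 2
    (arousal-related) theta oscillations. Provides a deterministic synthetic
    session generator (laminar LFP with 1/f background, speed- and
    state-gated theta oscillators, theta-phase-modulated gamma, phase-locked
    spike trains, arena tracking); Welch power spectra with baseline
    normalization and theta-peak detection; entropy-based phase-amplitude
    coupling (modulation index) and comodulograms; spike detection, waveform
    features, regular-spiking/interneuron classification and spike-field
    coupling via circular statistics; laminar current-source density;
    speed-binned relative-power maps and power-speed correlation; an offline
    replay of a closed-loop band-power trigger for optogenetic stimulation;
    circular-arena zone analysis; and a simplified compartmental CA1
    pyramidal-cell model with point-source extracellular potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
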