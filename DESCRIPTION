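Package: tacsnet
Title: Spiking Cortical Network Simulation of Transcranial Alternating
    Current Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates a two-population Izhikevich spiking cortical network
    (pyramidal and inhibitory neurons on 2-D grids) with conductance-based
    synapses subject to short-term depression, and studies how transcranial
    alternating and direct current stimulation (tACS/tDCS) interact with the
    network's endogenous slow oscillation.  Provides stimulation waveform
    generators including half-wave rectified variants, Welch power spectral
    density and relative band-power analyses of population activity,
    amplitude-by-frequency entrainment sweeps (Arnold tongue), and a
    closed-loop controller that detects the dominant frequency, phase and
    amplitude of ongoing activity from sliding-window spectra and delivers
    matched stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
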