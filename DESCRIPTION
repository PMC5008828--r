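Package: msnsig
Title: Mass-Action Kinetic Modeling of Calcium-Dopamine Integration in Striatal Neurons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action kinetic modeling of the signaling network
    that integrates NMDA-dependent calcium and D1-receptor dopamine transients in
    striatal medium spiny neurons. Provides a reaction-network representation with
    structural checks (moiety conservation, detailed balance), a stiff ODE engine
    with time-varying clamped inputs, a generator for the calcium pulse-train and
    dopamine transient stimuli, a calibrated striatal DARPP-32/ARPP-21/CaMKII/PP1
    network with mutant variants, an executable molecular-phenotype harness, and
    an in-silico experiment suite: input-interval (delta-t) response curves,
    input-order analysis, CaMKII amplitude thresholds, inter-trial refractoriness,
    input-strength robustness grids, and one-at-a-time parameter sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
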