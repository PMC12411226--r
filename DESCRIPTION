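Package: lietsim
Title: Modelling of Light Emission from Inelastic Electron Tunnelling in
    Plasmonic Metasurface Biosensors
Version: 0.1.0
Authors@R:
    person("lietsim", "developers", email = "lietsim@example.org",
           role = c("aut", "cre"))
Description: Forward model and analysis pipeline for self-illuminating
    tunnel-junction metasurface sensors. Computes the spectral electronic
    contribution of inelastic electron tunnelling from densities of states
    and Fermi-Dirac occupations, the antenna-mediated photonic outcoupling
    of buried transition dipoles via optical reciprocity on a 1D-periodic
    rigorous coupled-wave (RCWA) solver with a transfer-matrix reference,
    and their product, the emitted electroluminescence spectrum. Includes
    Simmons tunnel-barrier current-voltage modelling and fitting with a
    Fowler-Nordheim representation, refractometric sensing readouts
    (band-integrated differential signal, peak fold-change, triple-noise
    limit of detection), and seeded synthetic-measurement generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
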