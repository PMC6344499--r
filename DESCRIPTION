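Package: sabreqmc
Title: Quantum Monte Carlo Simulation of SABRE Hyperpolarization Dynamics
Version: 0.1.0
Authors@R:
    person("SABRE", "Simulation Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates parahydrogen-induced polarization by Signal
    Amplification By Reversible Exchange (SABRE) on small spin systems.
    Couples exact Liouville-von Neumann density-matrix propagation of the
    bound polarization-transfer-catalyst spin system to a discrete-event
    Monte Carlo model of chemical exchange, in which dissociating ligands
    are removed by partial trace and replaced by fresh, unpolarized ones
    while coherences among the remaining spins are retained.  Implements
    microtesla-field (SHEATH-style) and high-field rotating-frame
    (DARTH-style, adiabatically ramped rf) pulse sequences, quadrupolar
    damping of auxiliary nitrogen-14 nuclei, isotopic-dilution inactive
    periods, pulse-acquire spectrum synthesis from the accumulated
    dissociated-ligand density matrix, and exchange-lifetime (EXSY) fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
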