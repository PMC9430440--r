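Package: hbmap
Title: Hydrogen-Bond Structure and O-D Stretch Frequency Maps in
    Cryoprotectant-Water Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of hydrogen bonding in vitrified DMSO/water mixtures
    from atomic configurations and FTIR spectra. Computes instantaneous O-D
    stretch frequencies of dilute HDO probes with an electrostatic
    potential-based vibrational frequency map, tetrahedral order parameters,
    radial and orientational distribution functions, solvation-shell
    partitions and the joint frequency-distance population P(omega, r), and
    performs multi-Gaussian decomposition of temperature-dependent FTIR
    spectra. Includes generators for ice-like, gas-like and mixture
    configurations and for synthetic spectra, plus readers and writers for
    GRO, PDB and XYZ coordinate files with partial-charge topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
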