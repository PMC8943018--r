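Package: scfnn
Title: Self-Consistent Field Neural Network Potentials for Liquid Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Neural-network interatomic potentials for liquid water that learn both
    short-range interactions and the self-consistent response to long-range
    electrostatic fields. The Coulomb interaction is split into a Gaussian-truncated
    short-range part and a slowly varying long-range part; separate networks learn
    the short-range system (Wannier-centre positions and atomic forces) and the
    linear response to the effective long-range field, coupled through a
    self-consistent field iteration. Includes reciprocal-space evaluation of the
    screened electrostatic field, finite-field (constant displacement) molecular
    dynamics with a Berendsen thermostat, a classical synthetic-data generator with
    known ground-truth response for validation, and dielectric analysis machinery:
    longitudinal polarization correlations, Kirkwood factors, and static and
    high-frequency dielectric constants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
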