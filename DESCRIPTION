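Package: aotrap
Title: Angular Optical Trap Simulation and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Vector diffraction model of a high numerical-aperture optical
    trap focused through a glass-aqueous interface, coupled-dipole scattering
    of a birefringent quartz cylinder with optical force and torque from the
    Maxwell stress tensor, trap characterization (focal shift ratio, axial and
    angular stiffness maps), and the calibration estimators used on angular
    optical trap data: worm-like-chain DNA-ruler focal shift, Fabry-Perot
    fringe analysis, angular power-spectral-density stiffness calibration, and
    DNA twisting (torsional buckling) analysis, together with seeded synthetic
    trace generators for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
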