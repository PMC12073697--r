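Package: asdtherm
Title: Thermal and Dielectric Analysis of Amorphous Solid Dispersions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising drug-polymer amorphous solid
    dispersions from dielectric relaxation spectroscopy and temperature
    modulated calorimetry. Implements the conduction-free dielectric loss
    by the logarithmic derivative of the real permittivity,
    Havriliak-Negami deconvolution of overlapping relaxation modes,
    Vogel-Tammann-Fulcher-Hesse fits with dynamic glass-transition
    temperatures and fragility indices, Gordon-Taylor and
    Couchman-Karasz glass-transition mixing rules, Flory-Huggins
    drug-polymer solubility fitting, recrystallisation enthalpy
    accounting, and assembly of the combined phase-and-state diagram.
    Ground-truthed synthetic generators for dielectric isotherm sweeps,
    thermograms and isothermal recrystallisation series make every
    pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
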