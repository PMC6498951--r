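Package: ventopt
Title: Optimal Ventilation and Gas Transport in a Bifurcating-Tree Lung Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models oxygen and carbon dioxide transport in an idealized human
    lung: a symmetric dichotomous airway tree (17 conductive generations that
    shrink with a constant homothety ratio, followed by 6 acinar generations of
    fixed size) carrying each gas by convection and axial diffusion, with a
    reaction term for exchange across the alveolo-capillary membrane into blood.
    Blood-side partial pressures follow a nonlinear oxyhemoglobin (Hill)
    equilibrium for oxygen and a bicarbonate relation for carbon dioxide. The
    coupled one-dimensional branch equations and bifurcation balances are
    advanced with an implicit upwind scheme to a periodic breathing regime,
    yielding cycle-averaged gas flows and the respiratory exchange ratio. On top
    of the transport model the package computes elastic and viscous ventilation
    power, the amplitude-period constraint curve that holds the oxygen flow at a
    prescribed metabolic demand, and the power-minimizing ventilation pattern;
    scenario drivers cover exercise intensities, altitude hypoxia, lumped and
    geometry-linked resistance changes, and membrane-thickening (oedema) sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
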