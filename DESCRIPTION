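Package: coroffr
Title: Steady-State Multiscale Computation of Coronary Fractional Flow
    Reserve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes fractional flow reserve (FFR) along coronary artery
    trees with a steady-state geometric multiscale model.  Patient-specific
    boundary conditions are derived from cuff pressure, heart rate and
    cardiac output: the inlet is driven at the mean aortic pressure, each
    coronary outlet is closed by a lumped-parameter microcirculation
    resistance allocated by Murray's law and reduced to 24% of its resting
    value to emulate adenosine hyperemia, and the systemic circulation is
    lumped into a single descending-aorta resistance.  The vascular domain
    is solved as a steady reduced-order nonlinear network (tapered
    Poiseuille segments with an empirical stenosis pressure-loss model) and
    coupled to the 0D outlet models by a partitioned fixed-point iteration
    with dynamic relaxation.  Includes a synthetic coronary-tree and
    patient-parameter generator, a monolithic verification solver, and
    agreement/diagnostic-performance statistics (Pearson, Bland-Altman,
    ROC/AUC, Youden) for paired computed versus invasive FFR tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
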