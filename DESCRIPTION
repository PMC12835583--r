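Package: rvcirc
Title: Patient-Specific Lumped-Parameter Modeling of the Right Ventricle
    and Pulmonary Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and patient-specific calibration of a
    four-compartment lumped-parameter (Windkessel) model of the right
    ventricle and pulmonary circulation. The right ventricle is modeled
    with a linear time-varying elastance, the pulmonary arterial,
    capillary and venous beds as two-element Windkessels, and the
    tricuspid and pulmonic valves as ideal diodes. Includes parameter
    initialization from routine right-heart-catheterization summaries,
    Morris elementary-effects sensitivity screening, bounded multi-start
    least-squares calibration to pressure and flow waveforms, RV
    pressure-volume loop metrics including stroke work, a synthetic
    virtual-patient cohort generator spanning pulmonary hypertension
    phenotypes, and cohort-level statistics with linear discriminant
    analysis of phenotype separability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
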