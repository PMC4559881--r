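Package: amyloidpkpd
Title: Pharmacokinetic, Pharmacodynamic and Amyloid Histology Analysis for
    BACE Inhibitor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative workhorse analyses of preclinical
    BACE-1 inhibitor characterization: non-compartmental pharmacokinetics
    with unbound-exposure scaling, four-parameter-logistic dose-response
    fitting for in vitro IC50 and in vivo ED50, an indirect-response
    (turnover) model linking blood drug concentration to amyloid-beta
    suppression in CSF, area-under-the-effect-curve summaries, and an
    H-DAB brightfield image-quantification pipeline for amyloid plaque
    burden and glial cluster counts. Seeded synthetic-data generators
    emulate the corresponding study designs with ground truth attached,
    so every estimator can be exercised in closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
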