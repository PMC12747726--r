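Package: sacflow
Title: Post-Simulation Aneurysmal Hemodynamics, Velocity Informatics and
    Rupture-Status Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-resolved flow fields and wall shear
    stress in intracranial aneurysm sacs. Implements Newtonian and
    shear-thinning (Carreau-Yasuda, Casson, Herschel-Bulkley) blood
    viscosity laws; wall-shear-stress metrics (STA-WSS, WSS-max, WSS-min,
    low-shear area, oscillatory shear index, relative residence time);
    lambda2 vortex identification with degree-of-vortex-overlap and
    vortex-volume-fraction summaries; directional velocity-informatics
    texture features (first-order, GLCM, GLRLM, GLSZM; 74 features);
    paired-model agreement statistics (relative percent difference,
    regression slope, Pearson correlation, Bland-Altman, aligned rank
    transform ANOVA); and a linear-kernel SVM rupture-status pipeline with
    stepwise feature selection and exact linear SHAP attributions. A seeded
    synthetic generator provides pulsatile sac flows, wall shear series
    with controllable targets, and case cohorts in place of patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
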