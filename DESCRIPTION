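Package: coroflow
Title: Reduced-Order Patient-Specific Coronary Hemodynamics Before and After
    Aortic Valve Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (0D) simulation of the aorto-coronary
    circulation for patients with aortic stenosis and coronary artery
    disease. Builds an open-loop network of an aortic RCR Windkessel and
    coronary outlets with intramyocardial pressure sources, tunes boundary
    conditions to patient-level pressure and flow targets (4% of cardiac
    output at rest, 10-12% under adenosine hyperemia, 3:1 left-to-right
    coronary velocity ratio), and computes coronary physiology indices
    (FFR, iFR, Pd/Pa, CFR) together with a one-dimensional Poiseuille
    wall-shear-stress surrogate (TAWSS, OSI, high-WSS exposure) over the
    peri-lesion region. A synthetic cohort generator emulates a paired
    pre/post aortic-valve-replacement study population, and a statistics
    layer provides distribution-gated paired tests and Bland-Altman
    agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
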