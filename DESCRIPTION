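Package: qusagree
Title: Quantitative Ultrasound Tumor Characterization and Cross-Scanner Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative ultrasound (QUS) spectroscopy pipeline for tumor
    characterization from beamformed radiofrequency (RF) data: reference-phantom
    spectral normalization, spectral-difference local attenuation estimation and
    point compensation, spectral features (mid-band fit, spectral slope, spectral
    intercept), backscatter-coefficient features under a Gaussian form-factor
    scattering model (average scatterer diameter, average acoustic concentration),
    gray-level co-occurrence matrix texture features on QUS parametric maps, and
    two-scanner / two-time-point agreement analysis (Wilcoxon signed-rank,
    Bland-Altman). Includes a seeded phenomenological RF speckle simulator with
    prescribed backscatter and attenuation so the whole chain is validated by
    parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
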