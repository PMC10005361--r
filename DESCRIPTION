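Package: phistress
Title: Photosynthetic Quantum Efficiency Under Light, Temperature and
    Drought Stress
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Pulse-amplitude-modulated (PAM) chlorophyll-fluorescence
    quenching analysis and modelling of PSII photosynthetic quantum
    efficiency for sugarcane. Derives quenching parameters (PhiPSII, Fv/Fm,
    NPQ, qL, PhiNO) and relative substrate water content from raw
    fluorescence records; fits a piecewise-sinusoidal photothermal response
    model of quantum yield against temperature and irradiance; extends it
    with a drought-stress index driven by relative substrate water content,
    including changepoint estimation of the critical water content and
    drought-stage classification; summarizes excitation-energy distribution
    under progressive drought; and generates seeded synthetic pot
    experiments for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
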