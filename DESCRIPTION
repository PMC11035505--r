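Package: nmdoserate
Title: External Dose Rates from Nuclear-Medicine Patients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational assessment of external dose rates around
    nuclear-medicine patients. Solves linear compartmental biokinetic
    models analytically to fractional time-activity curves per source
    region, with an accumulate-and-void urinary bladder model; transports
    photons through labeled voxel phantoms with a Monte Carlo engine
    (photoelectric absorption, Klein-Nishina Compton scattering, forced
    detection for point tallies) and a deterministic point-kernel engine
    with buildup factors; converts fluence to ambient dose equivalent
    H*(10) with energy-dependent coefficients and organ doses to effective
    dose with tissue weighting factors; superposes per-region dose-rate
    factors over time and propagates uncertainties following the GUM with
    a log-normal biokinetic variability transform. Includes a seeded
    generator of stylized adult voxel phantoms spanning a realistic
    height/mass range and a generator of noisy synthetic dose-rate
    measurement series for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
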