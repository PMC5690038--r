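Package: gkmc
Title: Film-Derived Virtual-Source Monte Carlo Dose Engine for the Gamma
    Knife Perfexion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-source Monte Carlo dose engine for the Leksell Gamma
    Knife Perfexion radiosurgery unit (192 Co-60 sources in 8 sectors of 24,
    five rings, 4/8/16 mm collimators). Per-source fluence maps are derived
    from panoramic films wrapped on a 226 mm cylinder by an image-analysis
    pipeline (anisotropic diffusion smoothing, morphological opening,
    intensity-weighted centroiding); a synthetic-film generator replaces the
    physical measurement. Source particles are sampled from the tagged
    fluence maps and transported through water voxel phantoms with coupled
    photon-electron physics (Klein-Nishina Compton scattering, photoelectric
    absorption, pair production, straight-line CSDA electron deposition).
    Ring and collimator output factors are calibrated against a manufacturer
    reference table by tuning effective source-to-focus distances and
    fluence-mask thresholds; absolute dose conversion, dose profiles,
    dose-volume histograms and coverage metrics support plan-level
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    EBImage,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
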