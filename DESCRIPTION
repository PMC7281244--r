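Package: fibrilr
Title: SAXS and Optical Spectroscopy Analysis of Amyloid Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise amyloid fibrillation of model proteins
    (lysozyme, insulin) from solution scattering and optical spectroscopy.
    Implements absolute-scale small-angle X-ray scattering (SAXS) forward
    models for cylinders with radius polydispersity, Pedersen-Schurtenberger
    worm-like chains, spheres and atomic structures with a hydration shell
    (Debye formula); model-free Guinier, cross-sectional (rod-like) Guinier,
    two-population rod decomposition and Kratky shape classification;
    full-curve nonlinear least-squares fitting of species mixtures with
    seeded multi-start, curvature and bootstrap uncertainties and
    AIC-style model comparison; Congo Red 538/505 nm absorbance-ratio
    analysis with two-band area validation; circular dichroism band-shape
    classification (native-like vs beta-rich); sigmoidal fibrillation
    kinetics (lag, rate, plateau) with condition comparison; and seeded
    synthetic-data generators that emulate the beamline and spectrometer
    observables for every studied solvent condition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    pracma,
    bio3d,
    jsonlite,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
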