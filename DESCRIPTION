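Package: hgowall
Title: Uncertainty Quantification for Arterial Wall Mechanics Models
    Fitted to Diameter-Pressure Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the two-fibre Holzapfel-Gasser-Ogden constitutive model of
    the carotid artery wall to single-exponential diameter-pressure curves
    built from non-invasive measurements (diastolic/pulse pressure, diastolic
    diameter, distension, intima-media thickness), and quantifies how
    measurement noise propagates into the fitted mechanical characteristics.
    Provides thick-walled inflation mechanics with residual-stress
    (opening-angle) kinematics and axial pre-stretch, a low-discrepancy
    virtual measurement cohort sampled over intra-subject uncertainty
    domains, weighted multistart bounded least-squares fitting under a
    constant reduced axial force constraint, collagen load-bearing fractions,
    kernel-density/percentile summaries, variance-based global sensitivity
    analysis via Legendre polynomial chaos expansions (leave-one-out Q2,
    main and total Sobol indices), and a simulated collagen cross-link
    breaker (AGE-breaker) treatment arm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
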