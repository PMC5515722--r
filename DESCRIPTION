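Package: alphadose
Title: Macroscale Dosimetry for Alpha-Particle Emitter Labeled Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacokinetic fitting and absorbed-dose estimation for
    alpha-particle emitter radioimmunotherapy at the organ (macroscale)
    level. Fits mono- and bi-exponential clearance models to organ
    time-activity data, computes time-integrated activity per unit mass by
    closed-form integration of the fitted model or by a hybrid
    trapezoid-plus-exponential-tail rule, converts time-integrated activity
    to absorbed-dose coefficients using yield-weighted alpha energies of the
    full decay chain in secular equilibrium (Ac-225, Pb-212, At-211,
    Bi-213), strips kidney well-counter decay series into free Bi-213 and
    parent-bound components, and prescribes administered activity under
    organ dose limits. Includes a synthetic biodistribution generator that
    emulates a mouse study design for validation without animal data.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
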