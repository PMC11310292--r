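Package: endoctrl
Title: Diet-Dependent Endocrine Therapy Scheduling in ER-Positive Breast
    Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of the interplay between
    tumor volume, local estrogen concentration and mammary fat volume in
    estrogen-receptor-positive breast cancer, with an extension to sensitive
    and resistant tumor subpopulations under aromatase-inhibitor treatment.
    Provides stiff-capable simulation with treatment schedules (constant,
    alternating, tabulated), a synthetic-data generator emulating a two-arm
    (control diet vs high-fat diet) mouse experiment, weighted least-squares
    calibration with multistart optimization and profile-likelihood
    identifiability analysis, and a forward-backward sweep solver for the
    quadratic optimal control problem of scheduling estrogen-deprivation
    therapy, including scenario presets for adaptive and de novo resistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
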