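Package: eqdx
Title: Equieffective Dose and Dose-Protraction Calculations for
    Radiopharmaceutical Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the Lea-Catcheside dose-protraction factor (G),
    relative effectiveness (RE), biologically effective dose (BED) and
    equieffective dose (EQDX) for radiopharmaceutical therapy from
    region-level time-dose-rate measurements under the linear-quadratic
    model with monoexponential sublethal-damage repair.  Provides four
    interchangeable G-factor engines: a closed-form solution for
    biexponential dose-rate curves, the monoexponential limit, a hybrid
    method that integrates a piecewise-linear head numerically and its
    exponential tail analytically, and the fully numerical trapezoid
    recursion of Hobbs and Sgouros with a structured overflow guard.
    Includes biexponential curve fitting from sparse post-injection
    measurements, synthetic scenario generation, convergence and
    measurement-omission study drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
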