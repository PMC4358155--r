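Package: demhess
Title: Second Derivatives of Population Growth Rates for Matrix
    Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Matrix-calculus computation of the Hessian matrices (second
    derivatives) of three population growth rates used in ecology and
    evolutionary demography: the discrete-time growth rate lambda (the
    dominant eigenvalue of a stage-structured projection matrix), the
    invasion exponent r = log(lambda), and the net reproductive rate R0
    (the dominant eigenvalue of the next-generation matrix).  Second
    derivatives are available with respect to projection-matrix entries
    and with respect to lower-level parameters such as stage-specific
    survival probabilities, via a Hessian chain rule.  The package also
    provides the Hessian-based sensitivity of Tuljapurkar's small-noise
    approximation to the stochastic growth rate, classification of
    nonlinear and correlational selection from fitness curvature, an
    independent finite-difference oracle used to validate every analytic
    formula, seeded random Lefkovitch matrix generators, delimited-text
    model input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    MASS,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
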