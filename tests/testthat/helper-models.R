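# shared fixtures: small models with known closed-form properties

# imprimitive 2-stage Leslie model: lambda = 1, w = (2/3, 1/3),
# v = (3/4, 3/2) under e'w = 1, v'w = 1
leslie2 <- function() matrix(c(0, 0.5, 2, 0), 2, 2)

# the same model decomposed: U survival to stage 2, F fertility
leslie2_sm <- function() {
  stage_matrix(U = matrix(c(0, 0.5, 0, 0), 2, 2),
               F = matrix(c(0, 0, 2, 0), 2, 2))
}

# an aperiodic irreducible 3-stage model (all checks quiet)
model3 <- function() {
  matrix(c(0.2, 0.3, 0.0,
           0.5, 0.3, 0.4,
           1.8, 0.1, 0.5), 3, 3, byrow = TRUE)
}

# relative max deviation on a sensible scale
relerr <- function(a, b, floor = 1e-12) {
  max(abs(a - b)) / max(max(abs(b)), floor)
}

expect_relerr <- function(a, b, tol, floor = 1e-12) {
  expect_lt(relerr(a, b, floor), tol)
}

quiet_eig <- function(M) suppressWarnings(dominant_eigensystem(M))
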