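test_that("H[lambda; vecA] closed forms, symmetry and FD agreement", {
  # 1x1: lambda = a is linear
  H1 <- hessian_lambda_A(matrix(3))
  expect_equal(as.matrix(H1), matrix(0, 1, 1), ignore_attr = TRUE)

  set.seed(9)
  for (i in 1:3) {
    n <- sample(c(3, 4), 1)
    sm <- random_lefkovitch(n, seed = 300 + i)
    H <- hessian_lambda_A(sm)
    expect_identical(dim(H$H), as.integer(c(n^2, n^2)))
    expect_equal(H$H, t(H$H))
    expect_lt(H$asym, 1e-8)
    Hfd <- fd_hessian_auto(lambda_of_vecA(n), vec(sm$A))
    expect_lt(max(abs(H$H - Hfd)), 1e-4 * max(abs(H$H)))
  }
})

test_that("homogeneity and scale laws of the lambda Hessian", {
  for (seedi in c(31, 32)) {
    sm <- random_lefkovitch(5, seed = seedi)
    H <- hessian_lambda_A(sm)
    # differentiate Euler's identity: H vec(A) = 0
    expect_lt(max(abs(H$H %*% vec(sm$A))),
              1e-8 * max(abs(H$H)) * max(abs(vec(sm$A))))
    # lambda degree-1 => H degree -1: H(2A) = H(A)/2
    H2 <- hessian_lambda_A(2 * sm$A)
    expect_relerr(H2$H, H$H / 2, 1e-9)
  }
})

test_that("Hessian chain rule reduces correctly in special cases", {
  sm <- random_lefkovitch(3, seed = 41)
  # identity map theta = vecA reproduces the matrix-entry Hessian
  HA <- hessian_lambda_A(sm)
  Hid <- hessian_lambda_theta(map = identity_map(sm))
  expect_relerr(Hid$H, HA$H, 1e-12)
  expect_equal(Hid$value, HA$value)

  # scalar ray map A(th) = th * A0: lambda linear in th, curvature 0
  A0 <- sm$A
  ray <- custom_map(function(th) th[1] * A0,
                    jac = function(th) matrix(vec(A0), ncol = 1),
                    hess = function(th) matrix(0, 9, 1),
                    theta = 1.3, names = "scale")
  Hray <- hessian_lambda_theta(map = ray)
  expect_lt(abs(Hray$H[1, 1]), 1e-10)
})

test_that("covariation constraint F_i = c P_i matches the FD oracle", {
  # one shared parameter: fertility F[1,2] = th and survival
  # P = U[2,1] = c*th covary; analytic map derivatives are linear
  cc <- 2
  build <- function(th) {
    U <- matrix(c(0, cc * th[1], 0, 0.1), 2, 2)
    F <- matrix(c(0, 0, th[1], 0), 2, 2)
    list(U = U, F = F)
  }
  jacU <- function(th) matrix(c(0, cc, 0, 0), 4, 1)
  jacF <- function(th) matrix(c(0, 0, 1, 0), 4, 1)
  map <- custom_map(build, jac = list(U = jacU, F = jacF),
                    hess = list(U = function(th) matrix(0, 4, 1),
                                F = function(th) matrix(0, 4, 1)),
                    theta = 0.3, names = "theta")
  H <- hessian_lambda_theta(map = map)
  lam_th <- function(th) lambda_of_vecA(2)(vec(build(th)$U + build(th)$F))
  Hfd <- fd_hessian(lam_th, 0.3)
  expect_relerr(H$H, Hfd, 1e-5)
})

test_that("second-order delta-lambda expansion behaves as documented", {
  sm <- random_lefkovitch(4, seed = 51)
  expect_equal(delta_lambda_second_order(sm, matrix(0, 4, 4)), 0)
  # dA = eps*A: homogeneity kills the quadratic term, leaves eps*lambda
  lam <- dominant_eigensystem(sm)$lambda
  expect_equal(delta_lambda_second_order(sm, 0.01 * sm$A), 0.01 * lam,
               tolerance = 1e-9)
  # O(eps^3) error against the recomputed eigenvalue
  set.seed(6)
  E <- matrix(runif(16), 4, 4); E <- E / max(abs(E))
  err <- function(eps) {
    exact <- lambda_of_vecA(4)(vec(sm$A + eps * E)) - lam
    abs(delta_lambda_second_order(sm, eps * E) - exact)
  }
  expect_lt(err(1e-3), 1e-6)
  # cubic scaling: shrinking eps by 4 shrinks the error by ~64
  expect_lt(err(2.5e-4), err(1e-3) / 30)
})
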