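test_that("fundamental matrix and R0 basics", {
  expect_equal(fundamental_matrix(matrix(0, 2, 2)), diag(2))
  expect_equal(fundamental_matrix(matrix(0.5)), matrix(2))
  U <- matrix(c(0, 0.5, 0, 0), 2, 2)
  expect_equal(fundamental_matrix(U), matrix(c(1, 0.5, 0, 1), 2, 2))
  expect_error(fundamental_matrix(diag(2)), "not transient")

  # Leslie example: R = FN by hand, R0 = 1 and lambda(U+F) = 1
  F <- matrix(c(0, 0, 2, 0), 2, 2)
  ng <- R0_value(U, F)
  expect_equal(ng$R, matrix(c(1, 0, 2, 0), 2, 2))
  expect_equal(ng$R0, 1)
  expect_true(ng$single_offspring)
  expect_equal(quiet_eig(U + F)$lambda, 1, tolerance = 1e-12)

  expect_equal(R0_value(U, matrix(0, 2, 2))$R0, 0)
  expect_equal(R0_value(matrix(0.4), matrix(1.2))$R0, 2)
})

test_that("R0 = 1 exactly when lambda = 1 on calibrated random models", {
  for (seedi in c(71, 72, 73)) {
    sm <- random_lefkovitch(4, seed = seedi)
    # rescale fertility so that lambda(U + c F) = 1
    cfun <- function(cc) quiet_eig(sm$U + cc * sm$F)$lambda - 1
    cc <- uniroot(cfun, c(1e-6, 1e6), tol = 1e-14)$root
    ng <- R0_value(sm$U, cc * sm$F)
    expect_lt(abs(ng$R0 - 1), 1e-8)
  }
})

test_that("R0 Hessian closed forms for scalar models", {
  # u = 0.5, f = 1: R0 = f/(1-u), d2R0/du2 = 2f/(1-u)^3 = 16
  H <- hessian_R0_U(matrix(0.5), matrix(1))
  expect_equal(H$H[1, 1], 16, tolerance = 1e-10)
  expect_equal(max(abs(hessian_R0_F(matrix(0.5), matrix(1))$H)), 0)

  # full (u, f) Hessian of f/(1-u) at (0.5, 1): [[16, 4], [4, 0]]
  map <- custom_map(function(th) list(U = matrix(th[1]), F = matrix(th[2])),
                    jac = list(U = function(th) matrix(c(1, 0), 1),
                               F = function(th) matrix(c(0, 1), 1)),
                    hess = list(U = function(th) matrix(0, 2, 2),
                                F = function(th) matrix(0, 2, 2)),
                    theta = c(0.5, 1), names = c("u", "f"))
  Ht <- hessian_R0_theta(map = map)
  expect_equal(Ht$H, matrix(c(16, 4, 4, 0), 2, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("R0 Hessians in U and F match the FD oracle", {
  # single offspring type, including the U = 0 pure-fertility case
  U2 <- matrix(c(0, 0.5, 0, 0), 2, 2)
  F2 <- matrix(c(0, 0, 2, 0), 2, 2)
  H <- hessian_R0_U(U2, F2)
  expect_relerr(H$H, fd_hessian_auto(R0_of_vecU(F2), vec(U2)), 1e-5)

  sm <- random_lefkovitch(4, seed = 81)
  H <- hessian_R0_U(sm$U, sm$F)
  expect_relerr(H$H, fd_hessian_auto(R0_of_vecU(sm$F), vec(sm$U)), 1e-5)
  H0 <- hessian_R0_U(matrix(0, 4, 4), sm$F)
  expect_relerr(H0$H, fd_hessian_auto(R0_of_vecU(sm$F), rep(0, 16)), 1e-5)

  # single offspring: H[R0; vecF] is exactly zero (R0 linear in F)
  expect_equal(max(abs(hessian_R0_F(sm$U, sm$F)$H)), 0)

  # two offspring types: eigenvalue curvature in F is nonzero
  set.seed(4)
  U3 <- matrix(runif(9, 0, 0.25), 3, 3)
  F3 <- matrix(0, 3, 3); F3[1, 2:3] <- c(1.5, 2); F3[2, 3] <- 0.8
  HF <- hessian_R0_F(U3, F3)
  expect_gt(max(abs(HF$H)), 0)
  expect_relerr(HF$H, fd_hessian_auto(R0_of_vecF(U3, F0 = F3), vec(F3)), 1e-5)
  HU <- hessian_R0_U(U3, F3)
  expect_relerr(HU$H, fd_hessian_auto(R0_of_vecU(F3), vec(U3)), 1e-5)
})

test_that("parameter chain rule for R0: survival map and shortcut", {
  sm <- random_lefkovitch(3, seed = 82)
  smap <- survival_map(sm)
  Ht <- hessian_R0_theta(map = smap)
  G <- smap$G; Fm <- sm$F
  f <- function(sig) R0_of_vecU(Fm)(vec(G %*% diag(sig, 3)))
  expect_relerr(Ht$H, fd_hessian_auto(f, smap$theta), 1e-5)

  # single-offspring shortcut (projected entry form) vs the general
  # eigenvalue path: identical to near machine precision
  sm4 <- random_lefkovitch(4, seed = 83)
  smap4 <- survival_map(sm4)
  Hshort <- hessian_R0_theta(map = smap4, method = "entry")
  Hgen <- hessian_R0_theta(map = smap4, method = "eigen")
  expect_relerr(Hshort$H, Hgen$H, 1e-9)
})

test_that("N (I - U) = I and error propagation", {
  sm <- random_lefkovitch(5, seed = 84)
  N <- fundamental_matrix(sm$U)
  expect_lt(max(abs(N %*% (diag(5) - sm$U) - diag(5))), 1e-12)
  expect_error(hessian_R0_U(diag(2), matrix(0, 2, 2)), "not transient")
  expect_error(R0_value(matrix(0.5), matrix(-1)), "nonnegative")
})
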