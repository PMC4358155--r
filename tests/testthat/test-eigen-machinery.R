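test_that("dominant eigensystem applies both scaling conventions", {
  es1 <- dominant_eigensystem(matrix(2))
  expect_equal(es1$lambda, 2)
  expect_equal(unname(es1$w), 1)
  expect_equal(unname(es1$v), 1)

  # closed-form 2x2: lambda = 1, w = (2/3, 1/3), v = (3/4, 3/2)
  es <- quiet_eig(leslie2())
  expect_equal(es$lambda, 1, tolerance = 1e-12)
  expect_equal(unname(es$w), c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(unname(es$v), c(3 / 4, 3 / 2), tolerance = 1e-12)
  expect_equal(sum(es$w), 1)
  expect_equal(sum(es$v * es$w), 1)

  # residuals of the eigen equations
  A <- model3()
  es3 <- dominant_eigensystem(A)
  expect_relerr(A %*% es3$w, es3$lambda * es3$w, 1e-10)
  expect_relerr(t(es3$v) %*% A, es3$lambda * t(es3$v), 1e-10)
})

test_that("eigensystem failure modes are detected", {
  # rotation-like nonnegative matrix with complex dominant pair is
  # impossible; use a matrix with a repeated dominant eigenvalue instead
  expect_error(suppressWarnings(dominant_eigensystem(diag(c(1, 1)))),
               "not simple")
  expect_warning(dominant_eigensystem(leslie2()), "modulus dominance")
  # block-diagonal (reducible) but distinct blocks: warn and proceed
  B <- rbind(cbind(model3(), matrix(0, 3, 2)),
             cbind(matrix(0, 2, 3), matrix(c(0.1, 0.05, 0.1, 0.1), 2, 2)))
  expect_warning(es <- dominant_eigensystem(B), "reducible")
  expect_gt(es$lambda, 1)
  expect_error(stage_matrix(matrix(c(1, -0.1, 0, 1), 2, 2)), "nonnegative")
})

test_that("dlambda_dvecA gives the sensitivities v_i w_j", {
  expect_equal(as.numeric(dlambda_dvecA(matrix(2))), 1)
  es <- quiet_eig(leslie2())
  expect_equal(as.numeric(dlambda_dvecA(es)), c(0.5, 1, 0.25, 0.5),
               tolerance = 1e-12)
  # Euler identity for degree-1 homogeneity: D vec(A) = lambda
  for (A in list(model3(), leslie2())) {
    es <- quiet_eig(A)
    expect_equal(as.numeric(dlambda_dvecA(es) %*% vec(A)), es$lambda,
                 tolerance = 1e-10)
  }
  # FD agreement on random irreducible models
  set.seed(3)
  for (i in 1:4) {
    n <- sample(2:8, 1)
    sm <- random_lefkovitch(n, seed = 100 + i)
    es <- quiet_eig(sm)
    g <- fd_gradient(lambda_of_vecA(n), vec(sm$A))
    expect_relerr(as.numeric(dlambda_dvecA(es)), g, 1e-7)
  }
})

test_that("eigenvector Jacobians satisfy the differentiated scalings", {
  expect_equal(jacobian_w(matrix(2)), matrix(0, 1, 1, dimnames = list(NULL, "a[1,1]")))
  sm <- random_lefkovitch(3, seed = 11)
  es <- dominant_eigensystem(sm)
  Jw <- jacobian_w(es)
  Jv <- jacobian_v(es)
  # e' dw = 0 and v' dw + w' dv = 0 in every direction
  expect_lt(max(abs(colSums(Jw))), 1e-12)
  expect_lt(max(abs(t(es$v) %*% Jw + t(es$w) %*% Jv)), 1e-12)
  # FD oracle on the rescaled eigenvector maps
  n <- 3
  wfun <- function(x) {
    A <- unvec(x, n)
    eA <- eigen(A); i <- which.max(Re(eA$values))
    w <- Re(eA$vectors[, i]); w / sum(w)
  }
  vfun <- function(x) {
    A <- unvec(x, n)
    w <- wfun(x)
    eA <- eigen(t(A)); i <- which.max(Re(eA$values))
    v <- Re(eA$vectors[, i]); v / sum(v * w)
  }
  x0 <- vec(sm$A)
  num_jac <- function(fun) {
    vapply(seq_along(x0), function(k) {
      h <- 1e-6 * max(abs(x0[k]), 1)
      xp <- x0; xp[k] <- xp[k] + h
      xm <- x0; xm[k] <- xm[k] - h
      (fun(xp) - fun(xm)) / (2 * h)
    }, numeric(n))
  }
  expect_relerr(unname(Jw), num_jac(wfun), 1e-6)
  expect_relerr(unname(Jv), num_jac(vfun), 1e-6)
})

test_that("first-order perturbation is consistent with the gradient", {
  set.seed(5)
  sm <- random_lefkovitch(4, seed = 21)
  es <- dominant_eigensystem(sm)
  D <- dlambda_dvecA(es)
  for (i in 1:3) {
    E <- matrix(rnorm(16), 4, 4); E <- E / max(abs(E))
    eps <- 1e-6
    dl <- lambda_of_vecA(4)(vec(sm$A + eps * E)) - es$lambda
    expect_equal(dl, eps * as.numeric(D %*% vec(E)), tolerance = 1e-4)
  }
})
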