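test_that("survival decomposition U = G diag(sigma) is exact", {
  sm <- random_lefkovitch(5, seed = 91)
  smap <- survival_map(sm)
  expect_equal(smap$sigma, unname(colSums(sm$U)))
  expect_equal(smap$G %*% diag(smap$sigma), sm$U, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(unname(colSums(smap$G)), rep(1, 5), tolerance = 1e-12)
  # rebuilding the model from (G, sigma) changes nothing
  rebuilt <- smap$build(smap$theta)
  expect_equal(rebuilt$U + rebuilt$F, sm$A, tolerance = 1e-14,
               ignore_attr = TRUE)
  # the stacked Hessian of the map is literally zero
  expect_true(all(smap$hess_A == 0))
})

test_that("survival map jacobian is block-diagonal in G", {
  sm <- random_lefkovitch(3, seed = 92)
  smap <- survival_map(sm)
  for (j in 1:3) {
    col <- smap$jac_A[, j]
    M <- unvec(col, 3)
    expect_equal(M[, j], unname(smap$G[, j]))
    expect_true(all(M[, -j] == 0))
  }
})

test_that("2-stage closed form: lambda = sqrt(2 sigma1)", {
  # U = [[0,0],[0.5,0]], F = [[0,2],[0,0]]: sigma = (0.5, 0) and
  # lambda = sqrt(2 sigma1); d2 lambda / d sigma1^2 at 0.5 is -1
  sm <- leslie2_sm()
  expect_warning(smap <- survival_map(sm), "sigma\\[2\\] = 0")
  Hs <- suppressWarnings(hessian_lambda_theta(map = smap))
  expect_equal(Hs$H[1, 1], -1, tolerance = 1e-9)
  expect_equal(suppressWarnings(dominant_eigensystem(sm))$lambda,
               sqrt(2 * 0.5), tolerance = 1e-12)
})

test_that("survival Hessian of lambda reduces to the quadratic form", {
  sm <- random_lefkovitch(4, seed = 93)
  smap <- survival_map(sm)
  HA <- hessian_lambda_A(sm)
  B <- smap$jac_A
  expect_relerr(hessian_lambda_theta(map = smap)$H,
                t(B) %*% HA$H %*% B, 1e-12)
})

test_that("custom maps validate shapes and FD-fill derivatives", {
  A0 <- model3()
  # wrong jacobian shape errors on construction
  expect_error(custom_map(function(th) th[1] * A0,
                          jac = function(th) matrix(1, 2, 1),
                          theta = 1), "dimensions")
  # FD-generated derivatives work end to end (both fills are announced)
  msgs <- capture_messages(m <- custom_map(function(th) th[1] * A0,
                                           theta = 1.2))
  expect_length(grep("central differences", msgs), 2)
  expect_relerr(m$jac_A, matrix(vec(A0), ncol = 1), 1e-6)
  expect_lt(max(abs(m$hess_A)), 1e-4)
  expect_false(any(m$analytic))
})
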