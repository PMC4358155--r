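test_that("selection classification follows the sign rules", {
  Z <- matrix(0, 3, 3)
  rz <- classify_selection(Z, tol = 1e-8)
  expect_true(all(rz$traits$class == "linear"))
  expect_true(all(rz$pairs$sign == "none"))

  H <- matrix(c(-2, 0.5, 0.001,
                0.5, 3, -0.9,
                0.001, -0.9, 0.01), 3, 3)
  rownames(H) <- colnames(H) <- c("t1", "t2", "t3")
  r <- classify_selection(H)  # tol = 0.05 * 3 = 0.15
  expect_equal(r$traits$class, c("concave", "convex", "linear"))
  pr <- r$pairs
  expect_equal(pr$sign[pr$trait_i == "t1" & pr$trait_j == "t2"], "positive")
  expect_equal(pr$sign[pr$trait_i == "t2" & pr$trait_j == "t3"], "negative")
  expect_equal(pr$sign[pr$trait_i == "t1" & pr$trait_j == "t3"], "none")

  # invariant to symmetric positive rescaling (signs only)
  r2 <- classify_selection(10 * H)
  expect_equal(r2$traits$class, r$traits$class)
  expect_equal(r2$pairs$sign, r$pairs$sign)

  expect_error(classify_selection(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ESS stability classification", {
  expect_equal(ess_stability(c(-1, 1, 0)),
               c("stable", "unstable", "degenerate"))
  expect_equal(ess_stability(5e-9, tol = 1e-8), "degenerate")
})

test_that("report regenerated from exported Hessian files matches", {
  sm <- random_lefkovitch(3, seed = 111)
  Hs <- hessian_lambda_theta(map = survival_map(sm))
  in_mem <- classify_selection(Hs)
  for (fmt in c("square", "long", "json")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_hessian(Hs, f, format = fmt)
    back <- classify_selection(read_hessian(f, format = fmt))
    expect_equal(back$traits$class, in_mem$traits$class)
    expect_equal(back$pairs$sign, in_mem$pairs$sign)
    expect_equal(back$tol, in_mem$tol, tolerance = 1e-8)
    unlink(f)
  }
})

test_that("selection gradient root finder locates a singular strategy", {
  # trade-off: fertility th vs survival 0.9 - 0.4*th^2 on 2 stages;
  # lambda(th) peaks inside the interval
  build <- function(th) {
    matrix(c(0, 0.5, th, 0.9 - 0.4 * th^2), 2, 2)
  }
  root <- selection_gradient_root(build, c(0.3, 1.4))
  lamf <- function(th) lambda_of_vecA(2)(vec(build(th)))
  # the located point is a maximum of lambda
  expect_gt(lamf(root$root), lamf(root$root + 0.05))
  expect_gt(lamf(root$root), lamf(root$root - 0.05))
})
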