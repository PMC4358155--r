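test_that("small-noise approximation limits and structure", {
  sm <- random_lefkovitch(3, seed = 101)
  lam <- dominant_eigensystem(sm)$lambda
  env0 <- stochastic_env(sm$A)
  expect_equal(log_lambda_s_approx(env0), log(lam), tolerance = 1e-12)

  set.seed(8)
  L <- matrix(rnorm(81, 0, 0.02), 9)
  C <- crossprod(L)
  env <- stochastic_env(sm$A, C)
  lls <- log_lambda_s_approx(env)
  # variance on sensitive entries strictly penalizes stochastic growth
  expect_lt(lls, log(lam))
  # noise penalty is linear in C
  env2 <- stochastic_env(sm$A, 2 * C)
  expect_equal(log(lam) - log_lambda_s_approx(env2),
               2 * (log(lam) - lls), tolerance = 1e-12)

  expect_error(stochastic_env(sm$A, -C), "semidefinite")
  expect_error(stochastic_env(sm$A, C[1:4, 1:4]), "vec order")
})

test_that("printed stochastic sensitivity equals the FD gradient of the approximation", {
  sm <- random_lefkovitch(3, seed = 102)
  set.seed(12)
  L <- matrix(rnorm(81, 0, 0.02), 9)
  C <- crossprod(L)
  env <- stochastic_env(sm$A, C)
  sens <- dlogLambdaS_dvecA(env)
  f63 <- log_lambda_s_of_vecA(C)
  # the oracle map and the approximation agree at the base point
  expect_equal(f63(vec(sm$A)), log_lambda_s_approx(env), tolerance = 1e-14)
  g <- fd_gradient(f63, vec(sm$A))
  expect_relerr(as.numeric(sens), g, 1e-5)
  # C = 0 reduces to the deterministic sensitivities D / lambda
  env0 <- stochastic_env(sm$A)
  es <- dominant_eigensystem(sm)
  expect_relerr(as.numeric(dlogLambdaS_dvecA(env0)),
                as.numeric(dlambda_dvecA(es)) / es$lambda, 1e-12)
  # noise term linear in C: sens(2C) - D/lam = 2 (sens(C) - D/lam)
  env2 <- stochastic_env(sm$A, 2 * C)
  base <- as.numeric(dlambda_dvecA(es)) / es$lambda
  expect_relerr(as.numeric(dlogLambdaS_dvecA(env2)) - base,
                2 * (as.numeric(sens) - base), 1e-10)
})

test_that("matrix-product simulation is reproducible and correct at C = 0", {
  sm <- random_lefkovitch(2, seed = 103)
  lam <- dominant_eigensystem(sm)$lambda
  env0 <- stochastic_env(sm$A)
  sim <- stochastic_growth_sim(env0, steps = 200, seed = 1)
  # started at the stable structure, every increment is log lambda
  expect_equal(sim$estimate, log(lam), tolerance = 1e-6)

  set.seed(13)
  C <- diag(rep(1e-4, 4))
  # variance only on observed transitions to keep matrices nonnegative
  C[vec(sm$A) == 0, ] <- 0; C[, vec(sm$A) == 0] <- 0
  env <- stochastic_env(sm$A, C)
  s1 <- stochastic_growth_sim(env, steps = 4000, seed = 42)
  s1b <- stochastic_growth_sim(env, steps = 4000, seed = 42)
  expect_identical(s1$estimate, s1b$estimate)
  s2 <- stochastic_growth_sim(env, steps = 4000, seed = 43)
  expect_false(identical(s1$estimate, s2$estimate))
  # two seeds agree within 3 combined standard errors
  expect_lt(abs(s1$estimate - s2$estimate),
            3 * sqrt(s1$se^2 + s2$se^2))
})

test_that("noise penalty scales linearly on a simulated variance grid", {
  sm <- random_lefkovitch(2, seed = 104)
  lam <- dominant_eigensystem(sm)$lambda
  mask <- as.numeric(vec(sm$A) > 0)
  C1 <- diag(4e-4 * mask^2)
  # common random numbers: same seed, C halved scales the same draws
  pen <- function(C) {
    env <- stochastic_env(sm$A, C)
    log(lam) - stochastic_growth_sim(env, steps = 30000, seed = 7)$estimate
  }
  p1 <- pen(C1)
  p2 <- pen(C1 / 2)
  expect_gt(p1, 0)
  # halving C approximately halves the small-noise penalty
  expect_gt(p1 / p2, 1.6)
  expect_lt(p1 / p2, 2.4)
})

test_that("lognormal generator and extinction guard work", {
  sm <- random_lefkovitch(2, seed = 105)
  C <- diag(1e-4 * as.numeric(vec(sm$A) > 0))
  env <- stochastic_env(sm$A, C)
  s <- stochastic_growth_sim(env, steps = 500, seed = 3, dist = "lognormal")
  expect_true(is.finite(s$estimate))
  # catastrophic noise drives the population extinct
  bigC <- diag(25 * as.numeric(vec(sm$A) > 0))
  envbig <- stochastic_env(sm$A, bigC)
  expect_error(stochastic_growth_sim(envbig, steps = 2000, seed = 3),
               "extinct")
})
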