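#' Stochastic environment: mean matrix plus entry covariances
#'
#' Container for the small-noise description of a stochastic
#' environment: a mean projection matrix \code{Abar} and the
#' \code{n^2 x n^2} covariance matrix \code{C} of the entries of
#' \code{vec(A_t)}, assumed uncorrelated in time.  \code{C} is treated
#' as a primitive input; the package never estimates it from data.
#'
#' @param Abar nonnegative mean projection matrix with a simple real
#'   dominant eigenvalue.
#' @param C symmetric positive semidefinite \code{n^2 x n^2} covariance
#'   matrix (default zero: a deterministic environment).
#' @param tol tolerance for the symmetry/PSD checks.
#' @return an object of class \code{"stochastic_env"}.
#' @export
stochastic_env <- function(Abar, C = NULL, tol = 1e-8) {
  sm <- as_stage_matrix(Abar)
  n <- sm$n
  if (is.null(C)) C <- matrix(0, n * n, n * n)
  C <- as.matrix(C)
  if (!identical(dim(C), c(n * n, n * n)))
    stop(sprintf("stochastic_env(): C must be %d x %d (vec order)", n * n, n * n))
  scale <- max(abs(C), 1)
  if (max(abs(C - t(C))) > tol * scale)
    stop("stochastic_env(): C is not symmetric")
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -tol * max(abs(ev$values), 1))
    stop("stochastic_env(): C is not positive semidefinite")
  structure(list(Abar = sm$A, C = C, n = n, C_eig = ev),
            class = "stochastic_env")
}

#' @export
print.stochastic_env <- function(x, ...) {
  cat(sprintf("Stochastic environment: %d stages, total entry variance %.4g\n",
              x$n, sum(diag(x$C))))
  invisible(x)
}

#' Small-noise approximation to the stochastic growth rate
#'
#' Tuljapurkar's approximation for temporally uncorrelated environments,
#' written in terms of the sensitivity row vector
#' \eqn{D = D[\lambda; \mathrm{vec}\bar{A}]} of the dominant eigenvalue
#' \eqn{\bar\lambda} of the mean matrix:
#' \deqn{\log\lambda_s \approx \log\bar\lambda -
#'   \frac{D\,C\,D^T}{2\bar\lambda^2}.}
#' With \code{C = 0} this is exactly \eqn{\log\bar\lambda}; any noise
#' that loads on the sensitivities strictly reduces stochastic growth.
#'
#' @param env a [stochastic_env()].
#' @return scalar approximate \eqn{\log\lambda_s}.
#' @export
log_lambda_s_approx <- function(env) {
  stopifnot(inherits(env, "stochastic_env"))
  es <- dominant_eigensystem(env$Abar)
  D <- dlambda_dvecA(es)
  tau2 <- as.numeric(D %*% env$C %*% t(D))
  log(es$lambda) - tau2 / (2 * es$lambda^2)
}

#' Sensitivity of the small-noise stochastic growth rate
#'
#' Gradient of [log_lambda_s_approx()] with respect to the entries of
#' the mean matrix, holding the covariances fixed.  Differentiating the
#' approximation (with \eqn{\tau^2 = D C D^T} and
#' \eqn{H = H[\lambda; \mathrm{vec}\bar A]}) gives
#' \deqn{\frac{d \log\lambda_s}{d\,\mathrm{vec}\bar{A}} =
#'  \frac{D}{\bar\lambda} + \frac{\tau^2}{\bar\lambda^3} D -
#'  \frac{1}{\bar\lambda^2}\, D\,C\,H.}
#' With \code{C = 0} this reduces to the deterministic sensitivities of
#' \eqn{\log\bar\lambda}; the noise contribution is linear in \code{C}.
#'
#' @param env a [stochastic_env()].
#' @return a \code{1 x n^2} gradient in vec order.
#' @export
dlogLambdaS_dvecA <- function(env) {
  stopifnot(inherits(env, "stochastic_env"))
  es <- dominant_eigensystem(env$Abar)
  H <- hessian_lambda_A(env$Abar, es = es)
  D <- H$D
  lam <- es$lambda
  tau2 <- as.numeric(D %*% env$C %*% t(D))
  out <- D / lam + (tau2 / lam^3) * D - (D %*% env$C %*% H$H) / lam^2
  colnames(out) <- entry_labels(env$n)
  out
}

#' Small-noise approximation as a map over vec(Abar)
#'
#' Oracle form of [log_lambda_s_approx()]: a plain function of
#' \code{vec(Abar)} with the covariance matrix held fixed, imposing no
#' nonnegativity on probe points (the approximation is defined in a
#' neighbourhood of the mean matrix).  This is the map whose central
#' finite differences must agree with [dlogLambdaS_dvecA()].
#'
#' @param C fixed \code{n^2 x n^2} covariance matrix.
#' @param n stage count.
#' @return function mapping \code{vec(Abar)} to the approximate
#'   \eqn{\log\lambda_s}.
#' @export
log_lambda_s_of_vecA <- function(C, n = as.integer(sqrt(nrow(C)))) {
  C <- as.matrix(C)
  force(n)
  function(x) {
    A <- unvec(x, n)
    eA <- eigen(A)
    i <- which.max(Re(eA$values))
    lam <- Re(eA$values[i])
    w <- Re(eA$vectors[, i]); w <- w / sum(w)
    eAt <- eigen(t(A))
    v <- Re(eAt$vectors[, which.max(Re(eAt$values))])
    v <- v / sum(v * w)
    D <- kronecker(w, v)
    tau2 <- as.numeric(t(D) %*% C %*% D)
    log(lam) - tau2 / (2 * lam^2)
  }
}

#' Monte-Carlo estimate of the stochastic growth rate
#'
#' Simulates i.i.d. random projection matrices with mean \code{Abar} and
#' entry covariance approximately \code{C}, and accumulates the log
#' population growth \eqn{T^{-1} \log (N(T)/N(0))}.  Two generators are
#' available: \code{"truncnorm"} draws multivariate normal perturbations
#' with covariance \code{C} and clips negative entries at zero (the
#' default; the clipping fraction is reported as a diagnostic);
#' \code{"lognormal"} perturbs each nonzero entry independently with a
#' lognormal matched to its mean and variance (ignoring
#' cross-covariances in \code{C}).  The start vector is the stable stage
#' structure of \code{Abar}, which shortens transients.  The standard
#' error is computed by batch means to absorb the short-range
#' autocorrelation of the one-step log growth rates.
#'
#' @param env a [stochastic_env()].
#' @param steps number of time steps \code{T}.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param dist perturbation generator.
#' @param batch batch length for the batch-means standard error.
#' @return list with \code{estimate}, \code{se}, \code{steps},
#'   \code{clipped} (fraction of matrix entries clipped at zero).
#' @export
stochastic_growth_sim <- function(env, steps = 1e4, seed = NULL,
                                  dist = c("truncnorm", "lognormal"),
                                  batch = 50) {
  stopifnot(inherits(env, "stochastic_env"))
  dist <- match.arg(dist)
  if (steps < 1) stop("stochastic_growth_sim(): steps must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- env$n; n2 <- n * n
  Abar <- env$Abar
  w0 <- dominant_eigensystem(Abar)$w
  noisy <- max(abs(env$C)) > 0
  clipped <- 0L
  if (noisy) {
    if (dist == "truncnorm") {
      ev <- env$C_eig
      pos <- ev$values > 1e-14 * max(ev$values)
      L <- ev$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(ev$values[pos]), sum(pos))
      Z <- matrix(stats::rnorm(steps * ncol(L)), steps) %*% t(L)
    } else {
      vars <- diag(env$C)
      a0 <- vec(Abar)
      act <- which(vars > 0 & a0 > 0)
      if (any(vars > 0 & a0 <= 0))
        warning("lognormal generator: variance on zero-mean entries ignored")
    }
  }
  x <- w0
  incr <- numeric(steps)
  for (t in seq_len(steps)) {
    if (!noisy) {
      At <- Abar
    } else if (dist == "truncnorm") {
      At <- Abar + unvec(Z[t, ], n)
      neg <- At < 0
      clipped <- clipped + sum(neg)
      At[neg] <- 0
    } else {
      At <- Abar
      for (k in act) {
        m <- a0[k]; cv <- vars[k]
        sl2 <- log(1 + cv / m^2)
        At[k] <- stats::rlnorm(1, meanlog = log(m) - sl2 / 2, sdlog = sqrt(sl2))
      }
    }
    x <- as.numeric(At %*% x)
    tot <- sum(x)
    if (!is.finite(tot) || tot <= 0)
      stop("stochastic_growth_sim(): population went extinct; reduce the noise level")
    incr[t] <- log(tot)
    x <- x / tot
  }
  nb <- max(1L, floor(steps / batch))
  bm <- colMeans(matrix(incr[seq_len(nb * batch)], nrow = batch))
  se <- if (nb > 1) stats::sd(bm) / sqrt(nb) else NA_real_
  list(estimate = mean(incr), se = se, steps = steps,
       clipped = clipped / (steps * n2))
}
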