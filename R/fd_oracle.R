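#' Finite-difference configuration
#'
#' Central-difference step sizes used by the numerical oracle.  Defaults
#' are the optimal scalings for \emph{central} stencils under O(eps)
#' function noise: cube root of machine epsilon for first derivatives
#' (truncation O(h^2) balanced against rounding O(eps/h)) and fourth
#' root for second derivatives (rounding O(eps/h^2)).  Steps are applied
#' relative to the coordinate magnitude with an absolute floor for
#' coordinates near zero.
#'
#' @param h_grad relative step for gradients.
#' @param h_hess relative step for Hessians.
#' @param h_abs absolute floor on the coordinate magnitude used to scale
#'   steps.
#' @export
fd_config <- function(h_grad = .Machine$double.eps^(1/3),
                      h_hess = .Machine$double.eps^(1/4),
                      h_abs = 1) {
  stopifnot(h_grad > 0, h_hess > 0, h_abs > 0)
  structure(list(h_grad = h_grad, h_hess = h_hess, h_abs = h_abs),
            class = "fd_config")
}

#' Central finite-difference gradient
#'
#' Independent numerical oracle used to validate every analytic formula
#' in the package; it deliberately shares no code with the analytic
#' paths.
#'
#' @param f scalar-valued function of a numeric vector.
#' @param x evaluation point.
#' @param cfg an [fd_config()].
#' @return gradient vector of length \code{length(x)}.
#' @export
fd_gradient <- function(f, x, cfg = fd_config()) {
  x <- as.numeric(x)
  m <- length(x)
  g <- numeric(m)
  for (k in seq_len(m)) {
    h <- cfg$h_grad * max(abs(x[k]), cfg$h_abs)
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    fp <- f(xp); fm <- f(xm)
    if (!is.finite(fp) || !is.finite(fm))
      stop(sprintf("fd_gradient(): non-finite function value at coordinate %d", k))
    g[k] <- (fp - fm) / (2 * h)
  }
  g
}

#' Central finite-difference Hessian
#'
#' Second-difference stencil on the diagonal, four-point mixed stencil
#' off the diagonal; the result is symmetrized.  With
#' \code{richardson = TRUE} the stencil is evaluated at steps \code{h}
#' and \code{h/2} and extrapolated as \code{(4 H(h/2) - H(h)) / 3},
#' cancelling the leading O(h^2) truncation term; this matters for
#' stiff targets such as eigenvalues of matrices with small spectral
#' gaps, whose higher derivatives are large.
#'
#' @inheritParams fd_gradient
#' @param richardson extrapolate over two step sizes.
#' @return symmetric \code{length(x) x length(x)} matrix.
#' @export
fd_hessian <- function(f, x, cfg = fd_config(), richardson = FALSE) {
  if (richardson) {
    H1 <- fd_hessian(f, x, cfg, richardson = FALSE)
    cfg2 <- cfg
    cfg2$h_hess <- cfg$h_hess / 2
    H2 <- fd_hessian(f, x, cfg2, richardson = FALSE)
    return((4 * H2 - H1) / 3)
  }
  x <- as.numeric(x)
  m <- length(x)
  h <- cfg$h_hess * pmax(abs(x), cfg$h_abs)
  H <- matrix(0, m, m)
  f0 <- f(x)
  if (!is.finite(f0)) stop("fd_hessian(): non-finite function value at x")
  for (k in seq_len(m)) {
    xp <- x; xp[k] <- xp[k] + h[k]
    xm <- x; xm[k] <- xm[k] - h[k]
    fp <- f(xp); fm <- f(xm)
    if (!is.finite(fp) || !is.finite(fm))
      stop(sprintf("fd_hessian(): non-finite function value at coordinate %d", k))
    H[k, k] <- (fp - 2 * f0 + fm) / h[k]^2
  }
  if (m > 1) {
    for (k in 2:m) for (l in seq_len(k - 1)) {
      xpp <- x; xpp[k] <- xpp[k] + h[k]; xpp[l] <- xpp[l] + h[l]
      xpm <- x; xpm[k] <- xpm[k] + h[k]; xpm[l] <- xpm[l] - h[l]
      xmp <- x; xmp[k] <- xmp[k] - h[k]; xmp[l] <- xmp[l] + h[l]
      xmm <- x; xmm[k] <- xmm[k] - h[k]; xmm[l] <- xmm[l] - h[l]
      val <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[k] * h[l])
      if (!is.finite(val))
        stop(sprintf("fd_hessian(): non-finite stencil at coordinates (%d, %d)", k, l))
      H[k, l] <- H[l, k] <- val
    }
  }
  (H + t(H)) / 2
}

#' Step-adaptive Richardson finite-difference Hessian
#'
#' Evaluates the central Hessian stencil at a descending ladder of base
#' steps, each with its half-step Richardson partner, and returns the
#' extrapolation from the best-converged pair.  The within-pair stencil
#' difference is the error monitor: in the truncation-dominated regime
#' (stiff functions, e.g. eigenvalues of next-generation matrices with
#' small dominant eigenvalues, whose higher derivatives are enormous)
#' the differences shrink as the step decreases and the descent
#' continues; once rounding noise dominates the differences grow again
#' and the previous level wins.  The descent also stops early when a
#' pair already agrees to well below any useful tolerance.
#'
#' @inheritParams fd_gradient
#' @param steps descending ladder of base relative steps.
#' @return symmetric Hessian matrix.
#' @export
fd_hessian_auto <- function(f, x, steps = 1.2e-4 / 4^(0:3),
                            cfg = fd_config()) {
  stopifnot(length(steps) >= 1, all(diff(steps) < 0))
  cf <- function(h) { c2 <- cfg; c2$h_hess <- h; c2 }
  best <- NULL
  best_d <- Inf
  best_h <- steps[1]
  for (h in steps) {
    Ha <- fd_hessian(f, x, cf(h))
    Hb <- fd_hessian(f, x, cf(h / 2))
    d <- sqrt(sum((Ha - Hb)^2))
    R <- (4 * Hb - Ha) / 3
    if (d < best_d) {
      best <- R
      best_d <- d
      best_h <- h
    } else {
      break  # rounding regime reached; stop descending
    }
    sc <- max(abs(Hb), 1e-2)
    if (max(abs(Ha - Hb)) / sc < 1e-6) break  # already converged
  }
  attr(best, "step") <- best_h
  best
}

#' Numerical oracles for the growth rates
#'
#' Convenience wrappers turning a projection matrix (or decomposition)
#' into the scalar maps probed by the finite-difference oracle.
#' \code{lambda_of_vecA} returns the dominant eigenvalue as a function
#' of \code{vec(A)} (no nonnegativity clamp: the eigenvalue is defined
#' in a neighbourhood); \code{R0_of_vecU} and \code{R0_of_vecF} fix the
#' other factor of the decomposition.
#'
#' @param n stage count (for \code{lambda_of_vecA}).
#' @param U,F fixed matrices for the \code{R0} maps.
#' @param offspring_stage passed to [R0_value()].
#' @return a function of a numeric vector.
#' @export
lambda_of_vecA <- function(n) {
  function(x) {
    A <- unvec(x, n)
    ev <- eigen(A, only.values = TRUE)$values
    Re(ev[which.max(Re(ev))])
  }
}

#' @rdname lambda_of_vecA
#' @details The \code{R0} oracle maps freeze the offspring convention at
#'   the base point: with a single offspring type \eqn{R_0} is the
#'   \eqn{(o, o)} entry of \eqn{FN} (a definition that stays linear in
#'   \code{F} for all probe directions), otherwise the dominant
#'   eigenvalue of \eqn{FN}.  Probes do not enforce nonnegativity (the
#'   growth rates are defined in a neighbourhood); only the transience
#'   of \code{U} is a hard domain boundary.
#' @export
R0_of_vecU <- function(F, offspring_stage = NULL) {
  F <- as.matrix(F)
  n <- nrow(F)
  conv <- .offspring_convention(F, offspring_stage)
  function(x) {
    U <- unvec(x, n)
    if (max(Mod(eigen(U, only.values = TRUE)$values)) >= 1 - 1e-10)
      stop("R0 oracle: probe left the transient domain (rho(U) >= 1)")
    R <- F %*% solve(diag(n) - U)
    .R0_of_R(R, conv)
  }
}

#' @rdname lambda_of_vecA
#' @param F0 base fertility matrix fixing the offspring convention for
#'   \code{R0_of_vecF} (defaults to multiple offspring types).
#' @export
R0_of_vecF <- function(U, F0 = NULL, offspring_stage = NULL) {
  U <- as.matrix(U)
  n <- nrow(U)
  conv <- if (is.null(F0) && is.null(offspring_stage))
    list(single = FALSE, o = 1L)
  else .offspring_convention(F0, offspring_stage)
  N <- solve(diag(n) - U)
  function(x) .R0_of_R(unvec(x, n) %*% N, conv)
}

.offspring_convention <- function(F, offspring_stage = NULL) {
  nz <- which(rowSums(abs(as.matrix(F))) > 0)
  single <- length(nz) <= 1
  o <- offspring_stage %||% if (length(nz) >= 1) nz[1] else 1L
  list(single = single, o = as.integer(o))
}

.R0_of_R <- function(R, conv) {
  if (conv$single) {
    R[conv$o, conv$o]
  } else {
    ev <- eigen(R, only.values = TRUE)$values
    Re(ev[which.max(Re(ev))])
  }
}
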