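#' Differentiable parameter maps
#'
#' A \code{parameter_map} carries a map \eqn{\theta \mapsto A} (or
#' \eqn{\theta \mapsto (U, F)}), its Jacobian
#' \eqn{D[\mathrm{vec}A; \theta]} (\code{n^2 x s}) and its stacked
#' Hessian \eqn{H[\mathrm{vec}A; \theta]} (\code{n^2 s x s}; the
#' \code{s x s} Hessians of the individual entries of \code{vec(A)}
#' stacked rowwise, block \code{k} holding the Hessian of the
#' \code{k}-th vec component).  Missing derivatives are generated by the
#' central finite-difference oracle and flagged as such.
#'
#' @param build function taking a parameter vector and returning either
#'   a square matrix \code{A} or a list with components \code{U} and
#'   \code{F}.
#' @param jac optional analytic Jacobian: a function of \code{theta}
#'   returning the \code{n^2 x s} matrix (kind \code{"A"}) or a list
#'   \code{list(U = , F = )} of two such functions (kind \code{"UF"}).
#' @param hess optional analytic stacked Hessian, same convention.
#' @param theta numeric parameter vector at which the map is evaluated.
#' @param names optional parameter labels.
#' @param fd [fd_config()] used when derivatives must be generated
#'   numerically.
#' @return an object of class \code{"parameter_map"}.
#' @examples
#' # one-parameter covariation constraint F1 = c * P1 on a 2-stage model
#' cmap <- custom_map(function(th) {
#'   U <- matrix(c(0, 2 * th, 0, 0.1), 2, 2)
#'   F <- matrix(c(0, 0, th, 0), 2, 2)
#'   list(U = U, F = F)
#' }, theta = 0.3, names = "theta")
#' @export
custom_map <- function(build, jac = NULL, hess = NULL, theta,
                       names = NULL, fd = fd_config()) {
  theta <- as.numeric(theta)
  s <- length(theta)
  if (is.null(names)) names <- paste0("theta", seq_len(s))
  built <- build(theta)
  kind <- if (is.list(built)) "UF" else "A"
  getUF <- function(b) {
    if (kind == "A") {
      A <- as.matrix(b)
      list(A = A, U = NULL, F = NULL)
    } else {
      list(A = as.matrix(b$U) + as.matrix(b$F),
           U = as.matrix(b$U), F = as.matrix(b$F))
    }
  }
  ev <- getUF(built)
  n <- nrow(ev$A)
  if (ncol(ev$A) != n) stop("custom_map(): build must return a square matrix")
  n2 <- n * n
  vec_of <- function(which) function(th) {
    b <- getUF(build(th))
    vec(b[[which]])
  }
  analytic <- c(jac = !is.null(jac), hess = !is.null(hess))
  fd_jac <- function(fvec) {
    J <- vapply(seq_len(s), function(p) {
      h <- fd$h_grad * max(abs(theta[p]), fd$h_abs)
      tp <- theta; tp[p] <- tp[p] + h
      tm <- theta; tm[p] <- tm[p] - h
      (fvec(tp) - fvec(tm)) / (2 * h)
    }, numeric(n2))
    matrix(J, nrow = n2)
  }
  fd_stack <- function(fvec) {
    Hs <- matrix(0, n2 * s, s)
    for (k in seq_len(n2)) {
      fk <- function(th) fvec(th)[k]
      Hs[((k - 1) * s + 1):(k * s), ] <- fd_hessian(fk, theta, fd)
    }
    Hs
  }
  check_dim <- function(Mx, nr, nc, what) {
    Mx <- as.matrix(Mx)
    if (nrow(Mx) != nr || ncol(Mx) != nc)
      stop(sprintf("custom_map(): %s has dimensions %d x %d, expected %d x %d",
                   what, nrow(Mx), ncol(Mx), nr, nc))
    Mx
  }
  eval_d <- function(fun_or_list, which, fallback, nr, what) {
    if (is.null(fun_or_list)) return(fallback())
    f <- if (kind == "UF" && is.list(fun_or_list)) fun_or_list[[which]]
         else fun_or_list
    check_dim(f(theta), nr, s, what)
  }
  if (kind == "A") {
    jac_A <- eval_d(jac, "A", function() {
      message(sprintf("custom_map(): Jacobian by central differences (rel step %.2g)", fd$h_grad))
      fd_jac(vec_of("A"))
    }, n2, "jac")
    hess_A <- eval_d(hess, "A", function() {
      message(sprintf("custom_map(): stacked Hessian by central differences (rel step %.2g)", fd$h_hess))
      fd_stack(vec_of("A"))
    }, n2 * s, "hess")
    jac_U <- jac_F <- hess_U <- hess_F <- NULL
  } else {
    jac_U <- eval_d(jac, "U", function() fd_jac(vec_of("U")), n2, "jac$U")
    jac_F <- eval_d(jac, "F", function() fd_jac(vec_of("F")), n2, "jac$F")
    if (is.null(jac))
      message(sprintf("custom_map(): Jacobians by central differences (rel step %.2g)", fd$h_grad))
    hess_U <- eval_d(hess, "U", function() fd_stack(vec_of("U")), n2 * s, "hess$U")
    hess_F <- eval_d(hess, "F", function() fd_stack(vec_of("F")), n2 * s, "hess$F")
    if (is.null(hess))
      message(sprintf("custom_map(): stacked Hessians by central differences (rel step %.2g)", fd$h_hess))
    jac_A <- jac_U + jac_F
    hess_A <- hess_U + hess_F
  }
  structure(list(names = names, theta = theta, build = build, kind = kind,
                 A = ev$A, U = ev$U, F = ev$F, n = n, s = s,
                 jac_A = jac_A, hess_A = hess_A,
                 jac_U = jac_U, jac_F = jac_F,
                 hess_U = hess_U, hess_F = hess_F,
                 analytic = analytic),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("Parameter map (%s): %d parameters -> %d x %d matrix\n",
              x$kind, x$s, x$n, x$n))
  cat(sprintf("  jacobian: %s; stacked hessian: %s\n",
              if (x$analytic["jac"]) "analytic" else "finite differences",
              if (x$analytic["hess"]) "analytic" else "finite differences"))
  invisible(x)
}

#' Stage-specific survival parameterization
#'
#' Decomposes the transition matrix as \eqn{U = G\,\mathrm{diag}(\sigma)}
#' where \eqn{\sigma} holds the stage-specific survival probabilities
#' (the column sums of \code{U}) and \code{G} describes stage
#' transitions conditional on survival (columns of \code{G} sum to 1).
#' Assuming a prebreeding census, \code{F} does not depend on
#' \eqn{\sigma}, so \eqn{\partial a_{ij}/\partial\sigma_k = g_{ij}
#' \delta_{jk}} and the stacked Hessian \eqn{H[\mathrm{vec}A; \sigma]}
#' is exactly zero: the Hessian chain rule reduces to the quadratic form
#' \eqn{B^T H[\lambda; \mathrm{vec}A] B} with \eqn{B = D[\mathrm{vec}A;
#' \sigma]}.
#'
#' Columns with \eqn{\sigma_j = 0} leave the conditional transitions
#' undefined (0/0); the corresponding column of \code{G} is set to the
#' unit vector \eqn{e_j} with a warning, which keeps the map total
#' without altering \code{U}.  Derivatives with respect to such
#' \eqn{\sigma_j} are one-sided.
#'
#' @param M a [stage_matrix()] decomposed into \code{U} and \code{F}.
#' @return a [custom_map()]-style \code{parameter_map} over
#'   \eqn{\sigma}, with analytic (exact) Jacobian and an exactly zero
#'   stacked Hessian, plus components \code{G} and \code{sigma}.
#' @export
survival_map <- function(M) {
  sm <- as_stage_matrix(M)
  if (is.null(sm$U))
    stop("survival_map(): stage matrix must be decomposed into U and F")
  U <- sm$U; Fm <- sm$F
  n <- sm$n
  sigma <- colSums(U)
  if (any(sigma > 1 + 1e-8))
    stop("survival_map(): column sums of U exceed 1")
  G <- U
  for (j in seq_len(n)) {
    if (sigma[j] > 0) {
      G[, j] <- U[, j] / sigma[j]
    } else {
      warning(sprintf("survival_map(): sigma[%d] = 0; G column set to e_%d", j, j))
      G[, j] <- 0; G[j, j] <- 1
    }
  }
  n2 <- n * n
  jac_U <- matrix(0, n2, n)
  for (j in seq_len(n)) jac_U[(j - 1) * n + seq_len(n), j] <- G[, j]
  zero_stack <- matrix(0, n2 * n, n)
  build <- function(sig) list(U = G %*% diag(sig, n), F = Fm)
  map <- structure(list(
    names = paste0("sigma", seq_len(n)),
    theta = unname(sigma), build = build, kind = "UF",
    A = sm$A, U = U, F = Fm, n = n, s = n,
    jac_A = jac_U, hess_A = zero_stack,
    jac_U = jac_U, jac_F = matrix(0, n2, n),
    hess_U = zero_stack, hess_F = zero_stack,
    analytic = c(jac = TRUE, hess = TRUE),
    G = G, sigma = unname(sigma)),
    class = "parameter_map")
  map
}

#' Identity parameter map on vec(A)
#'
#' Each matrix entry is its own parameter; the Hessian chain rule then
#' reproduces the matrix-entry Hessians exactly.
#'
#' @param M a [stage_matrix()] or plain matrix.
#' @export
identity_map <- function(M) {
  sm <- as_stage_matrix(M)
  n <- sm$n
  custom_map(function(th) unvec(th, n), jac = function(th) diag(n * n),
             hess = function(th) matrix(0, n * n * n * n, n * n),
             theta = vec(sm$A), names = entry_labels(n))
}

.check_map <- function(map, M = NULL) {
  if (!inherits(map, "parameter_map"))
    stop("expected a parameter_map (see custom_map(), survival_map())")
  if (!is.null(M)) {
    sm <- as_stage_matrix(M)
    if (sm$n != map$n)
      stop("parameter map dimension does not match the stage matrix")
    if (max(abs(sm$A - map$A)) > 1e-6)
      warning("stage matrix differs from the map's evaluation point; using the map's A")
  }
  map
}
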