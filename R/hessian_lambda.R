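#' Hessian of lambda with respect to matrix entries
#'
#' The second derivatives of the dominant eigenvalue with respect to all
#' pairs of projection-matrix entries,
#' \eqn{H[\lambda; \mathrm{vec}A]}, an \code{n^2 x n^2} symmetric matrix
#' in vec order.  Starting from the first differential
#' \eqn{d\lambda = (w^T \otimes v^T)\, d\mathrm{vec}A} (under the
#' scalings \eqn{e^T w = 1}, \eqn{v^T w = 1}), differentiating again and
#' substituting the eigenvector Jacobians gives the bilinear form
#' \deqn{d^2\lambda = d\mathrm{vec}^T\!A\,
#'   \left[(I_n \otimes v)\, D[w] + (w \otimes I_n)\, D[v]\right]
#'   d\mathrm{vec}A,}
#' whose symmetrized coefficient matrix is the Hessian (second
#' identification theorem).
#'
#' @param M a [stage_matrix()] or plain nonnegative square matrix with a
#'   simple, real dominant eigenvalue.
#' @param es optionally a precomputed [dominant_eigensystem()].
#' @return a [growth_hessian_object()] with \code{rate = "lambda"},
#'   \code{wrt = "A"}.
#' @examples
#' hessian_lambda_A(matrix(c(0, 0.5, 2, 0), 2, 2))
#' @export
hessian_lambda_A <- function(M, es = NULL) {
  sm <- as_stage_matrix(M)
  if (is.null(es)) es <- dominant_eigensystem(sm)
  n <- es$n
  if (n == 1) {
    return(growth_hessian_object(matrix(0, 1, 1), "lambda", "A",
                                 entry_labels(1), value = es$lambda,
                                 D = matrix(1, 1, 1), n = 1L))
  }
  J <- .eig_jacobians(es)
  In <- diag(n)
  B <- (In %x% matrix(es$v, ncol = 1)) %*% J$Jw +
       (matrix(es$w, ncol = 1) %x% In) %*% J$Jv
  growth_hessian_object(B, "lambda", "A", entry_labels(n),
                        value = es$lambda, D = dlambda_dvecA(es), n = n)
}

# Hessian chain rule shared by lambda and R0:
#   H[f; theta] = J' H[f; x] J + sum_k D_k H[x_k; theta]
# where J = D[x; theta] (n2 x s) and Hx is the stacked Hessian of the
# inner map, row blocks of size s per component of x (block k = Hessian
# of x_k).  D is the 1 x n2 gradient of f in x.
.chain_hessian <- function(Hf, D, J, Hstack) {
  s <- ncol(J)
  term1 <- t(J) %*% Hf %*% J
  term2 <- matrix(0, s, s)
  if (!is.null(Hstack) && max(abs(Hstack)) > 0) {
    for (k in seq_len(nrow(J))) {
      dk <- D[k]
      if (dk != 0) {
        blk <- Hstack[((k - 1) * s + 1):(k * s), , drop = FALSE]
        term2 <- term2 + dk * blk
      }
    }
  }
  term1 + term2
}

#' Hessian of lambda with respect to lower-level parameters
#'
#' The Hessian chain rule: for a differentiable map
#' \eqn{\theta \mapsto A(\theta)} with Jacobian
#' \eqn{J = D[\mathrm{vec}A; \theta]} and stacked Hessian
#' \eqn{H[\mathrm{vec}A; \theta]} (the per-entry Hessians stacked
#' rowwise),
#' \deqn{H[\lambda; \theta] = J^T H[\lambda; \mathrm{vec}A]\, J
#'   + \sum_k \frac{\partial \lambda}{\partial (\mathrm{vec}A)_k}
#'     H[(\mathrm{vec}A)_k; \theta].}
#' With the identity map this reduces to [hessian_lambda_A()]; for the
#' built-in survival parameterization the stacked Hessian vanishes and
#' only the quadratic form survives.
#'
#' @param M a [stage_matrix()] consistent with the map's evaluation
#'   point, or \code{NULL} to use the map's own build.
#' @param map a [parameter_map()] (e.g. [survival_map()],
#'   [custom_map()]).
#' @return a [growth_hessian_object()] over the map's parameters.
#' @export
hessian_lambda_theta <- function(M = NULL, map) {
  map <- .check_map(map, M)
  es <- dominant_eigensystem(map$A)
  HA <- hessian_lambda_A(map$A, es = es)
  B <- .chain_hessian(HA$H, as.numeric(HA$D), map$jac_A, map$hess_A)
  Dth <- HA$D %*% map$jac_A
  growth_hessian_object(B, "lambda", "theta", map$names,
                        value = es$lambda, D = Dth, n = es$n)
}

#' Second-order approximation of a change in lambda
#'
#' Convenience helper returning the quadratic expansion
#' \deqn{\Delta\lambda \approx D\,\mathrm{vec}(\Delta A) +
#'   \tfrac12\,\mathrm{vec}^T(\Delta A)\, H\, \mathrm{vec}(\Delta A).}
#' Adding the second-order term is not guaranteed to improve on the
#' linear approximation; for some perturbations it is less accurate.
#'
#' @param M a [stage_matrix()] or plain matrix.
#' @param dA perturbation matrix of the same dimension.
#' @return scalar approximate \eqn{\Delta\lambda}.
#' @export
delta_lambda_second_order <- function(M, dA) {
  sm <- as_stage_matrix(M)
  dA <- as.matrix(dA)
  if (!identical(dim(dA), dim(sm$A)))
    stop("delta_lambda_second_order(): dA dimension mismatch")
  H <- hessian_lambda_A(sm)
  d <- vec(dA)
  as.numeric(H$D %*% d + 0.5 * t(d) %*% H$H %*% d)
}
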